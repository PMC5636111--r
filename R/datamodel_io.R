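#' @importFrom stats median pchisq pt pnorm phyper quantile cor sd var
#'   rnorm rbinom runif optim setNames complete.cases prcomp cov qnorm
#' @importFrom utils read.delim write.table head combn
NULL

# ---- interactome ------------------------------------------------------------

#' Construct an interactome from an edge table
#'
#' An interactome is a directed gene-gene interaction network. Edges carry a
#' directionality tag: `"directed"` arcs are kept as given, `"bidirected"`
#' entries are expanded internally into the two opposite arcs, which share one
#' statistical test downstream only in the sense that both are tested (each
#' direction is tested separately when the network is weighted). Seed genes
#' (a-priori disease-associated genes) get node weight 1, all others 0.
#'
#' @param edges data.frame with columns `source`, `target`, `tag`
#'   (tag in `c("directed", "bidirected")`; missing tag column means all
#'   directed). Self-loops are an error; duplicate arcs are collapsed.
#' @param seeds character vector of seed gene identifiers; ids absent from the
#'   network are counted but ignored.
#' @return object of class `interactome`: an igraph-backed directed graph with
#'   vertex attribute `seed` (0/1) and edge attributes `tag`.
#' @export
interactome <- function(edges, seeds = character()) {
  stopifnot(is.data.frame(edges), ncol(edges) >= 2)
  if (ncol(edges) < 3) edges$tag <- "directed"
  names(edges)[1:3] <- c("source", "target", "tag")
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$tag <- as.character(edges$tag)
  bad_tag <- !edges$tag %in% c("directed", "bidirected")
  if (any(bad_tag)) {
    stop("unknown directionality tag(s): ",
         paste(unique(edges$tag[bad_tag]), collapse = ", "))
  }
  if (any(edges$source == edges$target)) stop("self-loops are not allowed")
  if (nrow(edges) == 0) stop("empty graph")
  # drop exact duplicate entries (j, k, tag)
  edges <- edges[!duplicated(edges[, c("source", "target", "tag")]), ]

  # expand bidirected entries into two arcs, then collapse duplicate arcs
  bi <- edges$tag == "bidirected"
  arcs <- rbind(
    data.frame(from = edges$source, to = edges$target, tag = edges$tag,
               stringsAsFactors = FALSE),
    data.frame(from = edges$target[bi], to = edges$source[bi],
               tag = rep("bidirected", sum(bi)), stringsAsFactors = FALSE)
  )
  dup <- duplicated(paste(arcs$from, arcs$to, sep = "\r"))
  arcs <- arcs[!dup, ]

  nodes <- sort(unique(c(edges$source, edges$target)))
  g <- igraph::graph_from_data_frame(arcs, directed = TRUE,
                                     vertices = data.frame(name = nodes))
  seeds <- unique(as.character(seeds))
  igraph::V(g)$seed <- as.integer(nodes %in% seeds)
  structure(
    list(graph = g,
         n_input_directed = sum(!bi),
         n_input_bidirected = sum(bi),
         seeds_given = seeds,
         seeds_mapped = sum(nodes %in% seeds)),
    class = "interactome")
}

#' Read an interactome from a TSV or SIF edge list
#'
#' TSV dialect: header line, columns `source`, `target`, `tag`.
#' SIF dialect: `source<TAB>relation<TAB>target`, no header; a relation ending
#' in `"bidirected"` (or equal to `"<->"`) is treated as bidirected.
#'
#' @param path file path.
#' @param seeds character vector of seed gene ids.
#' @param format `"tsv"`, `"sif"`, or `"auto"` (by file extension).
#' @return an [interactome]. The number of mapped seeds is reported via
#'   `message()` and stored in the object.
#' @export
read_interactome <- function(path, seeds = character(),
                             format = c("auto", "tsv", "sif")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.sif$", path, ignore.case = TRUE)) "sif" else "tsv"
  }
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty graph: ", path)
  if (format == "tsv") {
    header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
    body <- lines[-1]
    parts <- strsplit(body, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf < 2)) {
      stop("malformed line ", which(nf < 2)[1] + 1L, " in ", path)
    }
    edges <- data.frame(
      source = vapply(parts, `[`, "", 1L),
      target = vapply(parts, `[`, "", 2L),
      tag = vapply(parts, function(p) if (length(p) >= 3) p[3] else "directed", ""),
      stringsAsFactors = FALSE)
  } else {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf < 3)) stop("malformed line ", which(nf < 3)[1], " in ", path)
    rel <- vapply(parts, `[`, "", 2L)
    edges <- data.frame(
      source = vapply(parts, `[`, "", 1L),
      target = vapply(parts, `[`, "", 3L),
      tag = ifelse(rel == "<->" | grepl("bidirected$", rel),
                   "bidirected", "directed"),
      stringsAsFactors = FALSE)
  }
  net <- interactome(edges, seeds)
  message(sprintf("read_interactome: %d/%d seeds mapped to %d nodes",
                  net$seeds_mapped, length(net$seeds_given),
                  igraph::vcount(net$graph)))
  net
}

# collapse the arc set back to input-level entries (bidirected pairs merged)
.interactome_entries <- function(net) {
  el <- igraph::as_data_frame(net$graph, what = "edges")
  bi <- el$tag == "bidirected"
  di <- el[!bi, c("from", "to", "tag")]
  if (any(bi)) {
    b <- el[bi, ]
    key <- ifelse(b$from < b$to, paste(b$from, b$to), paste(b$to, b$from))
    b <- b[!duplicated(key), ]
    lo <- pmin(b$from, b$to); hi <- pmax(b$from, b$to)
    bi_entries <- data.frame(from = lo, to = hi, tag = "bidirected",
                             stringsAsFactors = FALSE)
  } else {
    bi_entries <- di[0, ]
  }
  out <- rbind(di, bi_entries)
  names(out) <- c("source", "target", "tag")
  out[order(out$source, out$target, out$tag), ]
}

#' Write an interactome to disk
#'
#' @param net an [interactome].
#' @param path output file.
#' @param format `"tsv"` (round-trippable edge list), `"sif"`, or `"graphml"`.
#' @export
write_interactome <- function(net, path, format = c("tsv", "sif", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(net$graph, path, format = "graphml")
    return(invisible(path))
  }
  entries <- .interactome_entries(net)
  if (format == "tsv") {
    write.table(entries, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    sif <- data.frame(source = entries$source,
                      relation = ifelse(entries$tag == "bidirected",
                                        "<->", "->"),
                      target = entries$target)
    write.table(sif, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Summarise an interactome
#'
#' Reports node/edge counts, the median total degree and the mean directed
#' shortest-path distance over ordered *reachable* pairs; unreachable ordered
#' pairs are excluded (not set to infinity) and their count reported.
#'
#' @param net an [interactome].
#' @param weights optional per-arc distances in igraph edge order; default
#'   `NULL` counts hops.
#' @return list with `n_nodes`, `n_edges_directed`, `n_edges_bidirected`,
#'   `n_arcs`, `median_degree`, `mean_distance`, `n_unreachable_pairs`.
#' @export
interactome_summary <- function(net, weights = NULL) {
  g <- net$graph
  stopifnot(igraph::vcount(g) > 0)
  d <- igraph::distances(g, mode = "out",
                         weights = if (is.null(weights)) NA else weights)
  off <- row(d) != col(d)
  finite <- is.finite(d) & off
  list(
    n_nodes = igraph::vcount(g),
    n_edges_directed = net$n_input_directed,
    n_edges_bidirected = net$n_input_bidirected,
    n_arcs = igraph::ecount(g),
    median_degree = median(igraph::degree(g, mode = "all")),
    mean_distance = mean(d[finite]),
    n_unreachable_pairs = sum(off & !is.finite(d))
  )
}

# ---- gene scores ------------------------------------------------------------

#' Construct a gene score matrix
#'
#' Continuous per-sample gene scores (e.g. supervised PC1 of the SNPs in each
#' gene region) with a binary case/control label.
#'
#' @param scores numeric matrix, samples x genes, with dimnames.
#' @param group binary vector (0 = control, 1 = case), length `nrow(scores)`.
#' @return object of class `gene_score_matrix` with fields `scores`, `group`,
#'   and `degenerate` (genes constant within both groups simultaneously).
#' @export
gene_score_matrix <- function(scores, group) {
  scores <- as.matrix(scores)
  if (is.null(colnames(scores))) stop("scores must have gene column names")
  if (anyDuplicated(colnames(scores))) stop("gene identifiers must be unique")
  if (is.null(rownames(scores)))
    rownames(scores) <- paste0("S", seq_len(nrow(scores)))
  group <- as.integer(group)
  stopifnot(length(group) == nrow(scores), all(group %in% c(0L, 1L)))
  if (length(unique(group)) < 2) stop("group must contain both classes")
  sd0 <- apply(scores[group == 0L, , drop = FALSE], 2, sd)
  sd1 <- apply(scores[group == 1L, , drop = FALSE], 2, sd)
  degenerate <- colnames(scores)[sd0 == 0 & sd1 == 0]
  structure(list(scores = scores, group = group, degenerate = degenerate),
            class = "gene_score_matrix")
}

#' Read gene scores and group labels from TSV
#'
#' Scores: first column sample id, remaining columns gene scores.
#' Group: two columns, sample id and 0/1 label.
#'
#' @param scores_path,group_path file paths.
#' @return a [gene_score_matrix].
#' @export
read_gene_scores <- function(scores_path, group_path) {
  tab <- read.delim(scores_path, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  grp <- read.delim(group_path, check.names = FALSE)
  g <- setNames(as.integer(grp[[2]]), as.character(grp[[1]]))
  missing <- setdiff(rownames(m), names(g))
  if (length(missing) > 0)
    stop("samples without group label: ", paste(head(missing), collapse = ", "))
  gene_score_matrix(m, g[rownames(m)])
}

#' Write gene scores (and group labels) to TSV
#' @param gsm a [gene_score_matrix].
#' @param scores_path,group_path output files (`group_path` optional).
#' @export
write_gene_scores <- function(gsm, scores_path, group_path = NULL) {
  tab <- data.frame(sample = rownames(gsm$scores), gsm$scores,
                    check.names = FALSE)
  write.table(tab, scores_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(group_path)) {
    write.table(data.frame(sample = rownames(gsm$scores), group = gsm$group),
                group_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(scores_path)
}

# ---- genotypes --------------------------------------------------------------

#' Construct a genotype matrix with SNP and gene coordinates
#'
#' Additive coding: 0 = frequent homozygote, 1 = heterozygote, 2 = rare
#' homozygote; missing values allowed (NA). Coordinates are 1-based inclusive.
#'
#' @param geno integer matrix samples x SNPs (values 0/1/2/NA), with dimnames.
#' @param snp_coords data.frame `snp`, `chr`, `pos`.
#' @param gene_loci data.frame `gene`, `chr`, `start`, `end`.
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, snp_coords, gene_loci) {
  geno <- as.matrix(geno)
  ok <- geno %in% c(0, 1, 2) | is.na(geno)
  if (!all(ok)) stop("genotypes must be additive-coded 0/1/2 or NA")
  stopifnot(all(c("snp", "chr", "pos") %in% names(snp_coords)),
            all(c("gene", "chr", "start", "end") %in% names(gene_loci)),
            !is.null(colnames(geno)))
  if (!all(colnames(geno) %in% snp_coords$snp))
    stop("every genotyped SNP needs coordinates")
  structure(list(geno = geno, snp_coords = snp_coords, gene_loci = gene_loci),
            class = "genotype_matrix")
}

#' Read genotypes plus SNP/gene coordinate tables from TSV
#' @param geno_path samples x SNPs table, first column sample id, NA = missing.
#' @param snps_path columns `snp`, `chr`, `pos`.
#' @param loci_path columns `gene`, `chr`, `start`, `end`.
#' @return a [genotype_matrix].
#' @export
read_genotypes <- function(geno_path, snps_path, loci_path) {
  tab <- read.delim(geno_path, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  genotype_matrix(m, read.delim(snps_path), read.delim(loci_path))
}

# ---- gene sets --------------------------------------------------------------

#' Read gene sets in GMT format
#'
#' One set per line: `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path GMT file.
#' @return object of class `gene_set_collection`: named list of character
#'   vectors with a `description` attribute per set.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(parts) < 3
  if (any(short)) stop("malformed GMT line ", which(short)[1], " in ", path)
  nm <- vapply(parts, `[`, "", 1L)
  if (anyDuplicated(nm)) stop("duplicate gene-set names in ", path)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- nm
  attr(sets, "description") <- setNames(vapply(parts, `[`, "", 2L), nm)
  class(sets) <- "gene_set_collection"
  sets
}

#' Write gene sets in GMT format
#' @param sets a `gene_set_collection` or plain named list of gene vectors.
#' @param path output file.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.interactome <- function(x, ...) {
  cat(sprintf(
    "interactome: %d nodes, %d arcs (%d directed + %d bidirected entries), %d seeds mapped\n",
    igraph::vcount(x$graph), igraph::ecount(x$graph),
    x$n_input_directed, x$n_input_bidirected, x$seeds_mapped))
  invisible(x)
}

#' @export
print.gene_score_matrix <- function(x, ...) {
  cat(sprintf("gene_score_matrix: %d samples (%d cases / %d controls) x %d genes\n",
              nrow(x$scores), sum(x$group == 1), sum(x$group == 0),
              ncol(x$scores)))
  invisible(x)
}
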