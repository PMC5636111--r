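# Hypergeometric over-representation of module genes in gene sets, and the
# perturbance proportion of annotation-mapped subnetworks.

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test P(X >= k) per set, with Bonferroni
#' correction over the sets that could overlap the universe (K >= 1).
#' Module genes outside the universe are dropped with a message. Results are
#' sorted by decreasing gene ratio k/n (dot-plot order), ties by raw p.
#'
#' @param module_genes character vector of module (network) genes.
#' @param sets a `gene_set_collection` (see [read_gmt]) or named list.
#' @param universe character vector of background genes (defaults should be
#'   the genes of the mapped interactome, not the genome).
#' @return data.frame: `set`, `N`, `K`, `n`, `k`, `gene_ratio`, `p`,
#'   `p_adjust` (Bonferroni), `degenerate` (set covers the whole universe),
#'   `genes` (overlap, comma-separated).
#' @export
enrich <- function(module_genes, sets, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop("empty universe")
  module_genes <- unique(as.character(module_genes))
  outside <- setdiff(module_genes, universe)
  if (length(outside) > 0) {
    message(sprintf("enrich: dropping %d module gene(s) outside the universe",
                    length(outside)))
    module_genes <- intersect(module_genes, universe)
  }
  N <- length(universe)
  n <- length(module_genes)
  rows <- lapply(names(sets), function(nm) {
    set_u <- intersect(sets[[nm]], universe)
    K <- length(set_u)
    ov <- intersect(set_u, module_genes)
    k <- length(ov)
    p <- if (K == 0) NA_real_ else
      phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, N = N, K = K, n = n, k = k,
               gene_ratio = if (n > 0) k / n else NA_real_,
               p = p, degenerate = K == N,
               genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  testable <- !is.na(out$p)
  m <- sum(testable)
  out$p_adjust <- ifelse(testable, pmin(1, out$p * m), NA_real_)
  attr(out, "n_tested") <- m
  out[order(-out$gene_ratio, out$p), , drop = FALSE]
}

#' Perturbance proportion of an annotation-mapped subnetwork
#'
#' Induces the subgraph of the disease network on the genes carrying a given
#' annotation (LV nodes excluded) and reports the proportion of perturbed
#' edges in it next to the basal proportion of the whole network.
#'
#' @param net a `disease_network` or `steiner_tree`.
#' @param annotation_genes character vector of annotated genes (>= 2 must be
#'   in the network).
#' @return list: `n_mapped_genes`, `n_edges`, `n_perturbed`, `proportion`
#'   (NA when no edge is induced), `basal_n_edges`, `basal_n_perturbed`,
#'   `basal_proportion`.
#' @export
annotation_subnetwork_perturbance <- function(net, annotation_genes) {
  g <- .gene_graph(net)
  mapped <- intersect(unique(annotation_genes), igraph::V(g)$name)
  if (length(mapped) < 2) stop("annotation maps fewer than 2 network genes")
  sub <- igraph::induced_subgraph(g, which(igraph::V(g)$name %in% mapped))
  pert_all <- igraph::E(g)$perturbed
  pert_sub <- igraph::E(sub)$perturbed
  n_e <- igraph::ecount(sub)
  list(n_mapped_genes = length(mapped),
       n_edges = n_e,
       n_perturbed = if (n_e > 0) sum(pert_sub) else 0L,
       proportion = if (n_e > 0) sum(pert_sub) / n_e else NA_real_,
       basal_n_edges = igraph::ecount(g),
       basal_n_perturbed = sum(pert_all),
       basal_proportion = sum(pert_all) / igraph::ecount(g))
}
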