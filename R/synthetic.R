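# Synthetic-data generator: random sparse directed interactomes with a
# planted perturbation route, case/control gene scores drawn from the same
# linear-Gaussian SEM family the fitting stage assumes, and additive-coded
# genotypes with group-specific allele frequencies for the sPCA stage.

#' Simulation specification
#'
#' The defaults describe the stated world of the package's validation
#' experiments: a 30-node sparse directed interactome (pairwise connection
#' probability 0.1, one third of the entries bidirected as in curated
#' signalling networks), a 5-gene planted perturbation route (4 arcs) with
#' group shift a = 0.8 on the route head, path coefficients c = 0.5 and a
#' direct group effect b = 0.4 on every downstream route gene (each route
#' gene carries disease-associated variants of its own on top of the signal
#' propagated along the path; with b = 0 the group effect would decay
#' geometrically and the route would not be a perturbation route), one
#' latent pair with gamma = 0.6 and loadings (1, 0.8), and 300 samples per
#' group.
#'
#' @param n_nodes number of genes.
#' @param density probability an unordered gene pair is connected.
#' @param bidirected_fraction fraction of connected pairs that are
#'   bidirected entries.
#' @param n_seeds seed-set size (route endpoints always included).
#' @param route_length number of genes on the planted route.
#' @param a group shift on the route head.
#' @param b direct group effect on downstream route genes.
#' @param c_path path coefficient along route arcs.
#' @param n_latent_pairs planted latent common-cause pairs.
#' @param gamma group effect on each latent variable.
#' @param loadings length-2 loadings of each latent pair.
#' @param n_per_group samples per group.
#' @param seed master RNG seed; each operation derives its own stream
#'   (seed*1000 + counter).
#' @return list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_nodes = 30, density = 0.1,
                            bidirected_fraction = 1 / 3,
                            n_seeds = 8, route_length = 5,
                            a = 0.8, b = 0.4, c_path = 0.5,
                            n_latent_pairs = 1, gamma = 0.6,
                            loadings = c(1, 0.8),
                            n_per_group = 300, seed = 1) {
  stopifnot(route_length >= 2, route_length <= n_nodes,
            n_seeds >= 2, n_seeds <= n_nodes,
            all(is.finite(c(a, b, c_path, gamma, loadings))))
  structure(as.list(environment()), class = "simulation_spec")
}

.spec_seed <- function(spec, counter) {
  (spec$seed * 1000 + counter) %% .Machine$integer.max
}

#' Simulate a sparse directed interactome with a planted route
#'
#' Unordered node pairs connect independently with probability
#' `spec$density`; a connected pair is bidirected with probability
#' `spec$bidirected_fraction`, otherwise directed with random orientation.
#' The planted route arcs are guaranteed present (as directed entries) and
#' the route is an induced directed path (no other arcs among route genes).
#' The seed set emulates the outcome of a GWAS on the generated world: it
#' contains every gene with a true group effect (all route genes — the
#' route's endpoints in particular — and the latent-pair genes) plus random
#' extra genes standing in for false or unmappable associations, up to
#' `spec$n_seeds`. Generation retries (with a warning) until the underlying
#' undirected graph is connected.
#'
#' @param spec a [simulation_spec].
#' @return an [interactome]; attributes `route` (ordered node vector),
#'   `route_arcs` (data.frame from/to), `latent_pairs` (data.frame g1/g2).
#' @export
simulate_interactome <- function(spec) {
  set.seed(.spec_seed(spec, 1))
  nodes <- sprintf("g%02d", seq_len(spec$n_nodes))
  route <- sample(nodes, spec$route_length)
  for (try in 1:20) {
    pairs <- t(combn(nodes, 2))
    on <- runif(nrow(pairs)) < spec$density
    pairs <- pairs[on, , drop = FALSE]
    bi <- runif(nrow(pairs)) < spec$bidirected_fraction
    flip <- runif(nrow(pairs)) < 0.5
    edges <- data.frame(
      source = ifelse(flip, pairs[, 2], pairs[, 1]),
      target = ifelse(flip, pairs[, 1], pairs[, 2]),
      tag = ifelse(bi, "bidirected", "directed"),
      stringsAsFactors = FALSE)
    route_arcs <- data.frame(source = route[-length(route)],
                             target = route[-1], tag = "directed",
                             stringsAsFactors = FALSE)
    # the planted route is an induced directed path: drop every generated
    # connection among route genes (shortcuts would make the planted truth
    # ill-defined), then plant the route arcs
    drop <- edges$source %in% route & edges$target %in% route
    edges <- rbind(edges[!drop, ], route_arcs)
    # latent pairs among non-route genes
    nonroute <- setdiff(nodes, route)
    lp <- data.frame(g1 = character(0), g2 = character(0))
    if (spec$n_latent_pairs > 0) {
      cand <- sample(nonroute)
      for (i in seq_len(spec$n_latent_pairs)) {
        if (length(cand) < 2) break
        lp <- rbind(lp, data.frame(g1 = cand[1], g2 = cand[2],
                                   stringsAsFactors = FALSE))
        cand <- cand[-(1:2)]
      }
    }
    # seeds emulate GWAS-flagged genes: every gene with a true group effect
    # (route genes, latent-pair genes) plus random extras standing in for
    # false or unmappable associations
    assoc <- c(route, lp$g1, lp$g2)
    seeds <- unique(c(assoc, sample(setdiff(nodes, assoc),
                                    max(0, spec$n_seeds - length(assoc)))))
    net <- interactome(edges, seeds = seeds)
    und <- igraph::as_undirected(net$graph, mode = "collapse")
    if (igraph::vcount(net$graph) == spec$n_nodes &&
        igraph::is_connected(und)) break
    if (try == 20) stop("could not generate a connected interactome; raise density")
    warning("generated graph not connected; retrying")
  }
  attr(net, "route") <- route
  attr(net, "route_arcs") <- route_arcs[, 1:2]
  attr(net, "latent_pairs") <- lp
  net
}

#' Simulate case/control gene scores from the planted SEM
#'
#' Scores follow the linear-Gaussian structural equations in route order:
#' the route head gets `Y = a*C + U`, each downstream route gene
#' `Y = b*C + c_path*Y_parent + U`; each latent pair shares a factor
#' `LV = gamma*C + f` loading with `spec$loadings`; every other gene is
#' i.i.d. standard normal. Disturbances are standard normal.
#'
#' @param net an interactome from [simulate_interactome] (carries the route
#'   and latent-pair attributes) or any interactome (then only `spec`'s
#'   route genes present in the graph are planted).
#' @param spec a [simulation_spec].
#' @return a [gene_score_matrix]; attribute `truth` lists `route`,
#'   `route_arcs`, `perturbed_genes` (genes with a non-null total group
#'   effect) and `latent_pairs`.
#' @export
simulate_scores <- function(net, spec) {
  set.seed(.spec_seed(spec, 2))
  nodes <- igraph::V(net$graph)$name
  route <- intersect(attr(net, "route"), nodes)
  lp <- attr(net, "latent_pairs")
  n <- 2 * spec$n_per_group
  C <- rep(c(0L, 1L), each = spec$n_per_group)
  Y <- matrix(rnorm(n * length(nodes)), n, length(nodes),
              dimnames = list(sprintf("S%04d", seq_len(n)), nodes))
  if (length(route) >= 1) {
    Y[, route[1]] <- spec$a * C + rnorm(n)
    if (length(route) >= 2) {
      for (i in 2:length(route)) {
        Y[, route[i]] <- spec$b * C + spec$c_path * Y[, route[i - 1]] +
          rnorm(n)
      }
    }
  }
  if (!is.null(lp) && nrow(lp) > 0) {
    for (i in seq_len(nrow(lp))) {
      LV <- spec$gamma * C + rnorm(n)
      Y[, lp$g1[i]] <- spec$loadings[1] * LV + rnorm(n)
      Y[, lp$g2[i]] <- spec$loadings[2] * LV + rnorm(n)
    }
  }
  out <- gene_score_matrix(Y, C)
  # total group effect on route gene i: a*c^(i-1) + b * sum(c^(0..i-2))
  tot <- if (length(route) > 0) {
    vapply(seq_along(route), function(i) {
      spec$a * spec$c_path^(i - 1) +
        if (i > 1) spec$b * sum(spec$c_path^(0:(i - 2))) else 0
    }, 0)
  } else numeric(0)
  # latent-pair genes are group-dependent too: total effect gamma * loading
  lp_genes <- if (!is.null(lp) && nrow(lp) > 0 && abs(spec$gamma) > 1e-12)
    c(lp$g1, lp$g2)[rep(abs(spec$loadings) > 1e-12, each = nrow(lp))] else
    character(0)
  attr(out, "truth") <- list(
    route = route,
    route_arcs = attr(net, "route_arcs"),
    perturbed_genes = union(route[abs(tot) > 1e-12], lp_genes),
    total_effects = setNames(tot, route),
    latent_pairs = lp)
  out
}

#' Simulate additive-coded genotypes with planted frequency differences
#'
#' Lays `n_genes` loci 1 Mb apart on one chromosome, gives each
#' `snps_per_gene` SNPs inside the locus, and draws dosages
#' `Binomial(2, f)` with `f = base_freq` in controls and
#' `f = base_freq + delta` in cases for the first `informative_snps` SNPs of
#' each gene (the rest stay at `base_freq` in both groups).
#'
#' @param spec a [simulation_spec] (only `n_per_group` and `seed` are read).
#' @param n_genes,snps_per_gene,informative_snps layout of the genotype set.
#' @param base_freq,delta minor-allele frequency and its case/control
#'   difference; frequencies must stay inside (0, 1).
#' @return a [genotype_matrix]; attribute `group` holds the 0/1 labels and
#'   `informative` the informative SNP names.
#' @export
simulate_genotypes <- function(spec, n_genes = 5, snps_per_gene = 10,
                               informative_snps = 3, base_freq = 0.3,
                               delta = 0.2) {
  f_case <- base_freq + delta
  if (base_freq <= 0 || base_freq >= 1 || f_case <= 0 || f_case >= 1)
    stop("allele frequencies must lie in (0, 1)")
  set.seed(.spec_seed(spec, 3))
  n <- 2 * spec$n_per_group
  group <- rep(c(0L, 1L), each = spec$n_per_group)
  loci <- data.frame(gene = sprintf("gene%02d", seq_len(n_genes)),
                     chr = "chr1",
                     start = seq_len(n_genes) * 1e6,
                     end = seq_len(n_genes) * 1e6 + 5e4)
  snp_rows <- list(); cols <- list(); informative <- character(0)
  for (gi in seq_len(n_genes)) {
    for (si in seq_len(snps_per_gene)) {
      snp <- sprintf("%s_snp%02d", loci$gene[gi], si)
      info <- si <= informative_snps
      f <- ifelse(group == 1 & info, f_case, base_freq)
      cols[[snp]] <- rbinom(n, 2, f)
      snp_rows[[snp]] <- data.frame(snp = snp, chr = "chr1",
                                    pos = loci$start[gi] + si * 1000)
      if (info) informative <- c(informative, snp)
    }
  }
  geno <- do.call(cbind, cols)
  rownames(geno) <- sprintf("S%04d", seq_len(n))
  gm <- genotype_matrix(geno, do.call(rbind, snp_rows), loci)
  attr(gm, "group") <- group
  attr(gm, "informative") <- informative
  gm
}
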