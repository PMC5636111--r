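# Perturbance of a directed link j -> k: the case/control group effect on
# gene j, gene k and their direct connection, tested jointly through the
# recursive trivariate model
#   X_j = a*C + e1,   Y_k = b*C + c*X_j + e2
# The total group effect on k through j is tau = b + a*c; its p-value maps to
# the edge weight w = 1/(-ln p), so the most perturbed edges are the lightest.

# Vectorised trivariate fit. x, y: n x m matrices (one column per edge),
# C: binary group vector. Returns a data.frame of per-edge statistics.
# Intercepts are implicit: all moments are computed on centred columns, which
# matches covariance-structure ML for this recursive Gaussian system.
.edge_stats <- function(x, y, C, method = c("tau", "lrt")) {
  method <- match.arg(method)
  x <- as.matrix(x); y <- as.matrix(y)
  n <- length(C)
  stopifnot(nrow(x) == n, nrow(y) == n, ncol(x) == ncol(y))
  m <- ncol(x)
  Cc <- C - mean(C)
  xc <- sweep(x, 2, colMeans(x))
  yc <- sweep(y, 2, colMeans(y))
  Scc <- sum(Cc^2)
  Scx <- as.numeric(crossprod(Cc, xc))
  Scy <- as.numeric(crossprod(Cc, yc))
  Sxx <- colSums(xc^2)
  Sxy <- colSums(xc * yc)
  Syy <- colSums(yc^2)

  const_x <- Sxx <= 0
  const_y <- Syy <= 0

  # eq 1: X ~ C
  a <- ifelse(const_x, 0, Scx / Scc)
  rss1 <- pmax(Sxx - a^2 * Scc, 0)
  va <- rss1 / pmax(n - 2, 1) / Scc

  # eq 2: Y ~ C + X  (2x2 normal equations on centred data)
  det2 <- Scc * Sxx - Scx^2
  det2[const_x] <- NA
  b <- (Sxx * Scy - Scx * Sxy) / det2
  cc <- (Scc * Sxy - Scx * Scy) / det2
  b[const_x] <- Scy[const_x] / Scc
  cc[const_x] <- 0
  rss2 <- pmax(Syy - b * Scy - cc * Sxy, 0)
  s2 <- rss2 / pmax(n - 3, 1)
  # covariance of (b, c) from the inverse 2x2 moment matrix
  vb <- s2 * Sxx / det2
  vc <- s2 * Scc / det2
  cbc <- -s2 * Scx / det2
  vb[const_x] <- s2[const_x] / Scc
  vc[const_x] <- 0
  cbc[const_x] <- 0

  tau <- b + a * cc
  vtau <- vb + cc^2 * va + a^2 * vc + 2 * a * cbc
  t_stat <- tau / sqrt(pmax(vtau, .Machine$double.eps))
  df <- n - 3
  p <- 2 * pt(-abs(t_stat), df)

  if (method == "lrt") {
    # 3-df LRT of (a, b, tau jointly zero) == full group independence
    # log-likelihood difference from the two regressions' RSS ratios
    rss1_0 <- Sxx
    rss2_0 <- pmax(Syy - Sxy^2 / ifelse(const_x, Inf, Sxx), 0)
    lrt <- n * (log(rss1_0 / pmax(rss1, .Machine$double.eps)) +
                log(rss2_0 / pmax(rss2, .Machine$double.eps)))
    p <- pchisq(pmax(lrt, 0), df = 2, lower.tail = FALSE)
    t_stat <- sqrt(pmax(lrt, 0))
  }

  flagged <- const_x | const_y
  p[flagged] <- 1
  p <- pmin(pmax(p, 1e-16), 1 - 1e-16)
  w <- 1 / (-log(p))
  data.frame(a = a, b = b, c = cc, tau = tau, se = sqrt(pmax(vtau, 0)),
             t = t_stat, p = p, w = w, perturbed = p < 0.05,
             degenerate = flagged)
}

#' Perturbance test for one gene-gene link
#'
#' Fits the recursive trivariate model `X_j = a*C + e1`,
#' `Y_k = b*C + c*X_j + e2` by least squares (equivalent to ML for this
#' recursive Gaussian system) and tests the total group effect on gene `k`
#' through gene `j`, `tau = b + a*c`, with a delta-method standard error and a
#' Student-t reference with n - 3 degrees of freedom. The perturbance weight
#' is `w = 1/(-ln p)`; p is clamped to `[1e-16, 1 - 1e-16]` so w stays finite.
#' An edge with p < 0.05 (w < 0.3338) is flagged perturbed.
#'
#' @param scores a [gene_score_matrix].
#' @param j,k gene identifiers (direction j -> k).
#' @param method `"tau"` (default: one-parameter t-test of the combined
#'   difference) or `"lrt"` (2-df likelihood-ratio test of any group effect).
#' @return one-row data.frame: `j, k, a, b, c, tau, se, t, p, w, perturbed,
#'   degenerate`.
#' @export
edge_perturbance <- function(scores, j, k, method = c("tau", "lrt")) {
  stopifnot(inherits(scores, "gene_score_matrix"))
  miss <- setdiff(c(j, k), colnames(scores$scores))
  if (length(miss) > 0)
    stop("gene(s) missing from scores: ", paste(miss, collapse = ", "))
  n0 <- sum(scores$group == 0); n1 <- sum(scores$group == 1)
  if (min(n0, n1) < 10)
    warning(sprintf("fewer than 10 samples in a group (%d/%d)", n0, n1))
  st <- .edge_stats(scores$scores[, j, drop = FALSE],
                    scores$scores[, k, drop = FALSE],
                    scores$group, method = method)
  cbind(data.frame(j = j, k = k, stringsAsFactors = FALSE), st)
}

#' Weight a whole interactome by edge perturbance
#'
#' Applies [edge_perturbance] to every arc. The two arcs of a bidirected pair
#' are tested separately (j -> k and k -> j generally differ). Arcs with an
#' endpoint absent from the score matrix are dropped and counted; more than
#' 50% unmapped arcs aborts.
#'
#' @param scores a [gene_score_matrix].
#' @param net an [interactome].
#' @param method see [edge_perturbance].
#' @return object of class `weighted_interactome`: the (possibly reduced)
#'   interactome whose graph carries per-arc attributes
#'   `a, b, c, tau, se, t, p, w, perturbed`, plus an `edge_table` data.frame.
#' @export
weight_network <- function(scores, net, method = c("tau", "lrt")) {
  stopifnot(inherits(scores, "gene_score_matrix"),
            inherits(net, "interactome"))
  g <- net$graph
  el <- igraph::as_data_frame(g, what = "edges")
  genes <- colnames(scores$scores)
  mapped <- el$from %in% genes & el$to %in% genes
  n_drop <- sum(!mapped)
  if (n_drop > 0.5 * nrow(el)) {
    stop(sprintf("%d/%d arcs have endpoints missing from the scores",
                 n_drop, nrow(el)))
  }
  if (n_drop > 0) {
    g <- igraph::subgraph_from_edges(g, which(mapped), delete.vertices = TRUE)
    el <- el[mapped, , drop = FALSE]
  }
  st <- .edge_stats(scores$scores[, el$from, drop = FALSE],
                    scores$scores[, el$to, drop = FALSE],
                    scores$group, method = method)
  for (col in names(st)) g <- igraph::set_edge_attr(g, col, value = st[[col]])
  tab <- cbind(data.frame(j = el$from, k = el$to, tag = el$tag,
                          stringsAsFactors = FALSE), st)
  bi_pairs <- el$tag == "bidirected"
  structure(list(graph = g, edge_table = tab, n_dropped_arcs = n_drop,
                 n_input_directed = sum(!bi_pairs),
                 n_input_bidirected = sum(bi_pairs) %/% 2L,
                 seeds_given = net$seeds_given,
                 seeds_mapped = sum(igraph::V(g)$seed == 1)),
            class = c("weighted_interactome", "interactome"))
}

#' @export
print.weighted_interactome <- function(x, ...) {
  cat(sprintf(
    "weighted_interactome: %d nodes, %d arcs (%d perturbed, p < 0.05), %d arcs dropped\n",
    igraph::vcount(x$graph), igraph::ecount(x$graph),
    sum(x$edge_table$perturbed), x$n_dropped_arcs))
  invisible(x)
}

#' Write the weighted edge table to TSV
#' @param wnet a `weighted_interactome`.
#' @param path output file.
#' @export
write_weighted_edges <- function(wnet, path) {
  write.table(wnet$edge_table, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
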