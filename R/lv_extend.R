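# Latent-variable extension: screen residual covariances between target
# genes (ancestral bow-free pairs), fit a common-cause LV model per selected
# pair, and augment the Steiner tree into the final disease network.

#' Screen ancestral bow-free covariances between target genes
#'
#' For every unordered pair of out-degree-0 (target) genes with no directed
#' path between them, computes the residual correlation of the two genes
#' after removing the fitted parent and group effects, Fisher's normalising
#' transform `z = atanh(r)`, and `t = z * sqrt(n - 3)`. Pairs with `|t| > 2`
#' are selected.
#'
#' @param fit a `sem_fit` for the tree.
#' @param tree the `steiner_tree` the fit was built from.
#' @param scores a [gene_score_matrix].
#' @return data.frame: `g1`, `g2`, `r`, `fisher_z`, `t`, `selected`, ordered
#'   by decreasing `|t|`.
#' @export
screen_covariances <- function(fit, tree, scores) {
  stopifnot(inherits(fit, "sem_fit"))
  n <- nrow(scores$scores)
  if (n <= 3) stop("need more than 3 samples for Fisher's transform")
  model <- fit$model
  g <- tree$graph
  targets <- sort(igraph::V(g)$name[igraph::degree(g, mode = "out") == 0])
  if (length(targets) < 2)
    return(data.frame(g1 = character(0), g2 = character(0), r = numeric(0),
                      fisher_z = numeric(0), t = numeric(0),
                      selected = logical(0)))
  X <- cbind(C = scores$group, scores$scores[, model$genes, drop = FALSE])
  Xc <- sweep(X, 2, colMeans(X))
  resid <- Xc - Xc %*% t(fit$B)       # per-equation disturbances
  colnames(resid) <- colnames(X)

  cmb <- t(combn(targets, 2))
  # no directed path can join two out-degree-0 nodes; assert anyway
  dmat <- igraph::distances(g, v = targets, to = targets, mode = "out")
  keep <- !is.finite(dmat[cbind(cmb[, 1], cmb[, 2])]) &
          !is.finite(dmat[cbind(cmb[, 2], cmb[, 1])])
  cmb <- cmb[keep, , drop = FALSE]
  r <- vapply(seq_len(nrow(cmb)), function(i) {
    cor(resid[, cmb[i, 1]], resid[, cmb[i, 2]])
  }, 0)
  r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  z <- atanh(r)
  tstat <- z * sqrt(n - 3)
  out <- data.frame(g1 = cmb[, 1], g2 = cmb[, 2], r = r, fisher_z = z,
                    t = tstat, selected = abs(tstat) > 2,
                    stringsAsFactors = FALSE)
  out[order(-abs(out$t)), , drop = FALSE]
}

# implied covariance of (C, Yj, Yk) under the LV model
#   LV = gamma*C + d, var(d) = phi;  Yj = LV + ej;  Yk = lambda*LV + ek
.lv_sigma <- function(par, varC) {
  gamma <- par[1]; lambda <- par[2]
  phi <- exp(par[3]); tj <- exp(par[4]); tk <- exp(par[5])
  v <- gamma^2 * varC + phi
  Sigma <- matrix(0, 3, 3)
  Sigma[1, 1] <- varC
  Sigma[1, 2] <- Sigma[2, 1] <- gamma * varC
  Sigma[1, 3] <- Sigma[3, 1] <- lambda * gamma * varC
  Sigma[2, 2] <- v + tj
  Sigma[2, 3] <- Sigma[3, 2] <- lambda * v
  Sigma[3, 3] <- lambda^2 * v + tk
  Sigma
}

.lv_fit_once <- function(S, n) {
  varC <- S[1, 1]
  g0 <- S[1, 2] / varC
  l0 <- if (abs(S[1, 2]) > 1e-10) S[1, 3] / S[1, 2] else
    sign(S[2, 3] + 1e-300)
  v0 <- if (abs(l0) > 1e-10) S[2, 3] / l0 else 0.5 * S[2, 2]
  v0 <- max(v0, 1e-4)
  phi0 <- max(v0 - g0^2 * varC, 1e-4)
  tj0 <- max(S[2, 2] - v0, 1e-4)
  tk0 <- max(S[3, 3] - l0^2 * v0, 1e-4)
  par0 <- c(g0, l0, log(phi0), log(tj0), log(tk0))
  obj <- function(par) .sem_fml(.lv_sigma(par, varC), S)
  opt <- optim(par0, obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  opt
}

#' Fit the latent-variable common-cause model for one target pair
#'
#' Model: `LV = gamma*C + d`, `Y_j = LV + e_j` (loading fixed to 1 for
#' identification), `Y_k = lambda*LV + e_k`. Fitted by ML on the covariance
#' of `(C, Y_j, Y_k)`; goodness of fit by LRT against the saturated
#' covariance (6 moments - 5 free parameters = 1 df). The group effect gamma
#' gets a bootstrap t-test (stratified resampling). Residual variances are
#' log-parameterised, so Heywood cases are handled by the boundary; a fit
#' ending within 1e-6 of the boundary is flagged.
#'
#' @param pair one row of the [screen_covariances] table (or a list with
#'   `g1`, `g2`).
#' @param scores a [gene_score_matrix].
#' @param B bootstrap resamples for the gamma SE.
#' @param seed RNG seed.
#' @return object of class `lv_fit`: `g1`, `g2`, `gamma`, `lambda`,
#'   `gamma_se`, `gamma_t`, `gamma_p`, `LRT`, `df`, `p_LRT`, `good_fit`
#'   (p_LRT >= 0.05), `perturbed` (gamma significant AND good fit),
#'   `heywood`, `converged`.
#' @export
fit_lv_model <- function(pair, scores, B = 200, seed = 1) {
  g1 <- as.character(pair$g1); g2 <- as.character(pair$g2)
  X <- cbind(C = scores$group, scores$scores[, c(g1, g2), drop = FALSE])
  n <- nrow(X)
  S <- crossprod(sweep(X, 2, colMeans(X))) / n
  opt <- .lv_fit_once(S, n)
  est <- opt$par
  F_ML <- opt$value
  LRT <- n * F_ML
  p_LRT <- pchisq(LRT, df = 1, lower.tail = FALSE)
  heywood <- any(exp(est[3:5]) < 1e-6)

  idx0 <- which(scores$group == 0L); idx1 <- which(scores$group == 1L)
  set.seed(seed)
  gboot <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    take <- c(sample(idx0, length(idx0), replace = TRUE),
              sample(idx1, length(idx1), replace = TRUE))
    Xb <- X[take, , drop = FALSE]
    Sb <- crossprod(sweep(Xb, 2, colMeans(Xb))) / nrow(Xb)
    ob <- tryCatch(.lv_fit_once(Sb, nrow(Xb)), error = function(e) NULL)
    if (!is.null(ob) && ob$convergence == 0) gboot[b] <- ob$par[1]
  }
  se <- sd(gboot, na.rm = TRUE)
  tg <- est[1] / se
  pg <- 2 * pnorm(-abs(tg))
  structure(list(g1 = g1, g2 = g2,
                 gamma = est[1], lambda = est[2],
                 phi = exp(est[3]), theta1 = exp(est[4]), theta2 = exp(est[5]),
                 gamma_se = se, gamma_t = tg, gamma_p = pg,
                 F_ML = F_ML, LRT = LRT, df = 1L, p_LRT = p_LRT,
                 good_fit = p_LRT >= 0.05,
                 perturbed = pg < 0.05 && p_LRT >= 0.05,
                 heywood = heywood, converged = opt$convergence == 0,
                 n = n, B = B),
            class = "lv_fit")
}

#' @export
print.lv_fit <- function(x, ...) {
  cat(sprintf(
    "lv_fit %s--%s: gamma=%.3f (p=%.3g), lambda=%.3f, LRT=%.2f (p=%.3g)%s%s\n",
    x$g1, x$g2, x$gamma, x$gamma_p, x$lambda, x$LRT, x$p_LRT,
    if (x$good_fit) " [good fit]" else "",
    if (x$perturbed) " [perturbed]" else ""))
  invisible(x)
}

#' Augment the Steiner tree with latent-variable nodes
#'
#' Adds one LV node per fitted pair, linked to its two target genes (all
#' selected pairs enter the network; the good-fit & significant-gamma subset
#' is flagged perturbed). Node count = tree nodes + pairs; edge count = tree
#' edges + 2 * pairs. The tree's own nodes and edges are unchanged.
#'
#' @param tree a `steiner_tree`.
#' @param lv_fits list of `lv_fit` objects (may be empty).
#' @return object of class `disease_network`: igraph graph with vertex
#'   attribute `lv` (1 for LV nodes), LV arcs tagged `"lv"`, plus `lv_table`.
#' @export
augment_network <- function(tree, lv_fits = list()) {
  g <- tree$graph
  igraph::V(g)$lv <- 0L
  if (length(lv_fits) > 0) {
    for (i in seq_along(lv_fits)) {
      f <- lv_fits[[i]]
      nm <- paste0("LV", i)
      g <- igraph::add_vertices(g, 1, name = nm, lv = 1L, role = "lv",
                                seed = 0L, terminal = 0L,
                                main_component = NA_integer_)
      g <- igraph::add_edges(g, c(nm, f$g1, nm, f$g2),
                             attr = list(tag = "lv",
                                         perturbed = f$perturbed,
                                         p = f$gamma_p, w = NA_real_))
    }
  }
  lv_table <- if (length(lv_fits) > 0) {
    do.call(rbind, lapply(seq_along(lv_fits), function(i) {
      f <- lv_fits[[i]]
      data.frame(lv = paste0("LV", i), g1 = f$g1, g2 = f$g2,
                 gamma = f$gamma, gamma_p = f$gamma_p, lambda = f$lambda,
                 LRT = f$LRT, p_LRT = f$p_LRT, good_fit = f$good_fit,
                 perturbed = f$perturbed, heywood = f$heywood,
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame()
  }
  structure(list(graph = g, tree = tree, lv_table = lv_table,
                 n_tree_nodes = igraph::vcount(tree$graph),
                 n_tree_edges = igraph::ecount(tree$graph),
                 n_lv = length(lv_fits)),
            class = "disease_network")
}

#' @export
print.disease_network <- function(x, ...) {
  cat(sprintf(
    "disease_network: %d nodes (%d genes + %d LVs), %d edges (%d + 2*%d)\n",
    igraph::vcount(x$graph), x$n_tree_nodes, x$n_lv,
    igraph::ecount(x$graph), x$n_tree_edges, x$n_lv))
  if (x$n_lv > 0)
    cat(sprintf("  %d LVs with good fit, %d perturbed\n",
                sum(x$lv_table$good_fit), sum(x$lv_table$perturbed)))
  invisible(x)
}
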