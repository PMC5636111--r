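# Structural equation model over the Steiner tree.
#
# Every gene j becomes a variable Y_j with equation
#   Y_j = beta_jC * C + sum_{k in pa(j)} beta_jk * Y_k + U_j
# where C is the binary group node connected to every gene. Disturbance
# covariances psi_jk are allowed only between "sibling" pairs: out-degree-0
# (target) genes not joined by a directed edge (the bow-free condition).
# Fitting minimises the Gaussian ML discrepancy
#   F_ML = log|Sigma(theta)| + tr(S Sigma^-1) - log|S| - (p+1)
# over the joint vector (C, Y_1..Y_p), with var(C) fixed at its sample value.

#' Convert a Steiner tree into a SEM specification
#'
#' @param tree a `steiner_tree`.
#' @param beta gene-gene coefficient mode: `"ade"` (fixed at the
#'   group-frequency-weighted average of within-group OLS slopes),
#'   `"two"` (two free parameters, split by sign of the pooled endpoint
#'   correlation), `"fixed"` (constants 0.1 / -0.1 by the same split), or
#'   `"free"`.
#' @param variances `"equal"` (one disturbance variance) or `"unequal"`.
#' @param covariances `"zero"` or `"bowfree"` (free psi_jk for every
#'   unordered target pair not joined by a directed edge).
#' @return object of class `sem_model` with the ordered gene list, arc table,
#'   sibling pairs and constraint spec.
#' @export
tree_to_sem <- function(tree, beta = c("ade", "two", "fixed", "free"),
                        variances = c("equal", "unequal"),
                        covariances = c("bowfree", "zero")) {
  beta <- match.arg(beta)
  variances <- match.arg(variances)
  covariances <- match.arg(covariances)
  g <- tree$graph
  if (!igraph::is_dag(g)) stop("directed part of the tree contains a cycle")
  ord <- igraph::topo_sort(g, mode = "out")
  genes <- igraph::V(g)$name[as.integer(ord)]
  el <- igraph::as_data_frame(g, what = "edges")
  arcs <- data.frame(parent = el$from, child = el$to,
                     stringsAsFactors = FALSE)
  targets <- igraph::V(g)$name[igraph::degree(g, mode = "out") == 0]
  sib <- data.frame(g1 = character(0), g2 = character(0))
  if (covariances == "bowfree" && length(targets) >= 2) {
    cmb <- t(combn(sort(targets), 2))
    # targets have out-degree 0, so no directed edge or path can join them;
    # keep the explicit no-shared-edge check for safety
    joined <- paste(cmb[, 1], cmb[, 2]) %in%
      c(paste(arcs$parent, arcs$child), paste(arcs$child, arcs$parent))
    sib <- data.frame(g1 = cmb[!joined, 1], g2 = cmb[!joined, 2],
                      stringsAsFactors = FALSE)
  }
  structure(list(genes = genes, arcs = arcs, sib = sib,
                 exogenous = igraph::V(g)$name[
                   igraph::degree(g, mode = "in") == 0],
                 beta = beta, variances = variances,
                 covariances = covariances),
            class = "sem_model")
}

# ---- internal fitting machinery --------------------------------------------

# ML (1/n) covariance of cbind(C, genes)
.sem_sample_cov <- function(model, scores) {
  Y <- scores$scores[, model$genes, drop = FALSE]
  X <- cbind(C = scores$group, Y)
  n <- nrow(X)
  S <- crossprod(sweep(X, 2, colMeans(X))) / n
  list(S = S, n = n)
}

# fixed gene-gene beta values for the "ade" and "fixed" modes, and the
# sign partition used by the "two" and "fixed" modes
.sem_beta_fixed <- function(model, scores) {
  n_arc <- nrow(model$arcs)
  if (n_arc == 0) return(list(values = numeric(0), pos = logical(0)))
  Y <- scores$scores
  C <- scores$group
  pos <- logical(n_arc)
  ade <- numeric(n_arc)
  n <- length(C)
  for (i in seq_len(n_arc)) {
    pa <- Y[, model$arcs$parent[i]]
    ch <- Y[, model$arcs$child[i]]
    pos[i] <- cor(pa, ch) >= 0
    s <- 0
    for (g in c(0L, 1L)) {
      idx <- C == g
      vg <- var(pa[idx])
      slope <- if (is.na(vg) || vg == 0) 0 else
        cov(pa[idx], ch[idx]) / vg
      s <- s + sum(idx) / n * slope
    }
    ade[i] <- s
  }
  list(values = switch(model$beta,
                       ade = ade,
                       fixed = ifelse(pos, 0.1, -0.1),
                       NULL),
       pos = pos, ade = ade)
}

# parameter layout: named index list over theta
.sem_layout <- function(model) {
  p <- length(model$genes)
  n_arc <- nrow(model$arcs)
  k <- 0
  idx <- list()
  idx$bC <- k + seq_len(p); k <- k + p
  idx$bE <- switch(model$beta,
                   free = { r <- k + seq_len(n_arc); k <- k + n_arc; r },
                   two = { r <- k + 1:2; k <- k + 2; r },
                   integer(0))
  nv <- if (model$variances == "equal") 1L else p
  idx$v <- k + seq_len(nv); k <- k + nv
  ns <- nrow(model$sib)
  idx$s <- if (ns > 0) { r <- k + seq_len(ns); r } else integer(0)
  k <- k + ns
  idx$n_par <- k
  idx
}

# assemble B and Psi ((p+1) x (p+1), C first) from theta
.sem_matrices <- function(theta, model, layout, fixed_beta, varC) {
  p <- length(model$genes)
  d <- p + 1L
  gi <- setNames(seq_len(p) + 1L, model$genes)
  B <- matrix(0, d, d)
  B[2:d, 1] <- theta[layout$bC]
  if (nrow(model$arcs) > 0) {
    bvals <- switch(model$beta,
                    free = theta[layout$bE],
                    two = ifelse(fixed_beta$pos, theta[layout$bE[1]],
                                 theta[layout$bE[2]]),
                    fixed_beta$values)
    B[cbind(gi[model$arcs$child], gi[model$arcs$parent])] <- bvals
  }
  Psi <- matrix(0, d, d)
  Psi[1, 1] <- varC
  psis <- exp(theta[layout$v])
  diag(Psi)[2:d] <- if (model$variances == "equal") rep(psis[1], p) else psis
  if (nrow(model$sib) > 0) {
    i1 <- gi[model$sib$g1]; i2 <- gi[model$sib$g2]
    Psi[cbind(i1, i2)] <- theta[layout$s]
    Psi[cbind(i2, i1)] <- theta[layout$s]
  }
  list(B = B, Psi = Psi)
}

.sem_implied <- function(B, Psi) {
  IB <- diag(nrow(B)) - B
  Ainv <- solve(IB)
  Ainv %*% Psi %*% t(Ainv)
}

.sem_fml <- function(Sigma, S) {
  cS <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(cS)) return(1e10)
  ldet_Sigma <- 2 * sum(log(diag(cS)))
  Sinv <- chol2inv(cS)
  cs <- chol(S)
  ldet_S <- 2 * sum(log(diag(cs)))
  f <- ldet_Sigma + sum(Sinv * S) - ldet_S - nrow(S)
  if (!is.finite(f)) 1e10 else f
}

# per-equation OLS (covariance-based) start values; exact ML when betas are
# free, variances unequal, covariances zero
.sem_ols <- function(model, S) {
  p <- length(model$genes)
  gi <- setNames(seq_len(p) + 1L, model$genes)
  bC <- numeric(p)
  bE <- numeric(nrow(model$arcs))
  psi <- numeric(p)
  for (j in seq_len(p)) {
    gene <- model$genes[j]
    parents <- model$arcs$parent[model$arcs$child == gene]
    pr <- c(1L, gi[parents])
    coefs <- solve(S[pr, pr, drop = FALSE], S[pr, gi[gene]])
    bC[j] <- coefs[1]
    if (length(parents) > 0) {
      rows <- which(model$arcs$child == gene)
      bE[rows] <- coefs[-1][match(model$arcs$parent[rows], parents)]
    }
    psi[j] <- S[gi[gene], gi[gene]] -
      sum(coefs * S[pr, gi[gene]])
  }
  list(bC = bC, bE = bE, psi = pmax(psi, 1e-8))
}

#' Fit a SEM by maximum likelihood
#'
#' Minimises the ML discrepancy between the model-implied and sample
#' covariance of `(C, Y_1..Y_p)`. `var(C)` is fixed at its sample value.
#' Free-beta / unequal-variance / zero-covariance models are solved in closed
#' form (per-equation OLS, exact for recursive Gaussian systems); everything
#' else runs quasi-Newton (BFGS) from an OLS warm start.
#'
#' @param model a `sem_model`.
#' @param scores a [gene_score_matrix] containing all model genes.
#' @return object of class `sem_fit`: `estimates` (named vector of free
#'   parameters), `B`, `Psi`, `Sigma`, `S`, `F_ML`, `logL`, `LRT`, `df`,
#'   `AIC`, `BIC`, `SRMR`, `t` (free-parameter count), `n`, `converged`.
#' @export
fit_sem <- function(model, scores) {
  stopifnot(inherits(model, "sem_model"),
            inherits(scores, "gene_score_matrix"))
  miss <- setdiff(model$genes, colnames(scores$scores))
  if (length(miss) > 0)
    stop("genes missing from scores: ", paste(head(miss), collapse = ", "))
  sc <- .sem_sample_cov(model, scores)
  S <- sc$S; n <- sc$n
  p <- length(model$genes)
  if (n <= p + 1) warning("sample size does not exceed variable count")
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  ridge <- 0
  if (min(ev) < 1e-10) {
    ridge <- 1e-8
    S <- S + diag(ridge, nrow(S))
    message("singular sample covariance: ridge ", ridge, " applied")
  }
  varC <- S[1, 1]
  layout <- .sem_layout(model)
  fixed_beta <- .sem_beta_fixed(model, scores)
  ols <- .sem_ols(model, S)

  theta0 <- numeric(layout$n_par)
  theta0[layout$bC] <- ols$bC
  if (model$beta == "free") theta0[layout$bE] <- ols$bE
  if (model$beta == "two") {
    theta0[layout$bE[1]] <- mean(ols$bE[fixed_beta$pos], na.rm = TRUE)
    theta0[layout$bE[2]] <- mean(ols$bE[!fixed_beta$pos], na.rm = TRUE)
    theta0[layout$bE][!is.finite(theta0[layout$bE])] <- 0
  }
  theta0[layout$v] <- if (model$variances == "equal")
    log(mean(ols$psi)) else log(ols$psi)
  # sibling covariances start at 0 (theta defaults)

  obj <- function(theta) {
    M <- .sem_matrices(theta, model, layout, fixed_beta, varC)
    Sigma <- .sem_implied(M$B, M$Psi)
    .sem_fml(Sigma, S)
  }

  closed_form <- model$beta == "free" && model$variances == "unequal" &&
    nrow(model$sib) == 0
  if (closed_form || layout$n_par == 0) {
    theta <- theta0
    converged <- TRUE
  } else {
    opt <- optim(theta0, obj, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-12))
    theta <- opt$par
    converged <- opt$convergence == 0
    if (!converged) {
      gr <- max(abs(numDeriv_grad(obj, theta)))
      warning(sprintf("SEM fit did not converge (gradient inf-norm %.3g)", gr))
    }
  }

  M <- .sem_matrices(theta, model, layout, fixed_beta, varC)
  Sigma <- .sem_implied(M$B, M$Psi)
  F_ML <- .sem_fml(Sigma, S)
  d <- p + 1L
  logL <- -(n / 2) * (determinant(Sigma)$modulus[1] +
                      sum(solve(Sigma) * S) + d * log(2 * pi))
  t_par <- layout$n_par
  moments <- p * (p + 1) / 2 + p   # gene-gene moments + C-gene covariances
  df <- moments - t_par
  # SRMR over all unique moments of (C, Y), diagonal included
  sds <- sqrt(diag(S))
  res <- (S - Sigma) / tcrossprod(sds)
  SRMR <- sqrt(mean(res[upper.tri(res, diag = TRUE)]^2))

  nm <- c(paste0("bC_", model$genes),
          if (model$beta == "free")
            paste0("b_", model$arcs$child, "~", model$arcs$parent)
          else if (model$beta == "two") c("b_pos", "b_neg"),
          if (model$variances == "equal") "log_psi"
          else paste0("log_psi_", model$genes),
          if (nrow(model$sib) > 0)
            paste0("psi_", model$sib$g1, ":", model$sib$g2))
  names(theta) <- nm

  structure(list(model = model, estimates = theta, layout = layout,
                 fixed_beta = fixed_beta,
                 B = M$B, Psi = M$Psi, Sigma = Sigma, S = S,
                 F_ML = F_ML, logL = as.numeric(logL), LRT = n * F_ML,
                 df = df, t = t_par,
                 AIC = -2 * as.numeric(logL) + 2 * t_par,
                 BIC = -2 * as.numeric(logL) + t_par * log(n),
                 SRMR = SRMR, n = n, ridge = ridge, converged = converged),
            class = "sem_fit")
}

# small forward-difference gradient (diagnostic only)
numDeriv_grad <- function(f, x, eps = 1e-6) {
  f0 <- f(x)
  vapply(seq_along(x), function(i) {
    xi <- x; xi[i] <- xi[i] + eps
    (f(xi) - f0) / eps
  }, 0)
}

#' @export
print.sem_fit <- function(x, ...) {
  cat(sprintf(
    "sem_fit: %d genes | beta=%s var=%s cov=%s | t=%d df=%d\n  F_ML=%.6g LRT=%.2f AIC=%.2f BIC=%.2f SRMR=%.4f%s\n",
    length(x$model$genes), x$model$beta, x$model$variances,
    x$model$covariances, x$t, x$df, x$F_ML, x$LRT, x$AIC, x$BIC, x$SRMR,
    if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Bootstrap significance of SEM parameters
#'
#' Resamples cases and controls separately (stratified, with replacement),
#' refits, and forms t = MLE / bootstrap-SE with a two-sided normal p-value
#' per free parameter. A gene is flagged perturbed when its group coefficient
#' `beta_jC` has p < 0.05.
#'
#' @param model a `sem_model`.
#' @param scores a [gene_score_matrix].
#' @param B number of resamples (warn below 1000, error below... none; warn
#'   below 100).
#' @param seed RNG seed; fixed seed gives a bit-identical table.
#' @return list with `parameters` (data.frame: parameter, estimate, boot_se,
#'   t, p), `genes` (data.frame: gene, beta_C, boot_se, t, p, perturbed),
#'   `n_failed` resamples, and the point `fit`.
#' @export
bootstrap_significance <- function(model, scores, B = 1000, seed = 1) {
  if (B < 100) warning("B < 100 resamples is unreliable")
  else if (B < 1000) message("note: B below the conventional 1000 resamples")
  fit <- fit_sem(model, scores)
  idx0 <- which(scores$group == 0L)
  idx1 <- which(scores$group == 1L)
  set.seed(seed)
  est <- matrix(NA_real_, nrow = B, ncol = length(fit$estimates))
  n_failed <- 0
  for (b in seq_len(B)) {
    take <- c(sample(idx0, length(idx0), replace = TRUE),
              sample(idx1, length(idx1), replace = TRUE))
    bs <- gene_score_matrix(scores$scores[take, , drop = FALSE],
                            scores$group[take])
    fb <- tryCatch(suppressWarnings(fit_sem(model, bs)),
                   error = function(e) NULL)
    if (is.null(fb) || !fb$converged) { n_failed <- n_failed + 1; next }
    est[b, ] <- fb$estimates
  }
  if (n_failed > 0.05 * B)
    warning(sprintf("%d/%d bootstrap refits failed", n_failed, B))
  se <- apply(est, 2, sd, na.rm = TRUE)
  tval <- fit$estimates / se
  pval <- 2 * pnorm(-abs(tval))
  pars <- data.frame(parameter = names(fit$estimates),
                     estimate = unname(fit$estimates),
                     boot_se = se, t = tval, p = pval,
                     row.names = NULL)
  gid <- fit$layout$bC
  genes <- data.frame(gene = model$genes,
                      beta_C = unname(fit$estimates[gid]),
                      boot_se = se[gid], t = tval[gid], p = pval[gid],
                      perturbed = pval[gid] < 0.05,
                      row.names = NULL)
  list(parameters = pars, genes = genes, n_failed = n_failed, fit = fit,
       B = B, seed = seed)
}

#' Select the best SEM fit by AIC
#'
#' Returns the minimum-AIC fit among converged candidates; acceptability is
#' flagged by SRMR < 0.05; AIC ties break on the smaller parameter count t.
#'
#' @param fits list of `sem_fit` objects.
#' @return the selected `sem_fit`, with `$acceptable` (SRMR < 0.05) set.
#' @export
select_model <- function(fits) {
  conv <- Filter(function(f) isTRUE(f$converged), fits)
  if (length(conv) == 0) stop("no fit converged")
  aic <- vapply(conv, `[[`, 0, "AIC")
  tt <- vapply(conv, `[[`, 0, "t")
  best <- order(aic, tt)[1]
  out <- conv[[best]]
  out$acceptable <- out$SRMR < 0.05
  if (!out$acceptable)
    message(sprintf("selected model has SRMR %.3f >= 0.05 (flagged unacceptable)",
                    out$SRMR))
  out
}

#' The seven standard constraint variants
#'
#' Convenience list of the constraint combinations explored for model
#' selection: zero vs bow-free covariances, equal vs unequal variances, and
#' the four gene-gene beta modes.
#' @return data.frame with columns `beta`, `variances`, `covariances`.
#' @export
sem_variants <- function() {
  data.frame(
    beta       = c("ade",  "ade",     "ade",     "two",     "fixed",   "fixed",   "free"),
    variances  = c("equal", "equal",  "unequal", "equal",   "equal",   "unequal", "equal"),
    covariances = c("zero", "bowfree", "bowfree", "bowfree", "bowfree", "bowfree", "bowfree"),
    stringsAsFactors = FALSE)
}
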