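test_that("tree conversion builds the expected equations and siblings", {
  chain <- make_tree(c("a", "b"), c("b", "c"))
  m <- tree_to_sem(chain, beta = "free", covariances = "bowfree")
  expect_equal(m$genes[1], "a")                   # topological order
  expect_equal(nrow(m$arcs), 2)
  expect_equal(nrow(m$sib), 0)                    # single target
  expect_equal(m$exogenous, "a")

  fork <- make_tree(c("a", "a"), c("b", "c"))
  mf <- tree_to_sem(fork, beta = "free", covariances = "bowfree")
  expect_equal(nrow(mf$sib), 1)
  expect_setequal(unlist(mf$sib[1, ]), c("b", "c"))
  mz <- tree_to_sem(fork, beta = "free", covariances = "zero")
  expect_equal(nrow(mz$sib), 0)
})

test_that("saturated models fit perfectly: F_ML = SRMR = LRT = 0", {
  set.seed(41)
  # fork with free betas, unequal variances and the (b, c) covariance has
  # as many parameters as moments
  fork <- make_tree(c("a", "a"), c("b", "c"))
  Y <- matrix(rnorm(300 * 3), 300, 3, dimnames = list(NULL, c("a", "b", "c")))
  gsm <- gene_score_matrix(Y, rep(0:1, 150))
  m <- tree_to_sem(fork, beta = "free", variances = "unequal",
                   covariances = "bowfree")
  f <- fit_sem(m, gsm)
  expect_equal(f$df, 0)
  expect_lt(f$F_ML, 1e-8)
  expect_lt(f$SRMR, 1e-4)
  expect_lt(abs(f$LRT), 1e-5)
})

test_that("ML equals per-equation OLS for recursive zero-covariance models", {
  gsm <- chain_scores(250, seed = 42)
  chain <- make_tree(c("y1", "y2"), c("y2", "y3"))
  m <- tree_to_sem(chain, beta = "free", variances = "unequal",
                   covariances = "zero")
  f <- fit_sem(m, gsm)
  C <- gsm$group
  ols1 <- lm(gsm$scores[, "y1"] ~ C)
  ols2 <- lm(gsm$scores[, "y2"] ~ C + gsm$scores[, "y1"])
  ols3 <- lm(gsm$scores[, "y3"] ~ C + gsm$scores[, "y2"])
  est <- f$estimates
  expect_equal(unname(est["bC_y1"]), unname(coef(ols1)[2]), tolerance = 1e-6)
  expect_equal(unname(est["bC_y2"]), unname(coef(ols2)[2]), tolerance = 1e-6)
  expect_equal(unname(est["bC_y3"]), unname(coef(ols3)[2]), tolerance = 1e-6)
  expect_equal(unname(est["b_y2~y1"]), unname(coef(ols2)[3]), tolerance = 1e-6)
  expect_equal(unname(est["b_y3~y2"]), unname(coef(ols3)[3]), tolerance = 1e-6)
})

test_that("information criteria are consistent with logL and t", {
  gsm <- chain_scores(150, seed = 43)
  chain <- make_tree(c("y1", "y2"), c("y2", "y3"))
  for (v in c("equal", "unequal")) {
    f <- fit_sem(tree_to_sem(chain, beta = "free", variances = v,
                             covariances = "zero"), gsm)
    expect_equal(f$AIC, -2 * f$logL + 2 * f$t, tolerance = 1e-9)
    expect_equal(f$BIC, -2 * f$logL + f$t * log(f$n), tolerance = 1e-9)
    expect_gte(f$df, 0)
    expect_gte(f$F_ML, -1e-12)
  }
})

test_that("ADE fixes betas at the group-weighted within-group OLS slope", {
  gsm <- chain_scores(200, seed = 44)
  chain <- make_tree(c("y1", "y2"), c("y2", "y3"))
  m <- tree_to_sem(chain, beta = "ade", variances = "unequal",
                   covariances = "zero")
  f <- fit_sem(m, gsm)
  C <- gsm$group; Y <- gsm$scores
  for (i in 1:2) {
    pa <- m$arcs$parent[i]; ch <- m$arcs$child[i]
    s0 <- coef(lm(Y[C == 0, ch] ~ Y[C == 0, pa]))[2]
    s1 <- coef(lm(Y[C == 1, ch] ~ Y[C == 1, pa]))[2]
    ade <- unname(mean(C == 0) * s0 + mean(C == 1) * s1)
    gi <- which(colnames(f$S) == ch)
    pi_ <- which(colnames(f$S) == pa)
    expect_equal(f$B[gi, pi_], ade, tolerance = 1e-9)
  }
})

test_that("parameter recovery improves with n and stays within 3 SE", {
  truth_bC <- c(0.8, 0.4, 0.3); truth_bE <- c(0.5, 0.5)
  gsm <- chain_scores(1000, bC = truth_bC, bE = truth_bE, seed = 45)
  chain <- make_tree(c("y1", "y2"), c("y2", "y3"))
  f <- fit_sem(tree_to_sem(chain, beta = "free", variances = "unequal",
                           covariances = "zero"), gsm)
  est <- f$estimates
  expect_lt(max(abs(est[paste0("bC_", c("y1", "y2", "y3"))] - truth_bC)), 0.1)
  expect_lt(max(abs(est[c("b_y2~y1", "b_y3~y2")] - truth_bE)), 0.08)
})

test_that("bootstrap tables are deterministic and flag planted effects", {
  gsm <- chain_scores(120, seed = 46)
  chain <- make_tree(c("y1", "y2"), c("y2", "y3"))
  m <- tree_to_sem(chain, beta = "free", variances = "unequal",
                   covariances = "zero")
  b1 <- suppressWarnings(bootstrap_significance(m, gsm, B = 60, seed = 5))
  b2 <- suppressWarnings(bootstrap_significance(m, gsm, B = 60, seed = 5))
  expect_identical(b1$genes, b2$genes)
  expect_identical(b1$parameters, b2$parameters)
  # the planted group effect on y1 (0.8 at n = 240) must be flagged
  expect_true(b1$genes$perturbed[b1$genes$gene == "y1"])
})

test_that("model selection follows AIC with the SRMR acceptability flag", {
  f1 <- structure(list(AIC = -10, t = 5, SRMR = 0.01, converged = TRUE),
                  class = "sem_fit")
  f2 <- structure(list(AIC = -12, t = 9, SRMR = 0.06, converged = TRUE),
                  class = "sem_fit")
  f3 <- structure(list(AIC = -12, t = 4, SRMR = 0.02, converged = TRUE),
                  class = "sem_fit")
  sel <- suppressMessages(select_model(list(f1, f2)))
  expect_equal(sel$AIC, -12)
  expect_false(sel$acceptable)          # selected but flagged
  sel2 <- select_model(list(f2, f3))    # tie on AIC: smaller t wins
  expect_equal(sel2$t, 4)
  expect_error(select_model(list(structure(list(converged = FALSE),
                                           class = "sem_fit"))),
               "no fit converged")
})
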