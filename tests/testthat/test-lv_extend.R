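# generative fork with two extra disconnected targets whose disturbances may
# share a latent factor: a -> b, a -> c, plus isolated d, e reached from a
fork_latent_scores <- function(n_per_group, r_latent = 0, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  C <- rep(c(0L, 1L), each = n_per_group)
  a <- 0.5 * C + rnorm(n)
  f <- rnorm(n)                                # shared factor for (b, c)
  lam <- sqrt(r_latent)
  b <- 0.4 * a + lam * f + sqrt(1 - r_latent) * rnorm(n)
  cc <- 0.3 * a + lam * f + sqrt(1 - r_latent) * rnorm(n)
  d <- 0.2 * a + rnorm(n)
  gene_score_matrix(cbind(a = a, b = b, c = cc, d = d), C)
}

fork_tree <- make_tree(c("a", "a", "a"), c("b", "c", "d"))

test_that("screening reproduces the lm-residual atanh oracle", {
  gsm <- fork_latent_scores(150, r_latent = 0.25, seed = 51)
  m <- tree_to_sem(fork_tree, beta = "free", variances = "unequal",
                   covariances = "zero")
  f <- fit_sem(m, gsm)
  sc <- screen_covariances(f, fork_tree, gsm)
  expect_equal(nrow(sc), 3)                    # pairs among b, c, d

  # oracle: per-equation lm residuals, cor, atanh, z * sqrt(n - 3)
  C <- gsm$group; Y <- gsm$scores
  res <- sapply(c("b", "c", "d"), function(g)
    resid(lm(Y[, g] ~ C + Y[, "a"])))
  n <- nrow(Y)
  for (r in seq_len(nrow(sc))) {
    rr <- cor(res[, sc$g1[r]], res[, sc$g2[r]])
    expect_equal(sc$r[r], rr, tolerance = 1e-6)
    expect_equal(sc$t[r], atanh(rr) * sqrt(n - 3), tolerance = 1e-5)
  }
  # the closed-form threshold case: r = 0.2, n = 103 gives t just above 2
  expect_equal(atanh(0.2) * sqrt(103 - 3), 2.0273, tolerance = 1e-4)
  expect_equal(sc$selected, abs(sc$t) > 2)
})

test_that("the planted latent pair dominates the screen", {
  hits <- 0
  for (sd in 1:10) {
    gsm <- fork_latent_scores(300, r_latent = 0.3, seed = 100 + sd)
    f <- fit_sem(tree_to_sem(fork_tree, beta = "free",
                             variances = "unequal", covariances = "zero"),
                 gsm)
    sc <- screen_covariances(f, fork_tree, gsm)
    if (sc$g1[1] == "b" && sc$g2[1] == "c") hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("LV model recovers planted parameters and judges fit sensibly", {
  # data generated from the LV model itself
  set.seed(52)
  n <- 400
  C <- rep(c(0L, 1L), each = n / 2)
  LV <- 0.6 * C + rnorm(n)
  yj <- LV + rnorm(n)
  yk <- 0.8 * LV + rnorm(n)
  gsm <- gene_score_matrix(cbind(gj = yj, gk = yk), C)
  f <- fit_lv_model(list(g1 = "gj", g2 = "gk"), gsm, B = 100, seed = 3)
  expect_true(f$converged)
  expect_lt(abs(f$gamma - 0.6), 2 * f$gamma_se)
  expect_lt(abs(f$lambda - 0.8), 0.25)   # ~3 sampling SEs at n = 400
  expect_gte(f$p_LRT, 0.05)                   # the true model fits
  expect_true(f$perturbed)

  # independent targets: gamma should not be significant
  set.seed(53)
  gsm0 <- gene_score_matrix(cbind(gj = rnorm(n), gk = rnorm(n)), C)
  f0 <- fit_lv_model(list(g1 = "gj", g2 = "gk"), gsm0, B = 100, seed = 3)
  expect_gt(f0$gamma_p, 0.05)
})

test_that("near-identical targets collapse to loading 1", {
  set.seed(54)
  n <- 200
  C <- rep(0:1, n / 2)
  base <- 0.5 * C + rnorm(n)
  # numerically near-identical columns (exactly equal S would be singular)
  gsm <- gene_score_matrix(cbind(gj = base, gk = base + 1e-4 * rnorm(n)), C)
  f <- fit_lv_model(list(g1 = "gj", g2 = "gk"), gsm, B = 50, seed = 2)
  expect_equal(f$lambda, 1, tolerance = 1e-2)
  expect_true(f$heywood)                      # residuals hit the boundary
})

test_that("augmentation arithmetic is purely additive", {
  lvs <- list(make_lv_stub("b", "c"))
  dn <- augment_network(fork_tree, lvs)
  expect_equal(igraph::vcount(dn$graph), 4 + 1)
  expect_equal(igraph::ecount(dn$graph), 3 + 2)
  # tree arcs unchanged inside the network
  el <- igraph::as_edgelist(dn$graph)
  tree_arcs <- paste(el[, 1], el[, 2])[igraph::E(dn$graph)$tag != "lv"]
  el0 <- igraph::as_edgelist(fork_tree$graph)
  expect_setequal(tree_arcs, paste(el0[, 1], el0[, 2]))

  # zero pairs: network identical to the tree
  dn0 <- augment_network(fork_tree, list())
  expect_equal(igraph::vcount(dn0$graph), igraph::vcount(fork_tree$graph))
  expect_equal(igraph::ecount(dn0$graph), igraph::ecount(fork_tree$graph))
})

test_that("null pairs are selected at roughly the |t| > 2 rate", {
  sel <- 0; tot <- 0
  for (sd in 1:40) {
    gsm <- fork_latent_scores(150, r_latent = 0, seed = 200 + sd)
    f <- fit_sem(tree_to_sem(fork_tree, beta = "free",
                             variances = "unequal", covariances = "zero"),
                 gsm)
    sc <- screen_covariances(f, fork_tree, gsm)
    sel <- sel + sum(sc$selected); tot <- tot + nrow(sc)
  }
  expect_gt(sel / tot, 0.01)
  expect_lt(sel / tot, 0.10)
})
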