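test_that("Fisher path combination matches the chi-square oracle", {
  # single arc s -> t with p = 0.01: Fisher on one p is the identity
  w1 <- 1 / (-log(0.01))
  wnet <- make_wnet("s", "t", w1, seeds = c("s", "t"))
  pp <- seed_shortest_paths(wnet, c("s", "t"))
  expect_equal(pp$fisher_chi2, -2 * log(0.01), tolerance = 1e-10)  # 9.21
  expect_equal(pp$fisher_df, 2L)
  expect_equal(pp$path_p, 0.01, tolerance = 1e-10)

  # two-edge path with p = {0.05, 0.05}
  w05 <- 1 / (-log(0.05))
  wnet2 <- make_wnet(c("s", "m"), c("m", "t"), c(w05, w05),
                     seeds = c("s", "t"))
  pp2 <- seed_shortest_paths(wnet2, c("s", "t"))
  chi2 <- -2 * (log(0.05) + log(0.05))
  expect_equal(pp2$fisher_chi2, chi2, tolerance = 1e-10)           # 11.98
  expect_equal(pp2$fisher_df, 4L)
  expect_equal(pp2$path_p, pchisq(chi2, 4, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(pp2$path_p, 0.0175, tolerance = 2e-3)
})

test_that("shortest paths match exhaustive simple-path enumeration", {
  set.seed(21)
  nodes <- letters[1:8]
  from <- c(); to <- c()
  for (i in 1:8) for (j in 1:8) {
    if (i != j && runif(1) < 0.35) { from <- c(from, nodes[i]); to <- c(to, nodes[j]) }
  }
  w <- round(runif(length(from), 0.05, 1.5), 3)
  terms <- c("a", "d", "g")
  wnet <- make_wnet(from, to, w, seeds = terms)
  pp <- seed_shortest_paths(wnet, terms, alpha = 1)
  for (r in seq_len(nrow(pp))) {
    paths <- oracle_all_paths(from, to, pp$s[r], pp$t[r])
    wts <- vapply(paths, path_weight, 0, from = from, to = to, w = w)
    expect_equal(pp$dist[r], min(wts), tolerance = 1e-12)
  }
  # pairs absent from the table really are unreachable
  missing_pairs <- setdiff(
    apply(expand.grid(terms, terms), 1, paste, collapse = " "),
    c(paste(pp$s, pp$t), paste(terms, terms)))
  for (mp in missing_pairs) {
    st <- strsplit(mp, " ")[[1]]
    expect_length(oracle_all_paths(from, to, st[1], st[2]), 0)
  }
})

test_that("a significant terminal-to-terminal path is returned verbatim", {
  w <- rep(1 / (-log(1e-4)), 3)       # strongly significant chain
  wnet <- make_wnet(c("a", "b", "c"), c("b", "c", "d"), w,
                    seeds = c("a", "d"))
  tr <- steiner_tree(wnet, c("a", "d"))
  expect_equal(igraph::vcount(tr$graph), 4)
  expect_equal(igraph::ecount(tr$graph), 3)
  el <- igraph::as_edgelist(tr$graph)
  expect_setequal(paste(el[, 1], el[, 2]), c("a b", "b c", "c d"))
  roles <- classify_roles(tr)
  expect_equal(roles$n[roles$role == "source"], 1)
  expect_equal(roles$n[roles$role == "connector"], 2)
  expect_equal(roles$n[roles$role == "target"], 1)
})

test_that("SPH tree meets the Kou bound and hits the optimum on fixtures", {
  # constructed 7-node fixture: cheap spine, expensive decoys
  from <- c("t1", "m1", "m2", "t1", "t2", "x1", "x2", "t3")
  to   <- c("m1", "m2", "t2", "x1", "x2", "t3", "t3", "m1")
  w    <- c(0.05, 0.05, 0.05, 0.9, 0.9, 0.9, 0.08, 0.05)
  terms <- c("t1", "t2", "t3")
  wnet <- make_wnet(from, to, w, seeds = terms)
  tr <- steiner_tree(wnet, terms, alpha = 1)
  opt <- oracle_exact_steiner(from, to, w, terms)
  expect_lte(tr$total_weight, 2 * opt + 1e-9)
  expect_equal(tr$total_weight, opt, tolerance = 1e-9)

  # random enumerable fixtures: 2x guarantee holds on every one
  for (sd in 1:5) {
    set.seed(sd)
    nn <- 9
    nodes <- paste0("v", 1:nn)
    pairs <- t(combn(nodes, 2))
    on <- runif(nrow(pairs)) < 0.45
    from2 <- pairs[on, 1]; to2 <- pairs[on, 2]
    # make every edge bidirectional so the closure is well connected
    f <- c(from2, to2); t2 <- c(to2, from2)
    w2 <- rep(round(runif(sum(on), 0.05, 1), 3), 2)
    terms2 <- sample(nodes, 3)
    wnet2 <- make_wnet(f, t2, w2, seeds = terms2)
    tr2 <- tryCatch(steiner_tree(wnet2, terms2, alpha = 1),
                    error = function(e) NULL)
    if (is.null(tr2)) next
    opt2 <- oracle_exact_steiner(f, t2, w2, terms2)
    expect_lte(tr2$total_weight, 2 * opt2 + 1e-9)
  }
})

test_that("tree structure invariants hold on simulated fixtures", {
  for (sd in c(1, 4, 5)) {
    spec <- simulation_spec(seed = sd)
    net <- suppressWarnings(simulate_interactome(spec))
    scores <- simulate_scores(net, spec)
    wnet <- weight_network(scores, net)
    tr <- suppressWarnings(steiner_tree(wnet, net$seeds_given))
    g <- tr$graph
    # forest: |edges| = |nodes| - #components; connected case is the tree rule
    expect_equal(igraph::ecount(g), igraph::vcount(g) - tr$n_components)
    # every undirected leaf is a terminal
    und_deg <- igraph::degree(g, mode = "all")
    leaves <- igraph::V(g)$name[und_deg == 1]
    expect_true(all(leaves %in% tr$terminals))
    # role partition is exhaustive and disjoint
    roles <- igraph::V(g)$role
    expect_true(all(roles %in% c("source", "connector", "target")))
    expect_equal(sum(classify_roles(tr)$n), igraph::vcount(g))
    indeg <- igraph::degree(g, mode = "in")
    outdeg <- igraph::degree(g, mode = "out")
    expect_true(all(indeg[roles == "source"] == 0))
    expect_true(all(outdeg[roles == "target"] == 0))
    expect_true(all(indeg[roles == "connector"] > 0 &
                    outdeg[roles == "connector"] > 0))
  }
})

test_that("role classification handles chains and stars", {
  chain <- make_tree(c("a", "b"), c("b", "c"))
  rc <- classify_roles(chain)
  expect_equal(rc$n, c(1, 1, 1))
  star <- make_tree(rep("hub", 3), c("l1", "l2", "l3"))
  rs <- classify_roles(star)
  expect_equal(rs$n[rs$role == "source"], 1)
  expect_equal(rs$n[rs$role == "target"], 3)
  expect_equal(rs$n[rs$role == "connector"], 0)
})

test_that("filtering is monotone in alpha and output is deterministic", {
  set.seed(31)
  gsm <- null_scores(150, sprintf("g%02d", 1:15), seed = 31)
  net <- suppressWarnings(simulate_interactome(
    simulation_spec(n_nodes = 15, density = 0.25, seed = 31,
                    n_seeds = 5, route_length = 4)))
  scores <- simulate_scores(net, simulation_spec(n_nodes = 15, seed = 31))
  wnet <- weight_network(scores, net)
  pp_hi <- seed_shortest_paths(wnet, net$seeds_given, alpha = 0.05)
  pp_lo <- seed_shortest_paths(wnet, net$seeds_given, alpha = 0.01)
  sig_hi <- paste(pp_hi$s, pp_hi$t)[pp_hi$significant]
  sig_lo <- paste(pp_lo$s, pp_lo$t)[pp_lo$significant]
  expect_true(all(sig_lo %in% sig_hi))

  t1 <- suppressWarnings(steiner_tree(wnet, net$seeds_given))
  t2 <- suppressWarnings(steiner_tree(wnet, net$seeds_given))
  expect_identical(igraph::as_edgelist(t1$graph),
                   igraph::as_edgelist(t2$graph))
})
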