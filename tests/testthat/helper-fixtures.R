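# Fixture builders and independent brute-force oracles shared across tests.
# Oracles deliberately avoid the package's own code paths: BFS/DFS loops,
# explicit path enumeration, choose() summation, per-equation lm() fits.

# -- fixture builders ---------------------------------------------------------

edges_df <- function(from, to, tag = "directed") {
  data.frame(source = from, target = to, tag = tag, stringsAsFactors = FALSE)
}

# weighted_interactome with prescribed arc weights (p back-derived from w so
# the w = 1/(-ln p) invariant holds exactly)
make_wnet <- function(from, to, w, seeds = character()) {
  net <- interactome(edges_df(from, to), seeds = seeds)
  el <- igraph::as_data_frame(net$graph, what = "edges")
  key_in <- paste(from, to)
  ord <- match(paste(el$from, el$to), key_in)
  w_arc <- w[ord]
  p_arc <- exp(-1 / w_arc)
  g <- net$graph
  igraph::E(g)$w <- w_arc
  igraph::E(g)$p <- p_arc
  igraph::E(g)$perturbed <- p_arc < 0.05
  structure(list(graph = g,
                 edge_table = cbind(el[, c("from", "to")],
                                    p = p_arc, w = w_arc,
                                    perturbed = p_arc < 0.05),
                 n_dropped_arcs = 0L,
                 seeds_given = seeds, seeds_mapped = length(seeds)),
            class = c("weighted_interactome", "interactome"))
}

# steiner_tree object from an explicit arc list (used where a tree of known
# shape is needed without running the heuristic); roles derived from degrees
make_tree <- function(from, to, terminals = unique(c(from, to)),
                      w = rep(0.1, length(from)), p = NULL) {
  if (is.null(p)) p <- exp(-1 / w)
  nodes <- sort(unique(c(from, to)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, tag = "directed", w = w, p = p,
               perturbed = p < 0.05),
    directed = TRUE, vertices = data.frame(name = nodes))
  indeg <- igraph::degree(g, mode = "in")
  outdeg <- igraph::degree(g, mode = "out")
  igraph::V(g)$role <- ifelse(indeg == 0, "source",
                              ifelse(outdeg == 0, "target", "connector"))
  igraph::V(g)$terminal <- as.integer(nodes %in% terminals)
  igraph::V(g)$seed <- as.integer(nodes %in% terminals)
  igraph::V(g)$main_component <- 1L
  structure(list(graph = g, terminals = intersect(terminals, nodes),
                 paths = NULL, n_components = igraph::components(g)$no,
                 total_weight = sum(w)),
            class = "steiner_tree")
}

# a large random directed tree (synthetic stand-in for a cohort-scale tree;
# no real-data counterpart can ship with the package)
make_synthetic_tree <- function(n_nodes, seed = 1) {
  set.seed(seed)
  nodes <- sprintf("n%03d", seq_len(n_nodes))
  parent <- integer(0); child <- integer(0)
  for (i in 2:n_nodes) {
    parent <- c(parent, sample(i - 1, 1))
    child <- c(child, i)
  }
  flip <- runif(n_nodes - 1) < 0.3   # some arcs point rootward
  from <- ifelse(flip, nodes[child], nodes[parent])
  to <- ifelse(flip, nodes[parent], nodes[child])
  make_tree(from, to, terminals = sample(nodes, max(2, n_nodes %/% 2)),
            w = runif(n_nodes - 1, 0.02, 1.5))
}

# minimal lv_fit stand-in for augmentation arithmetic
make_lv_stub <- function(g1, g2) {
  structure(list(g1 = g1, g2 = g2, gamma = 0.5, lambda = 1,
                 phi = 1, theta1 = 1, theta2 = 1,
                 gamma_se = 0.1, gamma_t = 5, gamma_p = 1e-6,
                 F_ML = 0, LRT = 0.5, df = 1L, p_LRT = 0.5,
                 good_fit = TRUE, perturbed = TRUE, heywood = FALSE,
                 converged = TRUE, n = 100L, B = 0L),
            class = "lv_fit")
}

scores_from_matrix <- function(Y, C) gene_score_matrix(Y, C)

# -- independent oracles ------------------------------------------------------

# all-pairs hop distances by plain BFS over an arc list
oracle_bfs_distances <- function(from, to, nodes) {
  adj <- lapply(setNames(nodes, nodes), function(u) to[from == u])
  d <- matrix(Inf, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (s in nodes) {
    d[s, s] <- 0
    queue <- s
    while (length(queue) > 0) {
      u <- queue[1]; queue <- queue[-1]
      for (v in adj[[u]]) {
        if (!is.finite(d[s, v])) {
          d[s, v] <- d[s, u] + 1
          queue <- c(queue, v)
        }
      }
    }
  }
  d
}

# every simple directed path s -> t by DFS (small graphs only)
oracle_all_paths <- function(from, to, s, t, max_len = 12) {
  out <- list()
  walk <- function(path) {
    u <- path[length(path)]
    if (u == t) { out[[length(out) + 1]] <<- path; return(invisible()) }
    if (length(path) > max_len) return(invisible())
    for (v in to[from == u]) {
      if (!(v %in% path)) walk(c(path, v))
    }
  }
  walk(s)
  out
}

path_weight <- function(path, from, to, w) {
  sum(vapply(seq_len(length(path) - 1), function(i) {
    w[which(from == path[i] & to == path[i + 1])[1]]
  }, 0))
}

# exact minimum Steiner weight by enumerating Steiner-node subsets; operates
# on the symmetrised undirected weights (min of the two arc weights)
oracle_exact_steiner <- function(from, to, w, terminals) {
  key <- paste(pmin(from, to), pmax(from, to))
  uw <- tapply(w, key, min)
  ue <- do.call(rbind, strsplit(names(uw), " "))
  nodes <- sort(unique(c(from, to)))
  steiner_cand <- setdiff(nodes, terminals)
  best <- Inf
  for (k in 0:length(steiner_cand)) {
    combs <- if (k == 0) list(character(0)) else
      asplit(combn(steiner_cand, k), 2)
    for (extra in combs) {
      vs <- c(terminals, extra)
      sel <- ue[, 1] %in% vs & ue[, 2] %in% vs
      if (!any(sel)) next
      g <- igraph::graph_from_data_frame(
        data.frame(from = ue[sel, 1], to = ue[sel, 2],
                   weight = as.numeric(uw[sel])),
        directed = FALSE, vertices = data.frame(name = vs))
      if (!igraph::is_connected(g)) next
      mst <- igraph::mst(g)
      tot <- sum(igraph::E(mst)$weight)
      # MST spans all of vs; only count if terminals connected (they are)
      if (tot < best) best <- tot
    }
  }
  best
}

# fractional-count weighted betweenness by explicit path enumeration
oracle_betweenness <- function(from, to, w, nodes) {
  btw <- setNames(rep(0, length(nodes)), nodes)
  for (s in nodes) for (t in nodes) {
    if (s == t) next
    paths <- oracle_all_paths(from, to, s, t)
    if (length(paths) == 0) next
    wts <- vapply(paths, path_weight, 0, from = from, to = to, w = w)
    shortest <- paths[abs(wts - min(wts)) < 1e-12]
    for (p in shortest) {
      inner <- setdiff(p, c(s, t))
      btw[inner] <- btw[inner] + 1 / length(shortest)
    }
  }
  btw
}

# C -> Y1 -> Y2 -> Y3 generative chain
chain_scores <- function(n_per_group, bC = c(0.8, 0.4, 0.3),
                         bE = c(0.5, 0.5), psi = c(1, 1, 1), seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  C <- rep(c(0L, 1L), each = n_per_group)
  y1 <- bC[1] * C + rnorm(n, sd = sqrt(psi[1]))
  y2 <- bC[2] * C + bE[1] * y1 + rnorm(n, sd = sqrt(psi[2]))
  y3 <- bC[3] * C + bE[2] * y2 + rnorm(n, sd = sqrt(psi[3]))
  gene_score_matrix(cbind(y1 = y1, y2 = y2, y3 = y3), C)
}

# random score matrices
null_scores <- function(n_per_group, genes, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  Y <- matrix(rnorm(n * length(genes)), n, length(genes),
              dimnames = list(NULL, genes))
  gene_score_matrix(Y, rep(c(0L, 1L), each = n_per_group))
}
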