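# Steiner-tree extraction of the maximum-perturbance subnetwork.
#
# Shortest paths follow arc directions and minimise total perturbance weight
# sum(w); per-path significance combines the edge p-values by Fisher's method
# and is Bonferroni-corrected over the number of terminal-pair paths found.
# The tree itself follows Kou's shortest-path heuristic: metric closure on the
# terminals (significant paths only), MST of the closure, expansion to the
# concrete directed paths, second MST, and pruning of non-terminal leaves.

# Deterministic Dijkstra from `src` over an out-adjacency representation.
# Ties in the priority queue break on the lexicographically smaller node id;
# equal-distance relaxations keep the lexicographically smaller parent.
# adj: list per node index of list(to = int vector, w = numeric vector)
.dijkstra <- function(adj, n, names_, src) {
  dist <- rep(Inf, n)
  parent <- rep(NA_integer_, n)
  done <- rep(FALSE, n)
  dist[src] <- 0
  repeat {
    cand <- which(!done & is.finite(dist))
    if (length(cand) == 0) break
    u <- cand[order(dist[cand], names_[cand])][1]
    done[u] <- TRUE
    nb <- adj[[u]]
    if (length(nb$to) > 0) {
      for (i in seq_along(nb$to)) {
        v <- nb$to[i]
        nd <- dist[u] + nb$w[i]
        if (nd < dist[v] ||
            (nd == dist[v] && !is.na(parent[v]) &&
             names_[u] < names_[parent[v]])) {
          dist[v] <- nd
          parent[v] <- u
        }
      }
    }
  }
  list(dist = dist, parent = parent)
}

.out_adjacency <- function(g, w) {
  el <- igraph::as_edgelist(g, names = FALSE)
  n <- igraph::vcount(g)
  adj <- rep(list(list(to = integer(0), w = numeric(0))), n)
  for (u in unique(el[, 1])) {
    idx <- which(el[, 1] == u)
    adj[[u]] <- list(to = el[idx, 2], w = w[idx])
  }
  adj
}

.trace_path <- function(parent, src, dst) {
  path <- dst
  while (path[1] != src) {
    p <- parent[path[1]]
    if (is.na(p)) return(NULL)
    path <- c(p, path)
  }
  path
}

#' Directed shortest paths between all ordered seed pairs
#'
#' For every ordered pair of mapped terminals, the w-weighted directed
#' shortest path (deterministic Dijkstra), its Fisher-combined significance
#' `chi2 = -2 * sum(ln p_i)` on `2 * m` degrees of freedom, and a Bonferroni
#' flag `path_p < alpha / N_paths` where `N_paths` is the number of
#' finite-distance ordered pairs found.
#'
#' @param wnet a `weighted_interactome`.
#' @param terminals character vector of terminal (seed) gene ids.
#' @param alpha significance level before Bonferroni correction.
#' @return data.frame, one row per connected ordered pair: `s`, `t`, `dist`,
#'   `n_edges`, `fisher_chi2`, `fisher_df`, `path_p`, `significant`, and a
#'   list-column `path` of node-id vectors. Attribute `n_paths` holds the
#'   Bonferroni denominator.
#' @export
seed_shortest_paths <- function(wnet, terminals, alpha = 0.05) {
  g <- wnet$graph
  names_ <- igraph::V(g)$name
  terminals <- intersect(sort(unique(terminals)), names_)
  if (length(terminals) < 2) stop("need at least 2 mapped terminals")
  w <- igraph::E(g)$w
  p <- igraph::E(g)$p
  n <- igraph::vcount(g)
  adj <- .out_adjacency(g, w)
  tidx <- match(terminals, names_)
  # edge p lookup by "from\rto"
  el <- igraph::as_edgelist(g, names = FALSE)
  pmap <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(nrow(el)))
    assign(paste(el[i, 1], el[i, 2]), p[i], envir = pmap)

  rows <- list()
  for (s in tidx) {
    dj <- .dijkstra(adj, n, names_, s)
    for (t in setdiff(tidx, s)) {
      if (!is.finite(dj$dist[t])) next
      path <- .trace_path(dj$parent, s, t)
      if (is.null(path)) next
      pe <- vapply(seq_len(length(path) - 1), function(i) {
        get(paste(path[i], path[i + 1]), envir = pmap)
      }, 0)
      chi2 <- -2 * sum(log(pe))
      df <- 2L * length(pe)
      rows[[length(rows) + 1L]] <- list(
        s = names_[s], t = names_[t], dist = dj$dist[t],
        n_edges = length(pe), fisher_chi2 = chi2, fisher_df = df,
        path_p = pchisq(chi2, df, lower.tail = FALSE),
        path = names_[path])
    }
  }
  if (length(rows) == 0) stop("no terminal pair is connected")
  out <- data.frame(
    s = vapply(rows, `[[`, "", "s"),
    t = vapply(rows, `[[`, "", "t"),
    dist = vapply(rows, `[[`, 0, "dist"),
    n_edges = vapply(rows, `[[`, 0L, "n_edges"),
    fisher_chi2 = vapply(rows, `[[`, 0, "fisher_chi2"),
    fisher_df = vapply(rows, `[[`, 0L, "fisher_df"),
    path_p = vapply(rows, `[[`, 0, "path_p"),
    stringsAsFactors = FALSE)
  out$significant <- out$path_p < alpha / nrow(out)
  out$path <- I(lapply(rows, `[[`, "path"))
  attr(out, "n_paths") <- nrow(out)
  out
}

# undirected MST edge list via igraph, deterministic under fixed input order
.mst_edges <- function(edges_df) {
  # edges_df: from, to, weight (undirected); returns the selected rows
  edges_df <- edges_df[order(edges_df$weight, edges_df$from, edges_df$to), ]
  nodes <- sort(unique(c(edges_df$from, edges_df$to)))
  comp <- setNames(seq_along(nodes), nodes)  # union-find, path halving
  find <- function(x) {
    while (comp[[x]] != comp[[nodes[comp[[x]]]]]) comp[[x]] <<- comp[[nodes[comp[[x]]]]]
    comp[[x]]
  }
  keep <- logical(nrow(edges_df))
  for (i in seq_len(nrow(edges_df))) {
    ra <- find(edges_df$from[i]); rb <- find(edges_df$to[i])
    if (ra != rb) {
      comp[comp == rb] <- ra
      keep[i] <- TRUE
    }
  }
  edges_df[keep, , drop = FALSE]
}

#' Steiner tree by the shortest-path heuristic over significant paths
#'
#' Kou-style construction restricted to Bonferroni-significant terminal-pair
#' paths: (1) metric closure on the terminals (symmetrised distance: when both
#' directions are significant the cheaper path is used); (2) MST of the
#' closure; (3) expansion of closure edges to their concrete directed paths;
#' (4) MST of the expanded subgraph on w; (5) iterative pruning of
#' non-terminal leaves. Node roles (`source` / `connector` / `target`) come
#' from in/out-degrees on the final directed subgraph. If the filtered closure
#' is disconnected a spanning forest is returned with a warning; nodes carry a
#' `main_component` flag for the largest component.
#'
#' @param wnet a `weighted_interactome`.
#' @param terminals character vector of terminal gene ids.
#' @param alpha level for the Bonferroni path filter.
#' @return object of class `steiner_tree`: igraph directed graph with vertex
#'   attributes `role`, `terminal`, `seed`, `main_component` and inherited
#'   per-arc perturbance attributes; plus `terminals`, `paths` (the path
#'   table) and `n_components`.
#' @export
steiner_tree <- function(wnet, terminals, alpha = 0.05) {
  paths <- seed_shortest_paths(wnet, terminals, alpha)
  sig <- paths[paths$significant, , drop = FALSE]
  if (nrow(sig) == 0) stop("no significant path survives Bonferroni filtering")

  # (1) metric closure on terminals, unordered pairs, cheaper direction wins
  key <- ifelse(sig$s < sig$t, paste(sig$s, sig$t), paste(sig$t, sig$s))
  best <- vapply(split(seq_len(nrow(sig)), key), function(idx) {
    idx[order(sig$dist[idx], sig$s[idx])][1]
  }, 0L)
  closure <- data.frame(
    from = pmin(sig$s[best], sig$t[best]),
    to = pmax(sig$s[best], sig$t[best]),
    weight = sig$dist[best],
    path_row = best,
    stringsAsFactors = FALSE)

  # (2) MST of the closure (spanning forest if disconnected)
  mst1 <- .mst_edges(closure)
  n_comp_terms <- length(unique(c(closure$from, closure$to))) - nrow(mst1)
  if (n_comp_terms > 1)
    warning(sprintf("significant-path closure is disconnected (%d components); returning a forest",
                    n_comp_terms))

  # (3) expand closure MST edges to their concrete directed arcs
  g <- wnet$graph
  arc_keys <- character(0)
  for (r in mst1$path_row) {
    pth <- paths$path[[r]]
    arc_keys <- c(arc_keys,
                  paste(pth[-length(pth)], pth[-1], sep = "\r"))
  }
  arc_keys <- unique(arc_keys)
  el <- igraph::as_edgelist(g, names = TRUE)
  all_keys <- paste(el[, 1], el[, 2], sep = "\r")
  sub_eids <- match(arc_keys, all_keys)
  sub <- igraph::subgraph_from_edges(g, sub_eids, delete.vertices = TRUE)

  # (4) undirected MST of the expanded subgraph on w; when both arcs of a
  # node pair are present the cheaper carries the undirected edge
  sel <- igraph::as_data_frame(sub, what = "edges")
  und_key <- ifelse(sel$from < sel$to, paste(sel$from, sel$to),
                    paste(sel$to, sel$from))
  pick <- vapply(split(seq_len(nrow(sel)), und_key), function(idx) {
    idx[order(sel$w[idx], sel$from[idx])][1]
  }, 0L)
  und <- data.frame(from = pmin(sel$from[pick], sel$to[pick]),
                    to = pmax(sel$from[pick], sel$to[pick]),
                    weight = sel$w[pick], arc_row = pick,
                    stringsAsFactors = FALSE)
  mst2 <- .mst_edges(und)

  # (5) prune non-terminal leaves iteratively (on the undirected tree)
  keep_edges <- mst2
  repeat {
    deg <- table(c(keep_edges$from, keep_edges$to))
    leaves <- names(deg)[deg == 1]
    drop <- setdiff(leaves, terminals)
    if (length(drop) == 0) break
    keep_edges <- keep_edges[!(keep_edges$from %in% drop |
                               keep_edges$to %in% drop), , drop = FALSE]
    if (nrow(keep_edges) == 0) break
  }
  if (nrow(keep_edges) == 0) stop("tree pruned to nothing; no usable paths")

  final_arcs <- sel[keep_edges$arc_row, , drop = FALSE]
  tg <- igraph::graph_from_data_frame(
    final_arcs, directed = TRUE,
    vertices = data.frame(name = sort(unique(c(final_arcs$from,
                                               final_arcs$to)))))
  vn <- igraph::V(tg)$name
  indeg <- igraph::degree(tg, mode = "in")
  outdeg <- igraph::degree(tg, mode = "out")
  role <- ifelse(indeg == 0, "source", ifelse(outdeg == 0, "target",
                                              "connector"))
  igraph::V(tg)$role <- role
  igraph::V(tg)$terminal <- as.integer(vn %in% terminals)
  seed_flag <- igraph::V(g)$seed[match(vn, igraph::V(g)$name)]
  igraph::V(tg)$seed <- ifelse(is.na(seed_flag), 0L, seed_flag)
  comp <- igraph::components(tg, mode = "weak")
  igraph::V(tg)$main_component <-
    as.integer(comp$membership == which.max(comp$csize))

  structure(list(graph = tg, terminals = intersect(terminals, vn),
                 paths = paths, n_components = comp$no,
                 total_weight = sum(final_arcs$w)),
            class = "steiner_tree")
}

#' Classify tree nodes into sources, connectors, and targets
#'
#' Sources emit perturbance (in-degree 0), targets absorb it (out-degree 0),
#' connectors transmit it (both degrees positive).
#'
#' @param tree a `steiner_tree` (or `disease_network`, LV nodes excluded).
#' @return data.frame with one row per role: `role`, `n`, `n_seed`.
#' @export
classify_roles <- function(tree) {
  g <- tree$graph
  vv <- data.frame(role = igraph::V(g)$role, seed = igraph::V(g)$seed)
  if (!is.null(igraph::V(g)$lv)) vv <- vv[igraph::V(g)$lv == 0, ]
  out <- do.call(rbind, lapply(c("source", "connector", "target"),
    function(r) data.frame(role = r, n = sum(vv$role == r),
                           n_seed = sum(vv$seed[vv$role == r]))))
  out
}

#' @export
print.steiner_tree <- function(x, ...) {
  g <- x$graph
  cat(sprintf(
    "steiner_tree: %d nodes, %d edges, %d terminals, total weight %.4f%s\n",
    igraph::vcount(g), igraph::ecount(g), length(x$terminals),
    x$total_weight,
    if (x$n_components > 1) sprintf(" (forest, %d components)", x$n_components)
    else ""))
  print(classify_roles(x), row.names = FALSE)
  invisible(x)
}

#' Write a Steiner tree (or disease network) to GraphML plus TSV tables
#' @param tree a `steiner_tree` or `disease_network`.
#' @param graphml_path output GraphML file (optional, NULL to skip).
#' @param nodes_path,edges_path optional TSV outputs.
#' @export
write_tree <- function(tree, graphml_path = NULL, nodes_path = NULL,
                       edges_path = NULL) {
  g <- tree$graph
  if (!is.null(graphml_path))
    igraph::write_graph(g, graphml_path, format = "graphml")
  if (!is.null(nodes_path)) {
    nv <- igraph::as_data_frame(g, what = "vertices")
    write.table(nv, nodes_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(edges_path)) {
    ev <- igraph::as_data_frame(g, what = "edges")
    write.table(ev, edges_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(tree)
}
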