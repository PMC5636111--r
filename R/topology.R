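# Topological characterisation of the disease network: centralities, node
# classes (springs / sinks / hubs / bottlenecks / secondary sources), the
# essential-node subnetwork, and the seed-connectivity randomisation tests.

# gene-only directed graph (LV nodes and their links excluded)
.gene_graph <- function(net) {
  g <- net$graph
  if (!is.null(igraph::V(g)$lv) && any(igraph::V(g)$lv == 1))
    g <- igraph::induced_subgraph(g, which(igraph::V(g)$lv == 0))
  g
}

#' Per-node topological profiles
#'
#' Computes in/out/total degree and weighted betweenness (shortest paths on
#' the perturbance weight w, so the most perturbed routes are the shortest;
#' multiple shortest paths count fractionally), then flags node classes:
#' \itemize{
#' \item spring: source with out-degree strictly above the sources'
#'   upper quartile;
#' \item sink: target with in-degree strictly above the targets' upper
#'   quartile;
#' \item hub: connector with total degree > 3;
#' \item bottleneck: weighted betweenness strictly above the upper quartile;
#' \item essential: degree AND weighted betweenness both strictly above
#'   their upper quartiles;
#' \item secondary_source: a direct target of a source with in-degree 1 and
#'   out-degree 1 (ligand-receptor-like relays).
#' }
#' LV nodes are excluded from the ranking.
#'
#' @param net a `steiner_tree` or `disease_network`.
#' @return data.frame, one row per gene node: `node`, `role`, `seed`,
#'   `in_degree`, `out_degree`, `degree`, `betweenness`, and logical class
#'   flags.
#' @export
node_profiles <- function(net) {
  g <- .gene_graph(net)
  stopifnot(igraph::vcount(g) > 0)
  vn <- igraph::V(g)$name
  indeg <- igraph::degree(g, mode = "in")
  outdeg <- igraph::degree(g, mode = "out")
  deg <- indeg + outdeg
  w <- igraph::E(g)$w
  btw <- igraph::betweenness(g, directed = TRUE,
                             weights = if (is.null(w)) NULL else w)
  role <- igraph::V(g)$role
  if (is.null(role))
    role <- ifelse(indeg == 0, "source",
                   ifelse(outdeg == 0, "target", "connector"))

  q_src <- if (any(role == "source"))
    quantile(outdeg[role == "source"], 0.75, names = FALSE) else Inf
  q_tgt <- if (any(role == "target"))
    quantile(indeg[role == "target"], 0.75, names = FALSE) else Inf
  q_deg <- quantile(deg, 0.75, names = FALSE)
  q_btw <- quantile(btw, 0.75, names = FALSE)

  # direct targets of sources, relaying with exactly one in and one out arc
  el <- igraph::as_edgelist(g, names = TRUE)
  from_source <- el[el[, 1] %in% vn[role == "source"], 2]
  secondary <- vn %in% from_source & indeg == 1 & outdeg == 1

  seed <- igraph::V(g)$seed
  if (is.null(seed)) seed <- rep(0L, length(vn))
  data.frame(
    node = vn, role = role, seed = seed,
    in_degree = indeg, out_degree = outdeg, degree = deg,
    betweenness = btw,
    spring = role == "source" & outdeg > q_src,
    sink = role == "target" & indeg > q_tgt,
    hub = role == "connector" & deg > 3,
    bottleneck = btw > q_btw,
    essential = deg > q_deg & btw > q_btw,
    secondary_source = secondary,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Essential-node subnetwork
#'
#' Induced subgraph on nodes whose degree and weighted betweenness are both
#' strictly above their upper quartiles, keeping perturbance flags.
#'
#' @param profiles output of [node_profiles].
#' @param net the network the profiles were computed on.
#' @return igraph graph (possibly empty).
#' @export
essential_subnetwork <- function(profiles, net) {
  g <- .gene_graph(net)
  stopifnot(igraph::vcount(g) >= 4)
  keep <- profiles$node[profiles$essential]
  igraph::induced_subgraph(g, which(igraph::V(g)$name %in% keep))
}

#' Seed-connectivity randomisation / permutation test
#'
#' Tests whether the seed set is more tightly connected than chance: the
#' observed statistics are the median total degree of the seeds and the mean
#' directed shortest-path distance over reachable ordered seed pairs. The
#' null draws `B` replicates either by sampling |seeds| random nodes
#' (`mode = "sample"`) or by relabelling all nodes with a random permutation
#' and reading off the nodes now carrying seed labels (`mode = "permute"`).
#' Empirical one-sided p-values use the +1 continuity correction:
#' degree p = (1 + #\{null >= obs\}) / (B + 1),
#' distance p = (1 + #\{null <= obs\}) / (B + 1).
#'
#' @param net an [interactome].
#' @param seeds character vector of seed gene ids (>= 2 must map).
#' @param B replicates (warn below 100).
#' @param mode `"sample"` or `"permute"`.
#' @param seed_rng RNG seed.
#' @return list: `observed` (median_degree, mean_distance), `p_degree`,
#'   `p_distance`, `B`, `mode`, `n_seeds`.
#' @export
seed_connectivity_test <- function(net, seeds, B = 1000,
                                   mode = c("sample", "permute"),
                                   seed_rng = 1) {
  mode <- match.arg(mode)
  if (B < 100) warning("B < 100 replicates is unreliable")
  g <- net$graph
  vn <- igraph::V(g)$name
  seeds <- intersect(unique(seeds), vn)
  if (length(seeds) < 2) stop("need at least 2 mapped seeds")
  deg <- igraph::degree(g, mode = "all")
  names(deg) <- vn

  set_stats <- function(set) {
    d <- igraph::distances(g, v = set, to = set, mode = "out")
    diag(d) <- NA
    c(median(deg[set]), mean(d[is.finite(d)]))
  }
  obs <- set_stats(seeds)
  k <- length(seeds)
  set.seed(seed_rng)
  null_deg <- numeric(B); null_dist <- numeric(B)
  for (b in seq_len(B)) {
    set <- if (mode == "sample") {
      sample(vn, k)
    } else {
      perm <- sample(vn)          # node relabelling
      vn[perm %in% seeds]
    }
    st <- set_stats(set)
    null_deg[b] <- st[1]; null_dist[b] <- st[2]
  }
  list(observed = c(median_degree = obs[1], mean_distance = obs[2]),
       p_degree = (1 + sum(null_deg >= obs[1])) / (B + 1),
       p_distance = (1 + sum(null_dist <= obs[2], na.rm = TRUE)) / (B + 1),
       B = B, mode = mode, n_seeds = k)
}
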