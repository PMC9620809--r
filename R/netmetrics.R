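#' All-pairs shortest-path distances on a weighted connectome
#'
#' Edge weights are connection strengths; path lengths use the standard
#' inverse mapping `length = 1 / weight`, so stronger connections are
#' shorter. Unreachable pairs have infinite distance.
#'
#' @param m a `connectivity_matrix` or symmetric nonnegative matrix.
#' @return Symmetric matrix of shortest-path lengths (0 on the diagonal,
#'   `Inf` for disconnected pairs).
#' @export
shortest_path_distances <- function(m) {
  W <- as_weight_matrix(m)
  if (any(W < 0)) stopf("negative edge weights are not allowed")
  n <- nrow(W)
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  d <- igraph::distances(g, weights = 1 / igraph::E(g)$weight,
                         algorithm = "dijkstra")
  dimnames(d) <- dimnames(W)
  d
}

#' Weighted global efficiency
#'
#' `E_glob = 1/(N(N-1)) * sum_{i != j} 1/d(i, j)` with `1/Inf = 0`: the
#' average inverse shortest-path distance over ordered node pairs. On a
#' connectome it measures how well-integrated the whole network is; its
#' scale follows the edge-weight scale (multiplying all weights by c
#' multiplies the efficiency by c).
#'
#' @param m a `connectivity_matrix` or weight matrix.
#' @return Nonnegative scalar; 0 for an edgeless graph.
#' @examples
#' W <- matrix(1, 3, 3) - diag(3)   # complete triangle, unit weights
#' global_efficiency(W)             # 1
#' @export
global_efficiency <- function(m) {
  W <- as_weight_matrix(m)
  n <- nrow(W)
  if (n < 2L) stopf("global efficiency needs at least 2 nodes")
  d <- shortest_path_distances(W)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Weighted local efficiency
#'
#' For each node with at least two neighbors, the global efficiency of
#' the subgraph induced by its neighbors (retaining the original weights,
#' the Latora-Marchiori form); nodes with fewer than two neighbors
#' contribute 0. The value returned is the mean over all nodes — a
#' measure of fault tolerance at the local scale. `variant = "onnela"`
#' instead uses cube-root-transformed weights
#' (`W^(1/3)`) inside the neighborhood, one of the common weighted
#' generalizations.
#'
#' @param m a `connectivity_matrix` or weight matrix.
#' @param variant `"latora"` (default) or `"onnela"`.
#' @return Nonnegative scalar; 0 when no node has two connected neighbors.
#' @export
local_efficiency <- function(m, variant = c("latora", "onnela")) {
  variant <- match.arg(variant)
  W <- as_weight_matrix(m)
  n <- nrow(W)
  if (n < 2L) stopf("local efficiency needs at least 2 nodes")
  Wl <- if (variant == "onnela") W^(1 / 3) else W
  eff <- vapply(seq_len(n), function(i) {
    nb <- which(W[i, ] > 0)
    if (length(nb) < 2L) return(0)
    global_efficiency(Wl[nb, nb, drop = FALSE])
  }, numeric(1))
  mean(eff)
}

#' Summary graph metrics for a connectome
#'
#' @param m a `connectivity_matrix` or weight matrix.
#' @param variant local-efficiency variant, see [local_efficiency()].
#' @return list with `weighted_global_efficiency`,
#'   `weighted_local_efficiency`, `n_nodes`, `n_edges`.
#' @export
graph_metrics <- function(m, variant = "latora") {
  W <- as_weight_matrix(m)
  list(weighted_global_efficiency = global_efficiency(W),
       weighted_local_efficiency = local_efficiency(W, variant = variant),
       n_nodes = nrow(W),
       n_edges = sum(W[upper.tri(W)] > 0))
}
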