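#' Weighted graph from a connectivity matrix
#'
#' Edge weights are absolute correlations, `w_ij = |r_ij|`, with a zero
#' diagonal. Missing entries (degenerate ROIs) are treated as weight 0 and
#' counted in the `n_missing` attribute.
#'
#' @param matrix a [conn_matrix()] or a symmetric numeric matrix.
#' @return A `weighted_graph`: list with `w` (weight matrix), `nodes`,
#'   `n_missing`.
#' @export
to_weighted_graph <- function(matrix) {
  r <- if (inherits(matrix, "conn_matrix")) matrix$r else as.matrix(matrix)
  nodes <- rownames(r)
  if (is.null(nodes)) nodes <- sprintf("N%d", seq_len(nrow(r)))
  n_missing <- sum(is.na(r[upper.tri(r)]))
  w <- abs(r)
  w[is.na(w)] <- 0
  diag(w) <- 0
  if (max(abs(w - t(w))) > 1e-10) stop("matrix must be symmetric")
  w <- (w + t(w)) / 2
  dimnames(w) <- list(nodes, nodes)
  structure(list(w = w, nodes = nodes, n_missing = n_missing),
            class = "weighted_graph")
}

#' @rdname to_weighted_graph
#' @export
weighted_graph <- to_weighted_graph

#' @export
print.weighted_graph <- function(x, ...) {
  l <- sum(x$w[upper.tri(x$w)] > 0)
  cat(sprintf("Weighted graph: %d nodes, %d edges%s\n", nrow(x$w), l,
              if (x$n_missing) sprintf(" (%d missing entries -> 0)",
                                       x$n_missing) else ""))
  invisible(x)
}

as_wgraph <- function(g) {
  if (inherits(g, "weighted_graph")) g else to_weighted_graph(g)
}

#' Node strength
#'
#' `s_i = sum_j w_ij`: total connection weight of each node.
#'
#' @param g a `weighted_graph` (or coercible matrix).
#' @return Named numeric vector.
#' @export
strength <- function(g) {
  g <- as_wgraph(g)
  rowSums(g$w)
}

#' Weighted clustering coefficient (Onnela)
#'
#' \deqn{C_i = \frac{1}{k_i (k_i - 1)} \sum_{j,k} (w_{ij} w_{jk} w_{ki})^{1/3}}
#' with the sum over ordered neighbour pairs and `k_i` the (binary) degree.
#' Nodes with fewer than two neighbours get `C_i = 0`. With `normalize =
#' TRUE` (default) weights are divided by the maximum weight first so that
#' `C_i <= 1`.
#'
#' @param g a `weighted_graph`.
#' @param normalize divide weights by max weight before the triangle term.
#' @return Named numeric vector.
#' @export
clustering <- function(g, normalize = TRUE) {
  g <- as_wgraph(g)
  w <- g$w
  if (normalize && max(w) > 0) w <- w / max(w)
  a <- (w > 0) * 1
  k <- rowSums(a)
  w13 <- w^(1 / 3)
  # diag of (W^(1/3))^3 = sum over ordered (j,k) of (w_ij w_jk w_ki)^(1/3)
  cyc <- diag(w13 %*% w13 %*% w13)
  denom <- k * (k - 1)
  ci <- ifelse(denom > 0, cyc / denom, 0)
  names(ci) <- g$nodes
  ci
}

#' Weighted shortest-path matrix
#'
#' Dijkstra distances on edge lengths `1/w_ij` (the standard mapping for
#' connectivity graphs: stronger correlation = shorter path). Disconnected
#' pairs are `Inf`.
#'
#' @param g a `weighted_graph`.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
shortest_paths <- function(g) {
  g <- as_wgraph(g)
  w <- g$w
  n <- nrow(w)
  ig <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  len <- 1 / igraph::E(ig)$weight
  d <- igraph::distances(ig, weights = len, algorithm = "dijkstra")
  dimnames(d) <- list(g$nodes, g$nodes)
  d
}

#' Characteristic path length and global efficiency
#'
#' `char_path_length` is the mean weighted shortest path over ordered node
#' pairs (infinite, with a finite-pairs fallback reported, when the graph
#' is disconnected); `global_efficiency` is the mean reciprocal distance,
#' with `1/Inf = 0` for disconnected pairs.
#'
#' @param g a `weighted_graph`.
#' @param d optional precomputed distance matrix from [shortest_paths()].
#' @return `char_path_length`: list with `L` (possibly `Inf`), `L_finite`
#'   (mean over connected pairs) and `connected`. `global_efficiency`: a
#'   single number in [0, 1] for weights in [0, 1].
#' @export
char_path_length <- function(g, d = shortest_paths(g)) {
  n <- nrow(d)
  if (n < 2) stop("need at least 2 nodes")
  off <- d[row(d) != col(d)]
  connected <- all(is.finite(off))
  list(L = if (connected) mean(off) else Inf,
       L_finite = mean(off[is.finite(off)]),
       connected = connected)
}

#' @rdname char_path_length
#' @export
global_efficiency <- function(g, d = shortest_paths(g)) {
  n <- nrow(d)
  if (n < 2) stop("need at least 2 nodes")
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0   # 1/Inf = 0; also kills the 1/0 diagonal
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Weighted assortativity
#'
#' Weight-weighted degree-degree Pearson correlation over the edge set:
#' \deqn{r^w = \frac{H^{-1}\sum_{(i,j)\in L} w_{ij} k_i^w k_j^w -
#'   [H^{-1}\sum \tfrac12 w_{ij}(k_i^w + k_j^w)]^2}
#'   {H^{-1}\sum \tfrac12 w_{ij}(k_i^{w2} + k_j^{w2}) -
#'   [H^{-1}\sum \tfrac12 w_{ij}(k_i^w + k_j^w)]^2}}
#' where `k_i^w` are weighted degrees (strengths), `L` the edge set and
#' `H = sum of w_ij` the normalizer of the weighted moments (the
#' Leung-Chau estimator). This normalization makes the coefficient
#' invariant under a uniform rescaling of all weights and gives hub-leaf
#' stars their expected negative value. Returns `NA` with attribute
#' `undefined = TRUE` when the denominator is zero (e.g. regular graphs
#' with equal strengths).
#'
#' @param g a `weighted_graph` with at least one edge.
#' @return Numeric in [-1, 1], or NA (undefined).
#' @export
assortativity <- function(g) {
  g <- as_wgraph(g)
  w <- g$w
  ut <- upper.tri(w) & w > 0
  if (!any(ut)) stop("graph has no edges")
  wij <- w[ut]
  kw <- rowSums(w)
  ki <- kw[row(w)[ut]]
  kj <- kw[col(w)[ut]]
  H <- sum(wij)
  term_prod <- sum(wij * ki * kj) / H
  term_mean <- sum(0.5 * wij * (ki + kj)) / H
  term_sq <- sum(0.5 * wij * (ki^2 + kj^2)) / H
  denom <- term_sq - term_mean^2
  if (abs(denom) < 1e-12) return(structure(NA_real_, undefined = TRUE))
  (term_prod - term_mean^2) / denom
}

#' Betweenness centrality
#'
#' Standard shortest-path betweenness on edge lengths `1/w`, endpoints
#' excluded, normalized by the number of ordered node pairs excluding the
#' node itself, `(n-1)(n-2)`.
#'
#' @param g a `weighted_graph`.
#' @return Named numeric vector in [0, 1].
#' @export
betweenness <- function(g) {
  g <- as_wgraph(g)
  w <- g$w
  n <- nrow(w)
  ig <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  len <- 1 / igraph::E(ig)$weight
  b <- igraph::betweenness(ig, weights = len, directed = FALSE)
  b <- b * 2 / max((n - 1) * (n - 2), 1)   # undirected pairs counted once
  names(b) <- g$nodes
  b
}

#' All per-node and global graph metrics
#'
#' @param g a `weighted_graph` or [conn_matrix()].
#' @param normalize_clustering passed to [clustering()].
#' @return list with `nodes` (data.frame: node, strength, clustering,
#'   betweenness, mean_path) and `global` (L_w, L_w_finite, E_w, r_w,
#'   mean_C, mean_s, connected).
#' @export
graph_metrics <- function(g, normalize_clustering = TRUE) {
  g <- as_wgraph(g)
  d <- shortest_paths(g)
  s <- strength(g)
  ci <- clustering(g, normalize = normalize_clustering)
  bt <- betweenness(g)
  # per-node path length: mean distance to the other nodes (finite part)
  mean_path <- vapply(seq_len(nrow(d)), function(i) {
    di <- d[i, -i]
    mean(di[is.finite(di)])
  }, numeric(1))
  L <- char_path_length(g, d)
  rw <- assortativity(g)
  list(nodes = data.frame(node = g$nodes, strength = s, clustering = ci,
                          betweenness = bt, mean_path = mean_path,
                          row.names = NULL),
       global = list(L_w = L$L, L_w_finite = L$L_finite,
                     E_w = global_efficiency(g, d), r_w = as.numeric(rw),
                     r_w_undefined = isTRUE(attr(rw, "undefined")),
                     mean_C = mean(ci), mean_s = mean(s),
                     connected = L$connected))
}

#' Hub scores on a group-mean graph
#'
#' Scores each node 0-4: +1 for membership of the 20% highest strength, 20%
#' highest betweenness, 20% lowest per-node mean path length, and 20%
#' lowest clustering coefficient. Cutoffs are empirical 80th/20th
#' percentiles (linear interpolation); ties at the threshold all qualify.
#'
#' @param g a `weighted_graph` or [conn_matrix()] (typically a group mean).
#' @param normalize_clustering passed to [clustering()].
#' @return data.frame: node, strength, clustering, betweenness, mean_path,
#'   hub_score.
#' @export
hub_scores <- function(g, normalize_clustering = TRUE) {
  m <- graph_metrics(g, normalize_clustering)$nodes
  if (nrow(m) < 5)
    warning("fewer than 5 nodes: 20% quantile criteria are coarse")
  hi <- function(x) x >= quantile(x, 0.8, type = 7)
  lo <- function(x) x <= quantile(x, 0.2, type = 7)
  m$hub_score <- hi(m$strength) + hi(m$betweenness) +
    lo(m$mean_path) + lo(m$clustering)
  m
}
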