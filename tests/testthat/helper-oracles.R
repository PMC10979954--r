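# Brute-force oracles for weighted graph metrics on small graphs.
# Independent of the package implementation: exhaustive enumeration only.

# random symmetric weight matrix on n nodes; edge present with prob p_edge
random_weight_matrix <- function(n, p_edge = 0.8) {
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (runif(1) < p_edge) w[i, j] <- w[j, i] <- runif(1, 0.05, 1)
  }
  w
}

oracle_strength <- function(w) {
  n <- nrow(w)
  s <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (j != i) s[i] <- s[i] + w[i, j]
  s
}

# Onnela clustering by explicit loops over ordered neighbour pairs
oracle_clustering <- function(w, normalize = TRUE) {
  if (normalize && max(w) > 0) w <- w / max(w)
  n <- nrow(w)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(w[i, ] > 0)
    if (k < 2) next
    acc <- 0
    for (j in seq_len(n)) for (l in seq_len(n)) {
      if (j == i || l == i || j == l) next
      acc <- acc + (w[i, j] * w[j, l] * w[l, i])^(1 / 3)
    }
    ci[i] <- acc / (k * (k - 1))
  }
  ci
}

# shortest paths by enumerating every simple path (n <= 7)
oracle_shortest_paths <- function(w) {
  n <- nrow(w)
  len <- 1 / w
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  paths_from <- function(cur, target, visited, acc) {
    if (cur == target) return(acc)
    best <- Inf
    for (nxt in seq_len(n)) {
      if (visited[nxt] || w[cur, nxt] <= 0) next
      v <- visited; v[nxt] <- TRUE
      best <- min(best, paths_from(nxt, target, v, acc + len[cur, nxt]))
    }
    best
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    visited <- rep(FALSE, n); visited[i] <- TRUE
    d[i, j] <- paths_from(i, j, visited, 0)
  }
  d
}

oracle_char_path <- function(d) {
  off <- d[row(d) != col(d)]
  if (all(is.finite(off))) mean(off) else Inf
}

oracle_efficiency <- function(d) {
  off <- d[row(d) != col(d)]
  mean(ifelse(is.finite(off), 1 / off, 0))
}

# term-by-term evaluation of the weighted assortativity estimator
oracle_assortativity <- function(w) {
  n <- nrow(w)
  kw <- oracle_strength(w)
  sw <- 0; s1 <- 0; s2 <- 0; s3 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (w[i, j] <= 0) next
    sw <- sw + w[i, j]
    s1 <- s1 + w[i, j] * kw[i] * kw[j]
    s2 <- s2 + 0.5 * w[i, j] * (kw[i] + kw[j])
    s3 <- s3 + 0.5 * w[i, j] * (kw[i]^2 + kw[j]^2)
  }
  num <- s1 / sw - (s2 / sw)^2
  den <- s3 / sw - (s2 / sw)^2
  if (abs(den) < 1e-12) NA_real_ else num / den
}

# betweenness by enumerating all shortest paths between every pair
oracle_betweenness <- function(w, tol = 1e-9) {
  n <- nrow(w)
  len <- 1 / w
  d <- oracle_shortest_paths(w)
  count_through <- matrix(0, n, n)  # [pair-count matrix] paths x via-node
  b <- numeric(n)
  # enumerate all simple paths between s and t, keep those of minimal length
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(d[s, t])) next
    all_paths <- list()
    walk <- function(cur, visited, acc, nodes) {
      if (acc > d[s, t] + tol) return()
      if (cur == t) {
        if (abs(acc - d[s, t]) < tol)
          all_paths[[length(all_paths) + 1]] <<- nodes
        return()
      }
      for (nxt in seq_len(n)) {
        if (visited[nxt] || w[cur, nxt] <= 0) next
        v <- visited; v[nxt] <- TRUE
        walk(nxt, v, acc + len[cur, nxt], c(nodes, nxt))
      }
    }
    visited <- rep(FALSE, n); visited[s] <- TRUE
    walk(s, visited, 0, s)
    npaths <- length(all_paths)
    for (pth in all_paths) {
      interior <- setdiff(pth, c(s, t))
      b[interior] <- b[interior] + 1 / npaths
    }
  }
  b / max((n - 1) * (n - 2) / 2, 1)
}
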