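test_that("weighted graph conversion takes absolute weights, zero diagonal", {
  m <- diag(3)
  m[1, 2] <- m[2, 1] <- -0.6
  g <- to_weighted_graph(conn_matrix(m))
  expect_equal(unname(g$w[1, 2]), 0.6)
  expect_equal(unname(diag(g$w)), rep(0, 3))
  # missing entries become weight 0 and are counted
  m2 <- m; m2[1, 3] <- m2[3, 1] <- NA
  g2 <- to_weighted_graph(conn_matrix(m2))
  expect_equal(unname(g2$w[1, 3]), 0)
  expect_equal(g2$n_missing, 1)
  # all-zero off-diagonal: empty edge set
  g0 <- to_weighted_graph(conn_matrix(diag(3)))
  expect_true(all(g0$w == 0))
})

test_that("fixture graphs have their exact documented metrics", {
  k3 <- to_weighted_graph(gen_toy_graph("triangle_unit"))
  expect_equal(unname(strength(k3)), rep(2, 3))
  expect_equal(unname(clustering(k3)), rep(1, 3))
  expect_equal(char_path_length(k3)$L, 1)
  expect_equal(global_efficiency(k3), 1)
  expect_equal(unname(betweenness(k3)), rep(0, 3))

  st <- to_weighted_graph(gen_toy_graph("star5"))
  expect_equal(unname(strength(st)), c(2, rep(0.5, 4)))
  expect_equal(unname(clustering(st)), rep(0, 5))
  expect_lt(assortativity(st), 0)
  hub <- hub_scores(st)
  expect_gte(hub$hub_score[1], 3)

  p4 <- to_weighted_graph(gen_toy_graph("path4"))
  d <- shortest_paths(p4)
  expect_equal(unname(d[1, 4]), 3)
  # interior nodes carry 2 of the 3 pairs not involving themselves
  expect_equal(unname(betweenness(p4)), c(0, 2 / 3, 2 / 3, 0))

  # two nodes, w = 0.5 -> distance 2
  two <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(unname(shortest_paths(to_weighted_graph(conn_matrix(two)))[1, 2]), 2)

  # indirect route beats a weak direct edge
  tri <- diag(3)
  tri[1, 2] <- tri[2, 1] <- 0.2
  tri[1, 3] <- tri[3, 1] <- 1
  tri[2, 3] <- tri[3, 2] <- 1
  expect_equal(unname(shortest_paths(to_weighted_graph(conn_matrix(tri)))[1, 2]), 2)
})

test_that("metrics match exhaustive brute-force oracles on random graphs", {
  set.seed(77)
  for (i in 1:60) {
    n <- sample(3:6, 1)
    w <- random_weight_matrix(n, p_edge = runif(1, 0.4, 1))
    if (all(w == 0)) next
    g <- structure(list(w = w, nodes = sprintf("N%d", 1:n), n_missing = 0L),
                   class = "weighted_graph")
    d <- shortest_paths(g)
    expect_equal(unname(strength(g)), oracle_strength(w), tolerance = 1e-12)
    expect_equal(unname(clustering(g)), oracle_clustering(w),
                 tolerance = 1e-12)
    expect_equal(unname(d), oracle_shortest_paths(w), tolerance = 1e-10)
    expect_equal(char_path_length(g, d)$L, oracle_char_path(d),
                 tolerance = 1e-10)
    expect_equal(global_efficiency(g, d), oracle_efficiency(d),
                 tolerance = 1e-10)
    ra <- assortativity(g)
    ro <- oracle_assortativity(w)
    if (is.na(ro)) expect_true(is.na(ra)) else
      expect_equal(as.numeric(ra), ro, tolerance = 1e-10)
    expect_equal(unname(betweenness(g)), oracle_betweenness(w),
                 tolerance = 1e-9)
  }
})

test_that("metrics are invariant to node relabeling", {
  set.seed(42)
  w <- random_weight_matrix(6)
  g <- structure(list(w = w, nodes = sprintf("N%d", 1:6), n_missing = 0L),
                 class = "weighted_graph")
  perm <- sample(6)
  wp <- w[perm, perm]
  gp <- structure(list(w = wp, nodes = sprintf("N%d", 1:6), n_missing = 0L),
                  class = "weighted_graph")
  expect_equal(unname(strength(gp)), unname(strength(g))[perm])
  expect_equal(unname(clustering(gp)), unname(clustering(g))[perm])
  expect_equal(unname(betweenness(gp)), unname(betweenness(g))[perm],
               tolerance = 1e-12)
  expect_equal(global_efficiency(gp), global_efficiency(g))
  expect_equal(as.numeric(assortativity(gp)), as.numeric(assortativity(g)),
               tolerance = 1e-12)
})

test_that("uniform weight scaling acts as expected on each metric", {
  set.seed(9)
  w <- random_weight_matrix(5)
  g <- structure(list(w = w, nodes = sprintf("N%d", 1:5), n_missing = 0L),
                 class = "weighted_graph")
  for (c in c(0.3, 0.7, 1)) {
    gc <- structure(list(w = c * w, nodes = g$nodes, n_missing = 0L),
                    class = "weighted_graph")
    expect_equal(strength(gc), c * strength(g), tolerance = 1e-12)
    expect_equal(shortest_paths(gc), shortest_paths(g) / c,
                 tolerance = 1e-10)
    expect_equal(global_efficiency(gc), c * global_efficiency(g),
                 tolerance = 1e-12)
    expect_equal(as.numeric(assortativity(gc)),
                 as.numeric(assortativity(g)), tolerance = 1e-10)
    # normalized clustering is scale-free
    expect_equal(clustering(gc), clustering(g), tolerance = 1e-12)
  }
})

test_that("disconnection conventions: E counts cross pairs as 0, L flagged", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 1
  w[3, 4] <- w[4, 3] <- 0.5
  g <- structure(list(w = w, nodes = sprintf("N%d", 1:4), n_missing = 0L),
                 class = "weighted_graph")
  d <- shortest_paths(g)
  expect_true(is.infinite(d[1, 3]))
  L <- char_path_length(g, d)
  expect_true(is.infinite(L$L))
  expect_false(L$connected)
  expect_equal(L$L_finite, mean(c(1, 1, 2, 2)))
  # 4 finite ordered pairs of 12: (1+1+2+2)/12
  expect_equal(global_efficiency(g, d), (1 + 1 + 0.5 + 0.5) / 12 / 0.25 * 0.25)
  expect_equal(global_efficiency(g, d), (2 * 1 + 2 * 0.5) / 12)
})

test_that("hub scoring applies the 20% quantile rules with tie handling", {
  # all-equal complete graph: every node ties on every criterion -> score 4
  m <- matrix(0.5, 6, 6); diag(m) <- 1
  h <- hub_scores(to_weighted_graph(conn_matrix(m)))
  expect_true(all(h$hub_score == h$hub_score[1]))
  expect_equal(h$hub_score[1], 4)

  # random fixture: scores equal composition of oracle metrics + rule
  r5 <- to_weighted_graph(gen_toy_graph("random5_seeded"))
  h5 <- hub_scores(r5)
  w <- r5$w
  d <- oracle_shortest_paths(w)
  mp <- sapply(1:5, function(i) mean(d[i, -i][is.finite(d[i, -i])]))
  sc <- (oracle_strength(w) >= quantile(oracle_strength(w), 0.8)) +
    (oracle_betweenness(w) >= quantile(oracle_betweenness(w), 0.8)) +
    (mp <= quantile(mp, 0.2)) +
    (oracle_clustering(w) <= quantile(oracle_clustering(w), 0.2))
  expect_equal(h5$hub_score, unname(sc))
  expect_warning(hub_scores(to_weighted_graph(gen_toy_graph("path4"))),
                 "fewer than 5")
})

test_that("independent graph library agrees on strength as a cross-check", {
  w <- to_weighted_graph(gen_toy_graph("random5_seeded"))$w
  ig <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  expect_equal(unname(strength(w)), unname(igraph::strength(ig)),
               tolerance = 1e-12)
})
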