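test_that("closed forms hold on canonical small graphs", {
  # complete graph K4: clustering 1, betweenness 0, efficiency 1, cpl 1
  k4 <- adj_from_edges(4, list(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4),
                               c(3, 4)))
  lm <- local_measures(k4)
  expect_equal(lm$clustering, rep(1, 4))
  expect_equal(lm$betweenness, rep(0, 4))
  gm <- global_measures(k4)
  expect_equal(gm$global_efficiency, 1)
  expect_equal(gm$characteristic_path_length, 1)
  expect_equal(gm$modularity_q, 0)

  # path a-b-c: betweenness (0,1,0), degree (1,2,1)
  p3 <- adj_from_edges(3, list(c(1, 2), c(2, 3)))
  lp <- local_measures(p3)
  expect_equal(lp$degree, c(1L, 2L, 1L))
  expect_equal(lp$betweenness, c(0, 1, 0))

  # ring of 6: characteristic path length 1.8
  ring <- adj_from_edges(6, list(c(1, 2), c(2, 3), c(3, 4), c(4, 5),
                                 c(5, 6), c(6, 1)))
  expect_equal(global_measures(ring)$characteristic_path_length, 1.8)

  # two disjoint triangles: natural bipartition has Q = 0.5
  k33 <- adj_from_edges(6, list(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6),
                                c(4, 6)))
  mod <- modularity_spectral(k33)
  expect_equal(mod$q, 0.5)
  expect_equal(length(unique(mod$membership)), 2L)
  expect_equal(length(unique(mod$membership[1:3])), 1L)
  expect_equal(length(unique(mod$membership[4:6])), 1L)
})

test_that("matching index is 1 for twin nodes and matches the brute force", {
  # nodes 1 and 2 share exactly neighborhood {3,4}, no mutual edge
  a <- adj_from_edges(5, list(c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(4, 5)))
  m <- matching_index(a)
  expect_equal(m[1, 2], bf_matching_pair(a, 1, 2))
  twin <- adj_from_edges(4, list(c(1, 3), c(1, 4), c(2, 3), c(2, 4)))
  expect_equal(matching_index(twin)[1, 2], 1)
})

test_that("all local and global measures agree with brute-force oracles", {
  set.seed(8)
  for (rep in 1:12) {
    n <- sample(4:8, 1)
    a <- rand_adj(n, runif(1, 0.25, 0.7))
    g <- fixed_geometry(8)
    d <- distance_matrix(g)[seq_len(n), seq_len(n)]
    lm <- local_measures(a, d)
    expect_equal(lm$degree, as.integer(colSums(a)))
    expect_equal(lm$clustering, bf_clustering(a))
    expect_equal(lm$betweenness, bf_betweenness(a), tolerance = 1e-10)
    expect_equal(lm$local_efficiency, bf_local_efficiency(a))
    expect_equal(lm$nodal_edge_length, unname(rowSums(a * d)))
    expect_equal(lm$matching, rowSums(bf_matching(a)) / (n - 1))
    gm <- global_measures(a, d)
    expect_equal(gm$global_efficiency, bf_efficiency(a))
    expect_equal(gm$characteristic_path_length, bf_cpl(a))
    expect_equal(gm$modularity_q, bf_modularity_q(a, gm$membership))
    phi <- rich_club_curve_oracle_check(a)
    expect_true(phi)
  }
})

test_that("modularity refinement never lowers igraph's Q evaluation", {
  set.seed(19)
  for (rep in 1:6) {
    a <- rand_adj(7, 0.45)
    if (sum(a) == 0) next
    mod <- modularity_spectral(a)
    gi <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
    expect_equal(mod$q, igraph::modularity(gi, mod$membership),
                 tolerance = 1e-12)
  }
})

test_that("adding edges never decreases global efficiency", {
  set.seed(23)
  a <- rand_adj(12, 0.15)
  eff <- global_measures(a)$global_efficiency
  absent <- which(upper.tri(a) & a == 0L)
  for (e in sample(absent, 10)) {
    a[e] <- 1L
    a[cbind(col(a)[e], row(a)[e])] <- 1L
    a <- pmax(a, t(a))
    eff2 <- global_measures(a)$global_efficiency
    expect_gte(eff2, eff - 1e-12)
    eff <- eff2
  }
})
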