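test_that("value rules evaluate their defining examples", {
  # matching of twin nodes is 1
  twin <- adj_from_edges(4, list(c(1, 3), c(1, 4), c(2, 3), c(2, 4)))
  expect_equal(value_matrix(twin, "matching")[1, 2], 1)

  # neighbors on a path: ends share the middle node
  p3 <- adj_from_edges(3, list(c(1, 2), c(2, 3)))
  expect_equal(value_matrix(p3, "neighbors")[1, 3], 1)

  # degree product on a star: center (3) x leaf (1)
  star <- adj_from_edges(4, list(c(1, 2), c(1, 3), c(1, 4)))
  expect_equal(value_matrix(star, "deg-prod")[1, 2], 3)
  expect_equal(value_matrix(star, "deg-avg")[2, 3], 1)
  expect_equal(value_matrix(star, "deg-diff")[1, 2], 2)

  expect_error(value_matrix(p3, "not-a-rule"), "rule")

  # every rule matches an R-side recomputation on random graphs
  set.seed(12)
  for (rep in 1:5) {
    a <- rand_adj(7, 0.5)
    deg <- colSums(a)
    clu <- bf_clustering(a)
    m <- bf_matching(a)
    checks <- list(
      spatial = matrix(1, 7, 7) - diag(7),
      matching = m,
      "deg-avg" = outer(deg, deg, `+`) / 2,
      "deg-prod" = outer(deg, deg),
      "clu-min" = outer(clu, clu, pmin),
      "clu-diff" = abs(outer(clu, clu, `-`)))
    for (rule in names(checks)) {
      got <- value_matrix(a, rule)
      want <- checks[[rule]]
      diag(want) <- 0
      expect_equal(got, want, tolerance = 1e-12, ignore_attr = TRUE)
    }
  }
})

test_that("wiring probabilities normalise hand-computed score ratios", {
  # flat exponents: uniform over absent pairs
  a <- adj_from_edges(4, list(c(1, 2)))
  d <- matrix(2, 4, 4); diag(d) <- 0
  sp0 <- gnm_spec("spatial", 0, 0)
  p <- wiring_probabilities(d, value_matrix(a, "spatial"), sp0, a)
  expect_equal(sum(p[upper.tri(p)]), 1)
  expect_equal(p[1, 2], 0)
  absent <- p[upper.tri(p)][p[upper.tri(p)] > 0]
  expect_equal(absent, rep(1 / 5, 5))

  # two candidates, d = (1, 2), eta = -1: probabilities (2/3, 1/3)
  a2 <- matrix(0L, 3, 3)
  a2[1, 2] <- a2[2, 1] <- 1L   # leave pairs (1,3) and (2,3) open
  d2 <- matrix(0, 3, 3)
  d2[1, 2] <- d2[2, 1] <- 5
  d2[1, 3] <- d2[3, 1] <- 1
  d2[2, 3] <- d2[3, 2] <- 2
  sp1 <- gnm_spec("spatial", -1, 0)
  p2 <- wiring_probabilities(d2, value_matrix(a2, "spatial"), sp1, a2)
  expect_equal(p2[1, 3], 2 / 3, tolerance = 1e-9)
  expect_equal(p2[2, 3], 1 / 3, tolerance = 1e-9)

  # eta = -2 over d = (1, 2, 4): scores proportional to (1, 1/4, 1/16)
  a3 <- matrix(0L, 4, 4)
  a3[1, 3] <- a3[3, 1] <- 1L
  a3[1, 4] <- a3[4, 1] <- 1L
  a3[3, 4] <- a3[4, 3] <- 1L
  d3 <- matrix(1, 4, 4); diag(d3) <- 0
  d3[1, 2] <- d3[2, 1] <- 1
  d3[2, 3] <- d3[3, 2] <- 2
  d3[2, 4] <- d3[4, 2] <- 4
  sp2 <- gnm_spec("spatial", -2, 0)
  p3 <- wiring_probabilities(d3, value_matrix(a3, "spatial"), sp2, a3)
  w <- c(1, 1 / 4, 1 / 16) / sum(c(1, 1 / 4, 1 / 16))
  expect_equal(c(p3[1, 2], p3[2, 3], p3[2, 4]), w, tolerance = 1e-9)
})

test_that("growth respects the seed, edge target and determinism", {
  g <- generate_geometry(20, seed = 4)
  d <- distance_matrix(g)
  seed <- adj_from_edges(20, list(c(1, 2), c(3, 4), c(5, 6)))
  spec <- gnm_spec("matching", -2, 0.3)

  # zero-iteration growth returns the seed untouched
  tr0 <- grow_network(seed, d, spec, 3)
  expect_equal(nrow(tr0$trace), 0L)
  expect_identical(tr0$network$adjacency, seed)

  set.seed(10); tr1 <- grow_network(seed, d, spec, 40)
  set.seed(10); tr2 <- grow_network(seed, d, spec, 40)
  expect_identical(tr1$trace, tr2$trace)
  expect_equal(edge_count(tr1$network), 40)
  expect_true(all(tr1$network$adjacency[seed == 1L] == 1L))
  # trace replays to the final network
  rebuilt <- seed
  for (t in seq_len(nrow(tr1$trace))) {
    i <- tr1$trace$from[t]; j <- tr1$trace$to[t]
    expect_equal(rebuilt[i, j], 0L)
    rebuilt[i, j] <- rebuilt[j, i] <- 1L
  }
  expect_identical(rebuilt, tr1$network$adjacency)
  expect_error(grow_network(seed, d, spec, 2), "below seed")
})

test_that("strong distance penalty shortens added edges", {
  g <- generate_geometry(20, seed = 6)
  d <- distance_matrix(g)
  seed <- matrix(0L, 20, 20)
  mean_len <- function(eta, reps = 100) {
    spec <- gnm_spec("spatial", eta, 0)
    mean(vapply(seq_len(reps), function(i)
      mean(grow_network(seed, d, spec, 30)$trace$length), 0.0))
  }
  set.seed(9)
  expect_lt(mean_len(-8), mean_len(0))
})

test_that("under the spatial rule gamma is irrelevant", {
  g <- generate_geometry(14, seed = 8)
  d <- distance_matrix(g)
  seed <- matrix(0L, 14, 14)
  set.seed(33); t0 <- grow_network(seed, d, gnm_spec("spatial", -1, 0), 25)
  set.seed(33); t5 <- grow_network(seed, d, gnm_spec("spatial", -1, 5), 25)
  expect_identical(t0$trace$from, t5$trace$from)
  expect_identical(t0$trace$to, t5$trace$to)
  expect_equal(t0$trace$prob, t5$trace$prob, tolerance = 1e-12)
})

test_that("growth trace probabilities replay against the full recomputation", {
  g <- generate_geometry(12, seed = 15)
  d <- distance_matrix(g)
  seed <- matrix(0L, 12, 12)
  for (rule in c("matching", "neighbors", "clu-avg", "deg-prod")) {
    spec <- gnm_spec(rule, -1.3, 0.4)
    set.seed(50)
    tr <- grow_network(seed, d, spec, 20)
    a <- seed
    for (t in seq_len(nrow(tr$trace))) {
      p <- wiring_probabilities(d, value_matrix(a, rule), spec, a)
      i <- tr$trace$from[t]; j <- tr$trace$to[t]
      expect_equal(tr$trace$prob[t], p[i, j], tolerance = 1e-10)
      a[i, j] <- a[j, i] <- 1L
    }
  }
})

test_that("seed derivation applies the prevalence boundary inclusively", {
  n <- 6
  base <- adj_from_edges(n, list(c(1, 2), c(3, 4)))
  nets <- c(rep(list(binary_network(base)), 19),
            list(binary_network(adj_from_edges(n, list(c(1, 2))))))
  seed <- derive_seed_network(nets, 0.95)
  expect_equal(seed$adjacency[1, 2], 1L)  # 20/20
  expect_equal(seed$adjacency[3, 4], 1L)  # 19/20 >= 0.95
  expect_equal(eval(formals(derive_seed_network)$prevalence), 0.95)

  # identical cohort at prevalence 1 returns the common network
  expect_identical(derive_seed_network(rep(list(binary_network(base)), 5),
                                       1.0)$adjacency, base)
  expect_message(derive_seed_network(list(binary_network(matrix(0L, 4, 4))),
                                     0.95), "empty")
})
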