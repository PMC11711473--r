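test_that("KS statistic matches hand enumerations", {
  expect_equal(ks_statistic(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(ks_statistic(c(0, 0), c(1, 1)), 1)
  expect_equal(ks_statistic(c(1, 2, 3), c(2, 3, 4)), 1 / 3)
  expect_error(ks_statistic(numeric(), 1), "nonempty")
})

test_that("energy is zero on identity, one on extremes, and equals its max", {
  g <- fixed_geometry(8)
  d <- distance_matrix(g)
  set.seed(5)
  a <- rand_adj(8, 0.5)
  e <- energy(a, a, d)
  expect_equal(unname(e["energy"]), 0)

  empty <- matrix(0L, 8, 8)
  full <- 1L - diag(1L, 8)
  expect_equal(unname(energy(empty, full, d)["energy"]), 1)

  for (rep in 1:10) {
    x <- rand_adj(8, runif(1, 0.2, 0.8))
    y <- rand_adj(8, runif(1, 0.2, 0.8))
    e <- energy(x, y, d)
    expect_equal(unname(e["energy"]), max(e[-1]))
    expect_true(all(e >= 0 & e <= 1))
  }
  expect_error(energy(rand_adj(6), rand_adj(8), d), "node set")
})

test_that("parameter grids are inclusive, even and validated", {
  g <- make_grid(c(-3, 0), c(0.1, 0.6), 100, 100)
  expect_equal(nrow(g), 10000)
  expect_true(all(c(-3, 0) %in% g$eta))
  expect_true(all(c(0.1, 0.6) %in% g$gamma))
  expect_true(nrow(merge(data.frame(eta = -3, gamma = 0.1), g)) == 1)

  g1 <- make_grid(c(-2, -1), c(0.2, 0.4), 1, 1)
  expect_equal(nrow(g1), 1)
  expect_equal(g1$eta, -1.5)
  expect_equal(g1$gamma, 0.3)

  gs <- make_grid(c(-4, 0), c(0, 1), 5, 9)
  expect_equal(diff(sort(unique(gs$eta))), rep(1, 4))
  expect_equal(diff(sort(unique(gs$gamma))), rep(0.125, 8))
  expect_error(make_grid(c(-1, -1), c(0, 1), 3, 3), "degenerate")
})

test_that("self-generated networks are fit at their own parameters", {
  g <- generate_geometry(40, seed = 12)
  d <- distance_matrix(g)
  seed <- wiregrow:::seed_from_geometry(g, cohort_spec(n_nodes = 40,
                                                       rng_seed = 1))
  truth <- gnm_spec("matching", -2, 0.3)
  set.seed(61)
  obs <- grow_network(seed, d, truth, 100)$network
  # truth on the lattice, competitors well separated
  grid <- make_grid(c(-6, 0), c(0.3, 1.8), 4, 4)
  stopifnot(any(grid$eta == -2 & grid$gamma == 0.3))
  set.seed(62)
  fit <- gnm_fit(obs, d, seed = seed, rule = "matching", grid = grid,
                 nreps = 2)
  expect_equal(unname(coef(fit)), c(-2, 0.3), tolerance = 1e-12)
  # landscape bookkeeping: reported best is the landscape minimum
  expect_equal(fit$best$energy, min(fit$landscape$energy))
  expect_equal(nrow(fit$landscape), 16)
})

test_that("topological fingerprints are valid correlation matrices", {
  set.seed(77)
  g <- fixed_geometry(8)
  d <- distance_matrix(g)
  a <- rand_adj(8, 0.5)
  tf <- topological_fingerprint(a, d)
  expect_equal(dim(tf), c(6, 6))
  expect_equal(diag(tf), rep(1, 6), ignore_attr = TRUE)
  expect_equal(tf, t(tf))
  expect_true(all(abs(tf) <= 1 + 1e-12))

  # zero-variance measure (regular ring: constant degree) -> 0 by convention
  ring <- adj_from_edges(6, list(c(1, 2), c(2, 3), c(3, 4), c(4, 5),
                                 c(5, 6), c(6, 1)))
  dr <- distance_matrix(fixed_geometry(6))
  expect_warning(tfr <- topological_fingerprint(ring, dr), "zero-variance")
  expect_equal(tfr["degree", "betweenness"], 0, ignore_attr = TRUE)
  expect_equal(diag(tfr), rep(1, 6), ignore_attr = TRUE)
})

test_that("fingerprint dissimilarity is the Frobenius norm and a metric", {
  tf <- diag(6)
  expect_equal(tf_dissimilarity(tf, tf), 0)
  tf2 <- tf
  tf2[1, 2] <- tf2[2, 1] <- 0.5
  expect_equal(tf_dissimilarity(tf, tf2), sqrt(2 * 0.25), tolerance = 1e-12)
  expect_error(tf_dissimilarity(tf, diag(5)), "shape")

  set.seed(91)
  for (rep in 1:20) {
    a <- matrix(runif(36, -1, 1), 6)
    b <- matrix(runif(36, -1, 1), 6)
    c <- matrix(runif(36, -1, 1), 6)
    expect_lte(tf_dissimilarity(a, c),
               tf_dissimilarity(a, b) + tf_dissimilarity(b, c) + 1e-12)
  }
})

test_that("spatial embedding is 1 on identity and null under permutation", {
  set.seed(41)
  g <- generate_geometry(30, seed = 41)
  d <- distance_matrix(g)
  a <- rand_adj(30, 0.2)
  lm <- local_measures(a, d)
  se <- spatial_embedding(lm, lm)
  expect_equal(unname(se), rep(1, 6), tolerance = 1e-12)
  expect_named(se, c("degree", "clustering", "betweenness",
                     "nodal_edge_length", "local_efficiency", "matching"))

  perm_r <- replicate(50, {
    p <- sample(30)
    spatial_embedding(lm, lm[p, ])["degree"]
  })
  expect_lt(abs(mean(perm_r)), 3 * sd(perm_r) / sqrt(50))
})
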