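test_that("consensus mask keeps edges by prevalence with >= comparison", {
  n <- 5
  s1 <- toy_weighted(n, list(c(1, 2, 10), c(2, 3, 5)))
  s2 <- toy_weighted(n, list(c(1, 2, 8)))
  s3 <- toy_weighted(n, list(c(1, 2, 2), c(2, 3, 9), c(4, 5, 7)))
  cohort <- list(s1, s2, s3)

  # unanimity: edge (2,3) absent in one subject
  m1 <- consensus_mask(cohort, 1.0)$mask$adjacency
  expect_equal(m1[2, 3], 0L)
  expect_equal(m1[1, 2], 1L)

  # 2/3 >= 0.6 retains; strictly-greater flag drops it
  m06 <- consensus_mask(cohort, 0.6)$mask$adjacency
  expect_equal(m06[2, 3], 1L)
  expect_equal(m06[4, 5], 0L)   # 1/3 < 0.6
  m_strict <- consensus_mask(cohort, 2 / 3, strict = TRUE)$mask$adjacency
  expect_equal(m_strict[2, 3], 0L)

  # proportion -> 0+ gives the union of edges
  mu <- consensus_mask(cohort, 1e-9)$mask$adjacency
  expect_equal(sum(mu) / 2, 3)

  # mask applies multiplicatively to the weights
  masked <- consensus_mask(cohort, 1.0)$cohort
  expect_equal(masked[[3]]$weights[2, 3], 0)
  expect_equal(masked[[1]]$weights[1, 2], 10)
  expect_error(consensus_mask(list(), 0.6), "empty")
})

test_that("absolute thresholding uses the >= convention", {
  w <- toy_weighted(4, list(c(1, 2, 330), c(3, 4, 320)))
  b <- threshold_absolute(w, 325)
  expect_equal(b$adjacency[1, 2], 1L)
  expect_equal(b$adjacency[3, 4], 0L)
  b0 <- threshold_absolute(w, 0)
  expect_equal(edge_count(b0), 2)
  expect_equal(threshold_absolute(w, 320)$adjacency[3, 4], 1L)
  expect_equal(eval(formals(threshold_absolute)$min_count), 325)
})

test_that("density thresholding hits the exact rounded edge count deterministically", {
  set.seed(21)
  n <- 90
  w <- matrix(0, n, n)
  w[upper.tri(w)] <- sample(seq_len(n * (n - 1) / 2))
  w <- w + t(w)
  b <- threshold_to_density(w, 0.10)
  expect_equal(edge_count(b), 400)   # round(0.10 * 4005)

  # complete positive matrix at target 1 stays complete
  wc <- matrix(1, 6, 6); diag(wc) <- 0
  expect_equal(edge_count(threshold_to_density(wc, 1.0)), 15)

  # ties at the cutoff resolved reproducibly (lexicographic node pair)
  wt <- matrix(0, 4, 4)
  wt[1, 2] <- wt[2, 1] <- 5
  wt[1, 3] <- wt[3, 1] <- 5
  wt[1, 4] <- wt[4, 1] <- 5
  b1 <- threshold_to_density(wt, 2 / 6)
  b2 <- threshold_to_density(wt, 2 / 6)
  expect_identical(b1$adjacency, b2$adjacency)
  expect_equal(b1$adjacency[1, 2], 1L)
  expect_equal(b1$adjacency[1, 3], 1L)
  expect_equal(b1$adjacency[1, 4], 0L)

  expect_error(threshold_to_density(wt, 0.9), "cannot reach")
})

test_that("mean-density threshold search finds the smallest adequate count", {
  co <- small_cohort(n_subjects = 10, n_nodes = 40, seed = 31)
  res <- find_absolute_threshold_for_mean_density(co, 0.10)
  expect_lte(res$mean_density, 0.10)
  expect_lt(abs(res$mean_density - 0.10), 0.005)
  # smallest such threshold: one less overshoots
  dens_at <- function(t) mean(vapply(co$subjects, function(s)
    network_density(threshold_absolute(s, t)), 0.0))
  if (res$min_count > 0) expect_gt(dens_at(res$min_count - 1L), 0.10)
  # monotone non-increasing in the threshold
  ds <- vapply(c(0, 50, 150, 400, 1000), dens_at, 0.0)
  expect_true(all(diff(ds) <= 1e-12))
  # target above the union density needs no thresholding
  expect_equal(find_absolute_threshold_for_mean_density(co, 0.99)$min_count, 0L)
})

test_that("consensus network reproduces identical subjects and bin counts", {
  co <- small_cohort(n_subjects = 6, n_nodes = 30, seed = 17)
  nets <- lapply(co$subjects, threshold_to_density,
                 target_density = 0.15, geometry = co$geometry)
  d <- distance_matrix(co$geometry)

  # fixed point on a cohort of identical networks
  same <- rep(nets[1], 5)
  cons_same <- build_consensus_network(same, d, n_bins = 4)
  expect_identical(cons_same$adjacency, nets[[1]]$adjacency)

  # per-bin consensus edge count equals the rounded subject mean per bin
  cons <- build_consensus_network(nets, d, n_bins = 5)
  h <- co$geometry$hemisphere
  ut <- which(upper.tri(d), arr.ind = TRUE)
  prev <- Reduce(`+`, lapply(nets, function(x) x$adjacency)) / length(nets)
  cand <- prev[ut] > 0
  strat <- ifelse(h[ut[, 1]] == h[ut[, 2]], "intra", "inter")[cand]
  dd <- d[ut][cand]
  ca <- cons$adjacency[ut][cand]
  pres <- vapply(nets, function(x) x$adjacency[ut][cand], integer(sum(cand)))
  for (st in unique(strat)) {
    sel <- strat == st
    nb <- min(5, length(unique(dd[sel])))
    brk <- unique(quantile(dd[sel], probs = seq(0, 1, length.out = nb + 1)))
    bin <- cut(dd[sel], breaks = brk, include.lowest = TRUE, labels = FALSE)
    for (b in unique(bin)) {
      got <- sum(ca[sel][bin == b])
      want <- round(mean(colSums(pres[sel, , drop = FALSE][bin == b, ,
                                                           drop = FALSE])) + 1e-9)
      expect_equal(got, min(want, sum(bin == b)))
    }
  }
})

test_that("single-bin consensus degenerates to prevalence ranking", {
  n <- 6
  s1 <- binary_network(adj_from_edges(n, list(c(1, 2), c(3, 4), c(5, 6))))
  s2 <- binary_network(adj_from_edges(n, list(c(1, 2), c(3, 4))))
  s3 <- binary_network(adj_from_edges(n, list(c(1, 2), c(2, 3), c(5, 6))))
  d <- matrix(1, n, n) + outer(seq_len(n), seq_len(n)) / 100
  diag(d) <- 0
  cons <- build_consensus_network(list(s1, s2, s3), d, n_bins = 1,
                                  split_hemispheres = FALSE)
  # mean edge count is round(8/3) = 3: the three most prevalent edges
  expect_equal(edge_count(cons), 3)
  expect_equal(cons$adjacency[1, 2], 1L)  # prevalence 3/3
  expect_equal(cons$adjacency[3, 4], 1L)  # prevalence 2/3
  expect_equal(cons$adjacency[5, 6], 1L)  # prevalence 2/3
})

test_that("consensus length distribution beats prevalence-only consensus", {
  co <- small_cohort(n_subjects = 12, n_nodes = 40, seed = 53)
  nets <- lapply(co$subjects, threshold_to_density,
                 target_density = 0.12, geometry = co$geometry)
  d <- distance_matrix(co$geometry)
  cons_binned <- build_consensus_network(nets, d, n_bins = 10)
  m <- edge_count(cons_binned)
  # prevalence-only consensus at the same density
  prev <- Reduce(`+`, lapply(nets, function(x) x$adjacency))
  cons_prev <- threshold_to_density(prev, m / (40 * 39 / 2))
  pooled <- unlist(lapply(nets, function(x) d[edge_list(x)]))
  ks_binned <- ks_statistic(d[edge_list(cons_binned)], pooled)
  ks_prev <- ks_statistic(d[edge_list(cons_prev)], pooled)
  expect_lt(ks_binned, ks_prev)
})
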