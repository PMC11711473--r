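make_group_setup <- function(n = 20, seed = 44) {
  g <- generate_geometry(n, seed = seed)
  d <- distance_matrix(g)
  seed_net <- binary_network(adj_from_edges(n, list(c(1, 2), c(3, 4))), g)
  list(g = g, d = d, seed = seed_net)
}

test_that("a single run reduces to its own cumulative trace statistics", {
  s <- make_group_setup()
  cfg <- group_model_config(n_runs = 1, m_target = 30,
                            seed_network = s$seed)
  rich <- c(1, 2, 5, 6)
  set.seed(3)
  sm <- run_group(cfg, "term", s$d, rich)
  set.seed(3)
  tr <- grow_network(s$seed, s$d,
                     gnm_spec("matching", -1.74, 0.32), 30)
  is_rich <- seq_len(20) %in% rich
  ends <- is_rich[tr$trace$from] + is_rich[tr$trace$to]
  n_iter <- nrow(tr$trace)
  expect_equal(sm$by_iteration$length_all, cumsum(tr$trace$length) / seq_len(n_iter))
  # seed edge (1,2) is rich under this set; counts include it
  expect_equal(sm$by_iteration$count_rich,
               1 + cumsum(ends == 2))
  expect_equal(sm$final$n_rich + sm$final$n_feeder + sm$final$n_local, 30)
})

test_that("class counts sum to the running edge total at every iteration", {
  s <- make_group_setup()
  cfg <- group_model_config(n_runs = 4, m_target = 40, seed_network = s$seed)
  set.seed(8)
  sm <- run_group(cfg, "preterm", s$d, c(2, 3, 7))
  bi <- sm$by_iteration
  total <- bi$count_rich + bi$count_feeder + bi$count_local
  expect_equal(total, 2 + bi$iteration)   # 2 seed edges plus t additions
  expect_true(all(diff(bi$count_rich) >= 0))
  expect_true(all(diff(bi$count_local) >= 0))
})

test_that("identical parameters for both groups give null differences", {
  s <- make_group_setup()
  cfg <- group_model_config(term = c(eta = -1.8, gamma = 0.3),
                            preterm = c(eta = -1.8, gamma = 0.3),
                            n_runs = 60, m_target = 40,
                            seed_network = s$seed)
  set.seed(13)
  st <- run_group(cfg, "term", s$d, c(1, 2, 5))
  sp <- run_group(cfg, "preterm", s$d, c(1, 2, 5))
  cmp <- compare_groups(st, sp, n_perm = 400)
  fin <- cmp$final
  # permutation test should not reject a true null for the headline contrast
  expect_gt(fin$p_perm[fin$variable == "mean_length"], 0.01)
  se_len <- sd(c(st$final$mean_length, sp$final$mean_length)) * sqrt(2 / 60)
  expect_lt(abs(fin$difference[fin$variable == "mean_length"]), 4 * se_len)
})

test_that("mismatched configurations are rejected", {
  s <- make_group_setup()
  cfg1 <- group_model_config(n_runs = 2, m_target = 30, seed_network = s$seed)
  cfg2 <- group_model_config(n_runs = 2, m_target = 35, seed_network = s$seed)
  set.seed(1)
  a <- run_group(cfg1, "term", s$d, 1:3)
  b <- run_group(cfg2, "preterm", s$d, 1:3)
  expect_error(compare_groups(a, b), "m_target")
  c2 <- run_group(cfg1, "preterm", s$d, 1:4)
  expect_error(compare_groups(a, c2), "rich-node")
  expect_error(group_model_config(n_runs = 0, m_target = 10,
                                  seed_network = s$seed), "n_runs")
})

test_that("group experiment table is long-format per class and iteration", {
  s <- make_group_setup()
  cfg <- group_model_config(n_runs = 2, m_target = 25, seed_network = s$seed)
  set.seed(5)
  st <- run_group(cfg, "term", s$d, 1:3)
  sp <- run_group(cfg, "preterm", s$d, 1:3)
  tab <- group_experiment_table(list(st, sp))
  expect_equal(nrow(tab), 2 * 3 * (25 - 2))
  expect_setequal(unique(tab$class), c("rich", "feeder", "local"))
  expect_setequal(unique(tab$group), c("term", "preterm"))
})
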