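# Deterministic fixtures shared across test files.

# Small bilateral geometry with hand-set coordinates (no RNG).
fixed_geometry <- function(n = 8) {
  stopifnot(n %% 2 == 0)
  nh <- n / 2
  # right hemisphere: points on a slanted line, mirrored for the left
  right <- cbind(x = 20 + 3 * seq_len(nh), y = 7 * seq_len(nh) - 10,
                 z = 5 * ((seq_len(nh) %% 3) - 1))
  coords <- rbind(right, cbind(-right[, 1], right[, 2:3]))
  node_geometry(coords, rep(c("R", "L"), each = nh))
}

# Weighted connectome with all-distinct positive weights on given edges.
toy_weighted <- function(n, edges_weights, covariates = NULL) {
  w <- matrix(0, n, n)
  for (e in edges_weights) w[e[1], e[2]] <- w[e[2], e[1]] <- e[3]
  weighted_connectome(w, covariates)
}

toy_covariates <- function(id = "s1", pma = 40, ga = 39, sex = "F") {
  subject_covariates(id, pma, ga, sex)
}

# Quick small synthetic cohort used by several construction tests.
small_cohort <- function(n_subjects = 8, n_nodes = 40, seed = 42, ...) {
  generate_cohort(cohort_spec(n_subjects = n_subjects, n_nodes = n_nodes,
                              rng_seed = seed, ...))
}
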