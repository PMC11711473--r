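#' Specification of a synthetic cohort
#'
#' Defines the ground-truth generative process and demographic structure
#' of a simulated cohort of neonatal connectomes. Defaults emulate the
#' study conditions this package targets: a bilateral 90-node
#' parcellation, about 10% network density at term-equivalent age with
#' density increasing across postmenstrual age (PMA), roughly 29% of
#' subjects born preterm (< 37 weeks), and homophily ('matching') wiring
#' with group-specific exponents (term eta = -1.74, gamma = 0.32; preterm
#' eta = -1.85, gamma = 0.34). Streamline counts on present edges decay
#' with distance so that absolute thresholding sparsifies long connections
#' first, as in real tractography.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param n_nodes even number of nodes.
#' @param rule ground-truth value rule, one of [gnm_rules()].
#' @param eta_term,gamma_term wiring exponents for term subjects.
#' @param eta_preterm,gamma_preterm wiring exponents for preterm subjects.
#' @param density_at_term mean analysis density at 40 weeks PMA (the
#'   density the thresholded binary networks are meant to have).
#' @param density_slope change in density per week of PMA.
#' @param raw_density_factor the raw (weight > 0) connectome is this many
#'   times denser than the analysis density, so count thresholding has
#'   room to sparsify (raw tractography is far denser than the analysed
#'   networks); default 2.5.
#' @param preterm_fraction expected fraction of preterm births.
#' @param seed_frac seed network size as a fraction of the term-density
#'   edge count; the seed is the shortest-distance node pairs, shared by
#'   all subjects.
#' @param weight_scale mean streamline count at zero distance.
#' @param weight_decay distance (mm) over which the mean count decays by
#'   a factor e.
#' @param weight_dispersion negative-binomial size parameter of the count
#'   noise; larger is less dispersed. The default (8) keeps counts
#'   overdispersed relative to Poisson while leaving the shortest, most
#'   consistent connections present in nearly every subject, so a
#'   95%-prevalence seed network exists as it does in real cohorts.
#' @param hemi_offset,spread geometry parameters, see
#'   [generate_geometry()].
#' @param epsilon growth-model offset, see [gnm_spec()].
#' @param rng_seed integer seed; the whole cohort is a deterministic
#'   function of this spec.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 30L, n_nodes = 90L,
                        rule = "matching",
                        eta_term = -1.74, gamma_term = 0.32,
                        eta_preterm = -1.85, gamma_preterm = 0.34,
                        density_at_term = 0.10, density_slope = 0.004,
                        raw_density_factor = 2.5,
                        preterm_fraction = 0.29,
                        seed_frac = 0.10,
                        weight_scale = 450, weight_decay = 60,
                        weight_dispersion = 8,
                        hemi_offset = 25, spread = c(12, 35, 22),
                        epsilon = 1e-5,
                        rng_seed = 1L) {
  if (n_subjects < 2L) stop("n_subjects must be at least 2")
  if (n_nodes %% 2L != 0L) stop("n_nodes must be even")
  rule <- match.arg(rule, gnm_rules())
  if (density_at_term <= 0 || density_at_term > 1)
    stop("density_at_term must be in (0, 1]")
  if (raw_density_factor < 1) stop("raw_density_factor must be >= 1")
  if (density_at_term * raw_density_factor > 1)
    stop("raw density exceeds 100%")
  if (preterm_fraction < 0 || preterm_fraction > 1)
    stop("preterm_fraction must be in [0, 1]")
  if (weight_scale <= 0 || weight_decay <= 0 || weight_dispersion <= 0)
    stop("weight model parameters must be positive")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_nodes = as.integer(n_nodes), rule = rule,
                 eta_term = eta_term, gamma_term = gamma_term,
                 eta_preterm = eta_preterm, gamma_preterm = gamma_preterm,
                 density_at_term = density_at_term,
                 density_slope = density_slope,
                 raw_density_factor = raw_density_factor,
                 preterm_fraction = preterm_fraction,
                 seed_frac = seed_frac,
                 weight_scale = weight_scale, weight_decay = weight_decay,
                 weight_dispersion = weight_dispersion,
                 hemi_offset = hemi_offset, spread = spread,
                 epsilon = epsilon,
                 rng_seed = as.integer(rng_seed)),
            class = "cohort_spec")
}

# Analysis-density target as a function of scan age, clamped so the raw
# connectome always has headroom above the analysis density.
density_at_age <- function(spec, pma_weeks) {
  d <- spec$density_at_term + spec$density_slope * (pma_weeks - 40)
  pmin(pmax(d, 0.05), 0.9 / spec$raw_density_factor)
}

# Shared seed: the shortest-distance node pairs. Mimics the early
# emergence of short-range connections and guarantees every subject
# contains the seed, so a 95%-prevalence seed recovers it.
seed_from_geometry <- function(geometry, spec) {
  n <- length(geometry$node_ids)
  n_pairs <- n * (n - 1) / 2
  m_seed <- round_half_up(spec$seed_frac * spec$density_at_term * n_pairs)
  d <- geometry$dist
  ut <- which(upper.tri(d), arr.ind = TRUE)
  ord <- order(d[upper.tri(d)], ut[, 1L], ut[, 2L])
  keep <- ut[ord[seq_len(m_seed)], , drop = FALSE]
  a <- matrix(0L, n, n)
  a[keep] <- 1L
  a <- a + t(a)
  binary_network(a, geometry)
}

#' Sample covariates for one subject
#'
#' Gestational age at birth is drawn per group (term: 37-42 weeks,
#' preterm: 24-36.9); postnatal exposure before the scan is gamma
#' distributed with a mean that grows as birth age falls, reproducing the
#' negative birth-age / exposure correlation seen in neonatal imaging
#' cohorts (infants born early are scanned after a longer interval).
#'
#' @keywords internal
sample_covariates <- function(subject_id, preterm) {
  ga <- if (preterm) runif(1, 24, 36.9) else runif(1, 37, 42)
  mu_exposure <- max(0.8, 0.8 + 0.3 * (40 - ga))
  exposure <- rgamma(1, shape = 2, scale = mu_exposure / 2)
  pma <- min(ga + exposure, 45)
  subject_covariates(subject_id, pma_weeks = pma, ga_birth_weeks = ga,
                     sex = sample(c("F", "M"), 1L))
}

#' Generate one synthetic subject
#'
#' Grows a binary scaffold with the generative engine at the subject's
#' ground-truth parameters (group specific), to an edge count set by the
#' density-versus-age function, then assigns streamline counts on present
#' edges from a shifted negative-binomial distribution whose mean decays
#' with distance.
#'
#' @param geometry a [node_geometry()].
#' @param covariates a [subject_covariates()].
#' @param spec a [cohort_spec()].
#' @param seed_network shared seed `binary_network`; defaults to the
#'   shortest-distance seed implied by the spec.
#' @return A [weighted_connectome()].
#' @export
generate_subject <- function(geometry, covariates, spec,
                             seed_network = NULL) {
  if (is.null(seed_network)) seed_network <- seed_from_geometry(geometry, spec)
  n <- length(geometry$node_ids)
  n_pairs <- n * (n - 1) / 2
  dens <- density_at_age(spec, covariates$pma_weeks) * spec$raw_density_factor
  if (dens > 1) stop("target density exceeds 100%")
  m_target <- max(round_half_up(dens * n_pairs), edge_count(seed_network))
  preterm <- covariates$group == "preterm"
  gspec <- gnm_spec(spec$rule,
                    eta = if (preterm) spec$eta_preterm else spec$eta_term,
                    gamma = if (preterm) spec$gamma_preterm else spec$gamma_term,
                    epsilon = spec$epsilon)
  grown <- grow_network(seed_network, geometry$dist, gspec, m_target)
  a <- grown$network$adjacency
  d <- geometry$dist
  w <- matrix(0L, n, n)
  idx <- which(upper.tri(a) & a == 1L)
  mu <- spec$weight_scale * exp(-d[idx] / spec$weight_decay)
  # shifted to support {1, 2, ...}: present edges always carry >= 1 count
  w[idx] <- 1L + stats::rnbinom(length(idx), size = spec$weight_dispersion,
                                mu = mu)
  w <- w + t(w)
  weighted_connectome(w, covariates)
}

#' Generate a synthetic cohort
#'
#' All subjects share one bilateral geometry and one seed network; group
#' membership, scan ages, scaffold topology and streamline weights are
#' sampled per subject. The result is a deterministic function of the
#' spec (including its `rng_seed`).
#'
#' @param spec a [cohort_spec()].
#' @return An object of class `cohort`: list with `geometry`,
#'   `seed_network`, `subjects` (list of [weighted_connectome()]) and
#'   `spec`.
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stop("spec must be a cohort_spec")
  with_seed(spec$rng_seed, {
    geometry <- generate_geometry(spec$n_nodes, spec$hemi_offset,
                                  spec$spread)
    seed_net <- seed_from_geometry(geometry, spec)
    preterm <- rbinom(spec$n_subjects, 1L, spec$preterm_fraction) == 1L
    # both groups must be represented for group contrasts to be defined
    if (all(preterm)) preterm[1L] <- FALSE
    if (!any(preterm)) preterm[1L] <- TRUE
    subjects <- vector("list", spec$n_subjects)
    for (s in seq_len(spec$n_subjects)) {
      cov <- sample_covariates(sprintf("sub-%03d", s), preterm[s])
      subjects[[s]] <- generate_subject(geometry, cov, spec, seed_net)
    }
    structure(list(geometry = geometry, seed_network = seed_net,
                   subjects = subjects, spec = spec),
              class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  groups <- vapply(x$subjects, function(s) s$covariates$group, "")
  cat("Synthetic cohort:", length(x$subjects), "subjects (",
      sum(groups == "term"), "term /", sum(groups == "preterm"),
      "preterm ),", length(x$geometry$node_ids), "nodes\n")
  invisible(x)
}

#' Covariate table of a cohort
#'
#' @param cohort a `cohort` (or list of [weighted_connectome()]).
#' @return data frame: subject_id, pma, ga_birth, sex, group.
#' @export
covariate_table <- function(cohort) {
  subs <- if (inherits(cohort, "cohort")) cohort$subjects else cohort
  do.call(rbind, lapply(subs, function(s) {
    cv <- s$covariates
    data.frame(subject_id = cv$subject_id, pma = cv$pma_weeks,
               ga_birth = cv$ga_birth_weeks, sex = cv$sex,
               group = cv$group, stringsAsFactors = FALSE)
  }))
}
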