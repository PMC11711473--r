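#' Consensus mask over a weighted cohort
#'
#' An edge is kept when it has nonzero weight in at least `proportion` of
#' subjects (>= comparison; set `strict = TRUE` for >). The mask is
#' applied multiplicatively to every subject's weights, removing
#' low-consistency edges that are likely tractography false positives.
#'
#' @param cohort a `cohort` or list of [weighted_connectome()]s.
#' @param proportion required fraction of subjects, in (0, 1].
#' @param strict use strictly-greater comparison (default `FALSE`).
#' @return List with `mask` (a `binary_network`) and `cohort` (the masked
#'   subject list).
#' @export
consensus_mask <- function(cohort, proportion = 0.6, strict = FALSE) {
  subs <- if (inherits(cohort, "cohort")) cohort$subjects else cohort
  geometry <- if (inherits(cohort, "cohort")) cohort$geometry else NULL
  if (length(subs) == 0L) stop("empty cohort")
  if (proportion <= 0 || proportion > 1) stop("proportion must be in (0, 1]")
  pres <- Reduce(`+`, lapply(subs, function(s) (s$weights > 0) * 1L))
  frac <- pres / length(subs)
  mask <- if (strict) (frac > proportion) * 1L else (frac >= proportion) * 1L
  diag(mask) <- 0L
  masked <- lapply(subs, function(s)
    weighted_connectome(s$weights * mask, s$covariates))
  list(mask = binary_network(mask, geometry), cohort = masked)
}

#' Absolute streamline-count threshold
#'
#' Retains edges whose weight is at least `min_count` (>= convention) and
#' binarizes. The default of 325 streamlines is the count that brings a
#' large neonatal cohort to about 10% mean density.
#'
#' @param connectome a [weighted_connectome()] or weight matrix.
#' @param min_count nonnegative count threshold (default 325).
#' @param geometry optional [node_geometry()] to attach.
#' @return A `binary_network`.
#' @export
threshold_absolute <- function(connectome, min_count = 325, geometry = NULL) {
  if (min_count < 0) stop("min_count must be nonnegative")
  w <- if (inherits(connectome, "weighted_connectome")) connectome$weights
       else as.matrix(connectome)
  a <- (w >= min_count & w > 0) * 1L
  diag(a) <- 0L
  binary_network(a, geometry)
}

#' Density-controlled threshold
#'
#' Retains the strongest edges until the target density is reached:
#' `round(target_density * N(N-1)/2)` edges (base-R round, half to even:
#' a 90-node network at 10% density keeps exactly 400 of 4005 pairs).
#' Ties at the cutoff are broken deterministically by higher weight, then
#' lexicographic node pair, so repeated runs give identical networks.
#'
#' @param connectome a [weighted_connectome()] or weight matrix.
#' @param target_density desired edge density in (0, 1].
#' @param geometry optional [node_geometry()] to attach.
#' @return A `binary_network` with exactly the target edge count.
#' @export
threshold_to_density <- function(connectome, target_density = 0.10,
                                 geometry = NULL) {
  if (target_density <= 0 || target_density > 1)
    stop("target_density must be in (0, 1]")
  w <- if (inherits(connectome, "weighted_connectome")) connectome$weights
       else as.matrix(connectome)
  n <- nrow(w)
  n_pairs <- n * (n - 1) / 2
  m_target <- round(target_density * n_pairs)
  ut <- which(upper.tri(w), arr.ind = TRUE)
  wt <- w[ut]
  pos <- wt > 0
  if (sum(pos) < m_target)
    stop(sprintf(paste0("cannot reach density %.3f: %d nonzero edges ",
                        "available, %d required"),
                 target_density, sum(pos), m_target))
  ord <- order(-wt, ut[, 1L], ut[, 2L])
  keep <- ord[seq_len(m_target)]
  a <- matrix(0L, n, n)
  a[ut[keep, , drop = FALSE]] <- 1L
  a <- a + t(a)
  binary_network(a, geometry)
}

#' Find the absolute threshold for a target mean density
#'
#' Scans integer count thresholds (cohort mean density is non-increasing
#' in the threshold) and returns the smallest `min_count` whose mean
#' density across subjects is at or below the target.
#'
#' @param cohort a `cohort` or list of [weighted_connectome()]s.
#' @param target_mean_density desired mean density across subjects.
#' @return List: `min_count`, `mean_density` achieved, and the per-subject
#'   `densities` at that threshold.
#' @export
find_absolute_threshold_for_mean_density <- function(cohort,
                                                     target_mean_density = 0.10) {
  subs <- if (inherits(cohort, "cohort")) cohort$subjects else cohort
  if (length(subs) == 0L) stop("empty cohort")
  mean_density_at <- function(t) {
    mean(vapply(subs, function(s)
      network_density(threshold_absolute(s, t)), 0.0))
  }
  if (mean_density_at(0) <= target_mean_density)
    return(list(min_count = 0L, mean_density = mean_density_at(0),
                densities = vapply(subs, function(s)
                  network_density(threshold_absolute(s, 0L)), 0.0)))
  hi <- max(vapply(subs, function(s) max(s$weights), 0.0)) + 1
  if (mean_density_at(hi) > target_mean_density)
    stop("target mean density unreachable at any threshold")
  lo <- 0
  # binary search for the smallest threshold with mean density <= target
  while (hi - lo > 1) {
    mid <- floor((lo + hi) / 2)
    if (mean_density_at(mid) <= target_mean_density) hi <- mid else lo <- mid
  }
  list(min_count = as.integer(hi), mean_density = mean_density_at(hi),
       densities = vapply(subs, function(s)
         network_density(threshold_absolute(s, hi)), 0.0))
}

#' Length-distribution-preserving group consensus network
#'
#' Builds a single representative binary network whose connection-length
#' distribution matches the subjects'. Candidate edges are binned by
#' Euclidean length (equal-count bins; intra- and inter-hemispheric pairs
#' binned separately when hemisphere labels are available), and within
#' each bin the most prevalent edges are kept, as many as the rounded
#' subject-mean edge count of that bin. A plain prevalence consensus
#' (`n_bins = 1` and no hemisphere split) over-represents short edges;
#' binning preserves the long tail.
#'
#' @param cohort_binary list of `binary_network`s on one geometry.
#' @param distances Euclidean distance matrix; defaults to the geometry
#'   carried by the first subject.
#' @param n_bins number of equal-count distance bins (default 10).
#' @param split_hemispheres bin intra- and inter-hemispheric candidate
#'   pairs separately (default `TRUE` when hemisphere labels exist).
#' @return A `binary_network`.
#' @export
build_consensus_network <- function(cohort_binary, distances = NULL,
                                    n_bins = 10L,
                                    split_hemispheres = NULL) {
  if (length(cohort_binary) == 0L) stop("empty cohort")
  if (n_bins < 1L) stop("n_bins must be >= 1")
  geometry <- cohort_binary[[1L]]$geometry
  if (is.null(distances)) {
    if (is.null(geometry)) stop("distances required when networks carry no geometry")
    distances <- geometry$dist
  }
  if (is.null(split_hemispheres)) split_hemispheres <- !is.null(geometry)
  mats <- lapply(cohort_binary, as_adjacency)
  n <- nrow(mats[[1L]])
  prevalence <- Reduce(`+`, mats) / length(mats)

  ut <- which(upper.tri(prevalence), arr.ind = TRUE)
  cand <- prevalence[ut] > 0
  df <- data.frame(i = ut[cand, 1L], j = ut[cand, 2L],
                   prev = prevalence[ut][cand],
                   d = distances[ut][cand])
  if (split_hemispheres) {
    h <- geometry$hemisphere
    df$strat <- ifelse(h[df$i] == h[df$j], "intra", "inter")
  } else df$strat <- "all"

  # per-subject edge presence on the candidate list, for bin-mean counts
  pres <- vapply(mats, function(a) a[cbind(df$i, df$j)], integer(nrow(df)))
  pres <- matrix(pres, nrow = nrow(df))

  a <- matrix(0L, n, n)
  for (st in unique(df$strat)) {
    rows <- which(df$strat == st)
    dsub <- df[rows, , drop = FALSE]
    nb <- min(n_bins, length(unique(dsub$d)))
    brk <- unique(quantile(dsub$d, probs = seq(0, 1, length.out = nb + 1)))
    bin <- cut(dsub$d, breaks = brk, include.lowest = TRUE, labels = FALSE)
    for (b in unique(bin)) {
      brows <- rows[bin == b]
      # expected number of edges a subject places in this bin
      target <- round_half_up(mean(colSums(pres[brows, , drop = FALSE])))
      if (target <= 0) next
      if (target > length(brows)) {
        warning(sprintf("bin needs %d edges but has %d candidates; taking all",
                        target, length(brows)))
        target <- length(brows)
      }
      bd <- df[brows, , drop = FALSE]
      ord <- order(-bd$prev, bd$d, bd$i, bd$j)
      sel <- brows[ord[seq_len(target)]]
      a[cbind(df$i[sel], df$j[sel])] <- 1L
    }
  }
  a <- a + t(a)
  binary_network(a, geometry)
}

#' Threshold report for a cohort
#'
#' Records per-subject densities before and after a thresholding step.
#'
#' @param before,after lists of weighted connectomes / binary networks in
#'   matching order.
#' @param step character label of the step.
#' @param value threshold value applied.
#' @return List with the step label, value and per-subject densities.
#' @export
threshold_report <- function(before, after, step, value) {
  dens <- function(x) {
    if (inherits(x, "weighted_connectome")) {
      a <- (x$weights > 0) * 1L; diag(a) <- 0L
      network_density(a)
    } else network_density(x)
  }
  list(step = step, value = value,
       density_before = vapply(before, dens, 0.0),
       density_after = vapply(after, dens, 0.0))
}
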