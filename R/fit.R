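#' Two-sample Kolmogorov-Smirnov statistic
#'
#' Sup-distance between the empirical CDFs of two samples. Used as the
#' building block of the model-fit energy; returned on its natural
#' `[0, 1]` scale with no significance machinery.
#'
#' @param sample_a,sample_b nonempty numeric vectors.
#' @export
ks_statistic <- function(sample_a, sample_b) {
  if (!length(sample_a) || !length(sample_b)) stop("samples must be nonempty")
  pts <- sort(unique(c(sample_a, sample_b)))
  fa <- vapply(pts, function(x) mean(sample_a <= x), 0.0)
  fb <- vapply(pts, function(x) mean(sample_b <= x), 0.0)
  max(abs(fa - fb))
}

# The four nodal samples entering the energy. `ks_edge` switches the
# edge-length sample between the nodal total-length measure and the raw
# per-edge length list (conventions vary across the literature).
energy_samples <- function(network, distances, ks_edge = "nodal") {
  a <- as_adjacency(network)
  g <- as_igraph(a)
  d <- as.matrix(distances)
  lengths <- if (ks_edge == "nodal") rowSums(a * d) else d[edge_list(a)]
  if (!length(lengths)) lengths <- 0
  list(degree = as.numeric(colSums(a)),
       clustering = igraph::transitivity(g, type = "localundirected",
                                         isolates = "zero"),
       betweenness = igraph::betweenness(g, directed = FALSE, weights = NA),
       edge_length = as.numeric(lengths))
}

#' Model-fit energy between two networks
#'
#' The energy is the maximum of four KS statistics comparing the
#' distributions of degree, clustering coefficient, betweenness
#' centrality and edge length between an observed and a simulated
#' network: `E = max(KS_k, KS_c, KS_b, KS_e)`. Lower is better; identical
#' networks have energy 0.
#'
#' @param observed,simulated `binary_network`s (or adjacency matrices) on
#'   the same node set.
#' @param distances Euclidean distance matrix.
#' @param ks_edge `"nodal"` (default) compares nodal total edge lengths;
#'   `"edgewise"` compares the per-edge length lists.
#' @return Named numeric vector: `energy`, `ks_degree`, `ks_clustering`,
#'   `ks_betweenness`, `ks_edge_length`.
#' @export
energy <- function(observed, simulated, distances,
                   ks_edge = c("nodal", "edgewise")) {
  ks_edge <- match.arg(ks_edge)
  ao <- as_adjacency(observed)
  as_ <- as_adjacency(simulated)
  if (nrow(ao) != nrow(as_)) stop("networks must share one node set")
  so <- energy_samples(ao, distances, ks_edge)
  ss <- energy_samples(as_, distances, ks_edge)
  ks <- c(ks_degree = ks_statistic(so$degree, ss$degree),
          ks_clustering = ks_statistic(so$clustering, ss$clustering),
          ks_betweenness = ks_statistic(so$betweenness, ss$betweenness),
          ks_edge_length = ks_statistic(so$edge_length, ss$edge_length))
  c(energy = max(ks), ks)
}

#' Evenly spaced parameter grid
#'
#' @param eta_bounds,gamma_bounds length-2 ranges (inclusive).
#' @param n_eta,n_gamma points per axis; bounds are included when n > 1,
#'   a single point sits at the midpoint.
#' @return data frame of class `parameter_grid` with columns `eta`,
#'   `gamma` (row order: eta varies fastest).
#' @export
make_grid <- function(eta_bounds = c(-3, 0), gamma_bounds = c(0.1, 0.6),
                      n_eta = 20L, n_gamma = 20L) {
  axis_points <- function(b, k) {
    if (any(!is.finite(b))) stop("bounds must be finite")
    if (k < 1L) stop("grid axis needs at least one point")
    if (k == 1L) return(mean(b))
    if (b[1L] == b[2L]) stop("degenerate bounds with more than one point")
    seq(b[1L], b[2L], length.out = k)
  }
  g <- expand.grid(eta = axis_points(eta_bounds, n_eta),
                   gamma = axis_points(gamma_bounds, n_gamma))
  structure(g, class = c("parameter_grid", "data.frame"),
            eta_bounds = eta_bounds, gamma_bounds = gamma_bounds)
}

#' Fit a generative network model by grid search
#'
#' For every (eta, gamma) on the grid, one network is grown from the seed
#' to the observed edge count and scored with the max-KS [energy()]; the
#' best fit is the grid point of minimum energy (ties broken by smaller
#' `|eta|`, then smaller `gamma`). The full energy landscape is retained.
#' At the best fit, the topological-fingerprint dissimilarity and
#' per-measure spatial-embedding correlations between observed and
#' simulated networks are computed.
#'
#' @param observed observed `binary_network` (or adjacency matrix).
#' @param distances Euclidean distance matrix; defaults to the observed
#'   network's geometry.
#' @param seed seed network contained in every simulation; default empty.
#' @param rule value rule, one of [gnm_rules()].
#' @param grid a [make_grid()] data frame (default: 20 x 20 over
#'   -3 <= eta <= 0, 0.1 <= gamma <= 0.6, the usual refined homophily
#'   region).
#' @param epsilon offset added to the value term, see [gnm_spec()].
#' @param ks_edge edge-length convention passed to [energy()].
#' @param nreps simulations per grid point (default 1; energies are
#'   averaged over replicates).
#' @return An object of class `gnm_fit` with elements `landscape` (data
#'   frame: eta, gamma, energy and the four KS components), `best`
#'   (row of the landscape), `best_network`, `best_trace`,
#'   `tf_dissimilarity`, `spatial_embedding`, plus the call ingredients.
#' @seealso [coef.gnm_fit()], [simulate.gnm_fit()], [plot.gnm_fit()]
#' @export
gnm_fit <- function(observed, distances = NULL, seed = NULL,
                    rule = "matching", grid = make_grid(),
                    epsilon = 1e-5, ks_edge = c("nodal", "edgewise"),
                    nreps = 1L) {
  ks_edge <- match.arg(ks_edge)
  rule <- match.arg(rule, gnm_rules())
  ao <- as_adjacency(observed)
  n <- nrow(ao)
  if (is.null(distances)) distances <- distance_matrix(observed)
  distances <- as.matrix(distances)
  if (is.null(seed)) seed <- matrix(0L, n, n)
  as_seed <- as_adjacency(seed)
  m_obs <- edge_count(ao)
  if (m_obs < edge_count(as_seed))
    stop("observed network has fewer edges than the seed")

  obs_samples <- energy_samples(ao, distances, ks_edge)
  npt <- nrow(grid)
  land <- matrix(NA_real_, npt, 5L,
                 dimnames = list(NULL, c("energy", "ks_degree",
                                         "ks_clustering", "ks_betweenness",
                                         "ks_edge_length")))
  best_E <- Inf
  best_idx <- NA_integer_
  best_sim <- NULL
  for (p in seq_len(npt)) {
    spec <- gnm_spec(rule, grid$eta[p], grid$gamma[p], epsilon)
    acc <- numeric(5L)
    sim <- NULL
    for (r in seq_len(nreps)) {
      tr <- grow_network(as_seed, distances, spec, m_obs)
      ss <- energy_samples(tr$network$adjacency, distances, ks_edge)
      ks <- c(ks_statistic(obs_samples$degree, ss$degree),
              ks_statistic(obs_samples$clustering, ss$clustering),
              ks_statistic(obs_samples$betweenness, ss$betweenness),
              ks_statistic(obs_samples$edge_length, ss$edge_length))
      acc <- acc + c(max(ks), ks)
      sim <- tr
    }
    land[p, ] <- acc / nreps
    # ties: smaller |eta|, then smaller gamma (documented convention)
    if (land[p, 1L] < best_E - 1e-15 ||
        (abs(land[p, 1L] - best_E) <= 1e-15 && !is.na(best_idx) &&
         (abs(grid$eta[p]) < abs(grid$eta[best_idx]) - 1e-15 ||
          (abs(abs(grid$eta[p]) - abs(grid$eta[best_idx])) <= 1e-15 &&
           grid$gamma[p] < grid$gamma[best_idx])))) {
      best_E <- land[p, 1L]
      best_idx <- p
      best_sim <- sim
    }
  }
  landscape <- cbind(as.data.frame(grid), as.data.frame(land))

  tf_obs <- topological_fingerprint(ao, distances)
  tf_sim <- topological_fingerprint(best_sim$network$adjacency, distances)
  lm_obs <- local_measures(ao, distances)
  lm_sim <- local_measures(best_sim$network$adjacency, distances)
  structure(list(landscape = landscape,
                 best = landscape[best_idx, , drop = FALSE],
                 best_network = best_sim$network,
                 best_trace = best_sim$trace,
                 tf_dissimilarity = tf_dissimilarity(tf_obs, tf_sim),
                 spatial_embedding = spatial_embedding(lm_obs, lm_sim),
                 observed = binary_network(ao),
                 distances = distances, seed = as_seed,
                 rule = rule, grid = grid, epsilon = epsilon,
                 ks_edge = ks_edge, nreps = nreps),
            class = "gnm_fit")
}

#' @export
print.gnm_fit <- function(x, ...) {
  cat("Generative network model fit (rule:", sQuote(x$rule), ")\n")
  cat(sprintf("  grid: %d points; observed edges: %d\n",
              nrow(x$landscape), edge_count(x$observed)))
  cat(sprintf("  best fit: eta = %.4g, gamma = %.4g, energy = %.4f\n",
              x$best$eta, x$best$gamma, x$best$energy))
  invisible(x)
}

#' @export
summary.gnm_fit <- function(object, ...) {
  b <- object$best
  cat("Generative network model fit\n")
  cat("  rule:           ", object$rule, "\n")
  cat("  grid points:    ", nrow(object$landscape), "\n")
  cat(sprintf("  best (eta, gamma): (%.4g, %.4g)\n", b$eta, b$gamma))
  cat(sprintf("  energy: %.4f  (KS k %.3f, c %.3f, b %.3f, e %.3f)\n",
              b$energy, b$ks_degree, b$ks_clustering, b$ks_betweenness,
              b$ks_edge_length))
  cat(sprintf("  TF dissimilarity at best fit: %.4f\n",
              object$tf_dissimilarity))
  cat("  spatial embedding (Pearson r by measure):\n")
  print(round(object$spatial_embedding, 3))
  invisible(object)
}

#' @export
coef.gnm_fit <- function(object, ...) {
  c(eta = object$best$eta, gamma = object$best$gamma)
}

#' Simulate networks at the fitted parameters
#'
#' @param object a [gnm_fit()] object.
#' @param nsim number of networks to grow.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return List of `growth_trace` objects.
#' @export
simulate.gnm_fit <- function(object, nsim = 1, seed = NULL, ...) {
  with_seed(seed, {
    spec <- gnm_spec(object$rule, object$best$eta, object$best$gamma,
                     object$epsilon)
    m <- edge_count(object$observed)
    lapply(seq_len(nsim), function(i)
      grow_network(object$seed, object$distances, spec, m))
  })
}

#' Energy landscape heat map
#'
#' @param x a [gnm_fit()] object.
#' @param ... passed to [graphics::image()].
#' @export
plot.gnm_fit <- function(x, ...) {
  etas <- sort(unique(x$landscape$eta))
  gammas <- sort(unique(x$landscape$gamma))
  z <- matrix(NA_real_, length(etas), length(gammas))
  z[cbind(match(x$landscape$eta, etas), match(x$landscape$gamma, gammas))] <-
    x$landscape$energy
  image(etas, gammas, z, xlab = expression(eta), ylab = expression(gamma),
        col = hcl.colors(64, "viridis", rev = TRUE),
        main = sprintf("Energy landscape (%s)", x$rule), ...)
  points(x$best$eta, x$best$gamma, pch = 21, bg = "green", cex = 1.4)
  invisible(x)
}

#' Topological fingerprint of a network
#'
#' Pairwise Pearson correlation matrix of the six local measures (degree,
#' clustering, betweenness, nodal edge length, local efficiency,
#' matching) across nodes. Measures with zero variance get correlation 0
#' by convention (with a warning), keeping the fingerprint defined on
#' degenerate networks; the diagonal stays 1.
#'
#' @param network a `binary_network` or adjacency matrix.
#' @param distances Euclidean distance matrix.
#' @return 6 x 6 symmetric correlation matrix.
#' @export
topological_fingerprint <- function(network, distances = NULL) {
  lm <- local_measures(network, distances)
  x <- as.matrix(lm[, c("degree", "clustering", "betweenness",
                        "nodal_edge_length", "local_efficiency",
                        "matching")])
  sds <- apply(x, 2L, sd)
  tf <- suppressWarnings(cor(x))
  if (any(sds == 0)) {
    warning("zero-variance measure(s) in fingerprint: ",
            paste(colnames(x)[sds == 0], collapse = ", "),
            "; correlations set to 0")
    tf[sds == 0, ] <- 0
    tf[, sds == 0] <- 0
  }
  tf[is.na(tf)] <- 0
  diag(tf) <- 1
  tf
}

#' Dissimilarity between two topological fingerprints
#'
#' Euclidean (Frobenius) norm of the entrywise difference:
#' `sqrt(sum((TF_a - TF_b)^2))`.
#'
#' @param tf_a,tf_b equal-sized fingerprint matrices.
#' @export
tf_dissimilarity <- function(tf_a, tf_b) {
  if (!all(dim(tf_a) == dim(tf_b))) stop("fingerprints differ in shape")
  sqrt(sum((tf_a - tf_b)^2))
}

#' Spatial embedding of simulated local measures
#'
#' Node-wise Pearson correlation between observed and simulated local
#' measures: does the simulation place high-degree (etc.) nodes where the
#' observed network has them? Zero-variance measures yield `NA`.
#'
#' @param observed_local,simulated_local data frames from
#'   [local_measures()] with aligned node order.
#' @return Named numeric vector of correlations, one per measure.
#' @export
spatial_embedding <- function(observed_local, simulated_local) {
  meas <- c("degree", "clustering", "betweenness", "nodal_edge_length",
            "local_efficiency", "matching")
  if (nrow(observed_local) != nrow(simulated_local))
    stop("node sets differ")
  out <- vapply(meas, function(m) {
    a <- observed_local[[m]]
    b <- simulated_local[[m]]
    if (sd(a) == 0 || sd(b) == 0 || anyNA(a) || anyNA(b)) return(NA_real_)
    cor(a, b)
  }, 0.0)
  out
}

#' Bootstrap summary of per-subject spatial-embedding correlations
#'
#' @param correlations numeric vector (one correlation per subject).
#' @param n_boot bootstrap resamples for the confidence interval.
#' @param conf confidence level.
#' @return Named vector: mean, lower, upper, n.
#' @export
spatial_embedding_summary <- function(correlations, n_boot = 2000,
                                      conf = 0.95) {
  r <- correlations[!is.na(correlations)]
  if (!length(r)) return(c(mean = NA, lower = NA, upper = NA, n = 0))
  boots <- vapply(seq_len(n_boot), function(i)
    mean(sample(r, replace = TRUE)), 0.0)
  qs <- quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2))
  c(mean = mean(r), lower = unname(qs[1L]), upper = unname(qs[2L]),
    n = length(r))
}
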