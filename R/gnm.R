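#' The registered generative value rules
#'
#' Thirteen topological "value" terms k_ij used in the wiring equation
#' p_ij proportional to d_ij^eta * k_ij^gamma:
#'
#' * `spatial`: k = 1 everywhere (pure distance model).
#' * `neighbors`: number of neighbours shared by the two nodes.
#' * `matching`: shared neighbours divided by the union of the two
#'   neighbourhoods, excluding the pair itself (normalised `neighbors`).
#' * `clu-avg`, `clu-min`, `clu-max`, `clu-diff`, `clu-prod`: the named
#'   reduction (mean, min, max, absolute difference, product) of the two
#'   endpoints' local clustering coefficients.
#' * `deg-avg`, `deg-min`, `deg-max`, `deg-diff`, `deg-prod`: the same
#'   reductions applied to the endpoints' degrees.
#'
#' @return Character vector of rule names.
#' @export
gnm_rules <- function() {
  c("spatial", "neighbors", "matching",
    "clu-avg", "clu-min", "clu-max", "clu-diff", "clu-prod",
    "deg-avg", "deg-min", "deg-max", "deg-diff", "deg-prod")
}

#' Generative model specification
#'
#' @param rule one of [gnm_rules()].
#' @param eta cost exponent on Euclidean distance; negative values favour
#'   short-range connections.
#' @param gamma value exponent; weighs the topological value term.
#' @param epsilon small positive offset added to k before exponentiation so
#'   zero-value pairs stay reachable (default 1e-5).
#' @return An object of class `gnm_spec`.
#' @export
gnm_spec <- function(rule = "matching", eta = -1.74, gamma = 0.32,
                     epsilon = 1e-5) {
  rule <- match.arg(rule, gnm_rules())
  if (!is.finite(eta) || !is.finite(gamma)) stop("eta and gamma must be finite")
  if (epsilon <= 0) stop("epsilon must be positive")
  structure(list(rule = rule, eta = eta, gamma = gamma, epsilon = epsilon),
            class = "gnm_spec")
}

#' @export
print.gnm_spec <- function(x, ...) {
  cat(sprintf("GNM spec: rule '%s', eta = %g, gamma = %g, epsilon = %g\n",
              x$rule, x$eta, x$gamma, x$epsilon))
  invisible(x)
}

#' Topological value matrix of a binary network
#'
#' Evaluates one of the 13 registered value rules on the current adjacency.
#' The same implementation drives every growth iteration, so rule tests
#' here exercise the engine itself.
#'
#' @param network a `binary_network` or adjacency matrix.
#' @param rule one of [gnm_rules()].
#' @return N x N nonnegative symmetric matrix; diagonal is zero.
#' @export
value_matrix <- function(network, rule = "matching") {
  if (length(rule) != 1L || !rule %in% gnm_rules())
    stop("unknown value rule: ", rule)
  a <- as_adjacency(network)
  k <- value_matrix_cpp(a, rule)
  dimnames(k) <- dimnames(a)
  k
}

#' Matching index matrix
#'
#' Normalised neighbourhood overlap of all node pairs: shared neighbours
#' divided by the union of both neighbourhoods excluding the pair itself.
#' This single implementation is shared by the graph measures and the
#' generative engine.
#'
#' @inheritParams value_matrix
#' @export
matching_index <- function(network) {
  value_matrix(network, "matching")
}

#' Wiring probabilities over absent edges
#'
#' For each unconnected pair (i, j) the score is
#' `d_ij^eta * (k_ij + epsilon)^gamma`; probabilities are the scores
#' normalised to sum to one over absent pairs. Existing edges and self
#' pairs have probability zero.
#'
#' @param distances positive off-diagonal Euclidean distance matrix.
#' @param k value matrix (from [value_matrix()]).
#' @param spec a [gnm_spec()].
#' @param adjacency current adjacency (`binary_network` or matrix).
#' @return Symmetric N x N matrix; entry (i, j) is the selection
#'   probability of the unordered pair, so the upper triangle sums to 1.
#' @export
wiring_probabilities <- function(distances, k, spec, adjacency) {
  a <- as_adjacency(adjacency)
  n <- nrow(a)
  if (any(distances[row(distances) != col(distances)] <= 0))
    stop("off-diagonal distances must be positive")
  # log-space for numerical safety at extreme exponents
  ls <- spec$eta * log(distances) + spec$gamma * log(k + spec$epsilon)
  ls[a == 1L] <- -Inf
  diag(ls) <- -Inf
  mx <- max(ls)
  if (!is.finite(mx)) stop("no absent pairs with positive score")
  s <- exp(ls - mx)
  s / (sum(s) / 2)  # each unordered pair appears in both triangles
}

#' Grow a network under the generative model
#'
#' Starting from a seed network, adds one edge per iteration: all absent
#' pairs are scored by distance cost and topological value, one pair is
#' drawn from the normalised scores, and the value term is recomputed
#' before the next addition. The seed is immutable and is contained in
#' every grown network. Sampling uses inverse-CDF over a deterministic
#' pair ordering, so traces are reproducible given the R RNG state.
#'
#' @param seed seed `binary_network` (or adjacency); may be empty.
#' @param distances Euclidean distance matrix.
#' @param spec a [gnm_spec()].
#' @param m_target total edge count to grow to (seed edges included).
#' @return An object of class `growth_trace`: list with `network` (the
#'   final `binary_network`), `trace` (data frame: iteration, from, to,
#'   prob, length), and `m_seed`.
#' @examples
#' g <- generate_geometry(20, seed = 1)
#' tr <- grow_network(matrix(0, 20, 20), distance_matrix(g),
#'                    gnm_spec("matching", -2, 0.3), m_target = 30)
#' tr$network
#' @export
grow_network <- function(seed, distances, spec, m_target) {
  a <- as_adjacency(seed)
  geometry <- if (inherits(seed, "binary_network")) seed$geometry else NULL
  if (!inherits(spec, "gnm_spec")) stop("spec must be a gnm_spec")
  res <- grow_network_cpp(a, as.matrix(distances), spec$rule,
                          spec$eta, spec$gamma, spec$epsilon,
                          as.integer(m_target))
  n_add <- nrow(res$edges)
  trace <- data.frame(iteration = seq_len(n_add),
                      from = res$edges[, 1L], to = res$edges[, 2L],
                      prob = res$stats[, 1L], length = res$stats[, 2L])
  structure(list(network = binary_network(res$adjacency, geometry),
                 trace = trace, m_seed = res$m_seed, spec = spec),
            class = "growth_trace")
}

#' @export
print.growth_trace <- function(x, ...) {
  cat("Growth trace:", nrow(x$trace), "edges added to a", x$m_seed,
      "edge seed under rule", sQuote(x$spec$rule), "\n")
  invisible(x)
}

#' Derive a seed network from a binarized cohort
#'
#' Edges present in at least `prevalence` of subjects form the seed from
#' which all simulations grow. The default 0.95 keeps only near-universal
#' connections, yielding a sparse common scaffold.
#'
#' @param cohort_binary list of `binary_network`s on one geometry.
#' @param prevalence fraction of subjects required (default 0.95); the
#'   comparison is `>=`.
#' @return A `binary_network` (possibly empty, with a message).
#' @export
derive_seed_network <- function(cohort_binary, prevalence = 0.95) {
  if (length(cohort_binary) == 0L) stop("empty cohort")
  if (prevalence <= 0 || prevalence > 1) stop("prevalence must be in (0, 1]")
  mats <- lapply(cohort_binary, as_adjacency)
  n <- nrow(mats[[1L]])
  if (!all(vapply(mats, nrow, 1L) == n))
    stop("all subjects must share one geometry")
  presence <- Reduce(`+`, mats) / length(mats)
  seed <- ifelse(presence >= prevalence, 1L, 0L)
  geometry <- cohort_binary[[1L]]$geometry
  net <- binary_network(seed, geometry)
  if (edge_count(net) == 0L)
    message("seed network is empty; growth will start from no edges")
  net
}
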