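#' Degree-preserving network randomization
#'
#' Double-edge-swap rewiring that preserves every node's degree exactly
#' while randomising topology; the standard null model for rich-club
#' normalization. Attempts `iterations_per_edge * m` swaps; picks without
#' a valid swap are skipped, so networks admitting no swap (e.g. stars)
#' are returned unchanged.
#'
#' @param network a `binary_network` or adjacency matrix.
#' @param iterations_per_edge swap attempts per edge (default 10).
#' @return A `binary_network` with attribute `"swaps"` (number of swaps
#'   performed).
#' @export
rewire_preserving_degree <- function(network, iterations_per_edge = 10) {
  a <- as_adjacency(network)
  geometry <- if (inherits(network, "binary_network")) network$geometry else NULL
  m <- sum(a) / 2
  res <- rewire_cpp(a, as.integer(ceiling(iterations_per_edge * m)))
  out <- binary_network(res$adjacency, geometry)
  attr(out, "swaps") <- res$swaps
  out
}

# phi(k) for all degree levels k = 0 .. max(deg)-1 over subgraphs of
# nodes with degree strictly greater than k. Vectorised: an edge survives
# level k iff min(deg_i, deg_j) > k.
rich_club_curve <- function(a) {
  deg <- colSums(a)
  kmax <- max(deg)
  if (kmax < 1) return(data.frame(k = integer(), n_nodes = integer(),
                                  n_edges = integer(), phi = numeric()))
  el <- edge_list(a)
  mindeg <- pmin(deg[el[, 1L]], deg[el[, 2L]])
  ks <- 0:(kmax - 1)
  n_k <- vapply(ks, function(k) sum(deg > k), 0L)
  e_k <- vapply(ks, function(k) sum(mindeg > k), 0L)
  phi <- ifelse(n_k >= 2, e_k / (n_k * (n_k - 1) / 2), NA_real_)
  data.frame(k = ks, n_nodes = n_k, n_edges = e_k, phi = phi)
}

#' Normalized rich-club detection
#'
#' Computes the rich-club coefficient phi(k) over nodes of degree > k,
#' normalises it by the mean coefficient of degree-preserving rewired
#' nulls, and flags levels where the observed coefficient exceeds chance
#' (one-sided empirical p < alpha per level, uncorrected). Contiguous
#' significant levels form candidate clubs; the club with the most nodes
#' is selected and its members (degree >= k*) are the rich nodes.
#'
#' @param network a `binary_network` or adjacency matrix.
#' @param n_nulls number of rewired null networks (default 1000).
#' @param alpha significance level per degree level (default 0.05).
#' @param iterations_per_edge swap attempts per edge per null.
#' @return An object of class `rich_club`: data frame `levels` (k, phi,
#'   null mean/sd, phi_norm, p, significant), `k_star`, `rich_nodes`
#'   (integer indices), and all candidate `clubs`.
#' @export
rich_club <- function(network, n_nulls = 1000, alpha = 0.05,
                      iterations_per_edge = 10) {
  if (n_nulls < 1) stop("n_nulls must be >= 1")
  a <- as_adjacency(network)
  obs <- rich_club_curve(a)
  if (nrow(obs) == 0L)
    return(structure(list(levels = obs, k_star = NA_integer_,
                          rich_nodes = integer(), clubs = list()),
                     class = "rich_club"))
  m <- sum(a) / 2
  null_phi <- matrix(NA_real_, nrow = nrow(obs), ncol = n_nulls)
  for (b in seq_len(n_nulls)) {
    nb <- rewire_cpp(a, as.integer(ceiling(iterations_per_edge * m)))$adjacency
    null_phi[, b] <- rich_club_curve(nb)$phi
  }
  null_mean <- rowMeans(null_phi, na.rm = TRUE)
  null_sd <- apply(null_phi, 1L, sd, na.rm = TRUE)
  # one-sided: how often does a null club coefficient reach the observed?
  p <- rowMeans(null_phi >= obs$phi, na.rm = TRUE)
  p[is.na(obs$phi)] <- NA_real_
  levels <- cbind(obs,
                  null_mean = null_mean, null_sd = null_sd,
                  phi_norm = obs$phi / null_mean, p = p,
                  significant = !is.na(p) & p < alpha)
  sig <- which(levels$significant)
  clubs <- list()
  if (length(sig)) {
    runs <- split(sig, cumsum(c(1, diff(sig) != 1)))
    deg <- colSums(a)
    clubs <- lapply(runs, function(r) {
      k1 <- levels$k[r[1L]]
      list(k_range = levels$k[range(r)], k_star = k1 + 1L,
           nodes = which(deg > k1))
    })
  }
  if (length(clubs)) {
    sizes <- vapply(clubs, function(cl) length(cl$nodes), 0L)
    best <- clubs[[which.max(sizes)]]
    k_star <- best$k_star
    rich_nodes <- best$nodes
  } else {
    k_star <- NA_integer_
    rich_nodes <- integer()
  }
  structure(list(levels = levels, k_star = k_star, rich_nodes = rich_nodes,
                 clubs = clubs),
            class = "rich_club")
}

#' @export
print.rich_club <- function(x, ...) {
  nsig <- sum(x$levels$significant, na.rm = TRUE)
  cat("Rich-club analysis:", nsig, "significant degree levels,",
      length(x$clubs), "candidate club(s)\n")
  if (length(x$rich_nodes))
    cat("Selected club: k* =", x$k_star, "with", length(x$rich_nodes),
        "nodes\n")
  else cat("No significant rich club detected\n")
  invisible(x)
}

#' Classify edges as rich, feeder or local
#'
#' Rich edges join two rich-club nodes, feeder edges join a rich node to
#' a non-rich node, and local edges join two non-rich nodes. Each edge is
#' labeled exactly once.
#'
#' @param network a `binary_network` or adjacency matrix.
#' @param rich_nodes integer indices of rich-club nodes (may be empty).
#' @param distances optional Euclidean distance matrix for edge lengths.
#' @return List with `edges` (data frame: i, j, class, length) and
#'   `summary` (class, count, mean_length; mean length is `NA` for empty
#'   classes).
#' @export
classify_edges <- function(network, rich_nodes, distances = NULL) {
  a <- as_adjacency(network)
  n <- nrow(a)
  if (length(rich_nodes) && (min(rich_nodes) < 1 || max(rich_nodes) > n))
    stop("rich_nodes out of range")
  if (is.null(distances) && inherits(network, "binary_network") &&
      !is.null(network$geometry))
    distances <- network$geometry$dist
  el <- edge_list(a)
  is_rich <- rep(FALSE, n)
  is_rich[rich_nodes] <- TRUE
  n_rich_ends <- (el[, 1L] %in% which(is_rich)) + (el[, 2L] %in% which(is_rich))
  cls <- c("local", "feeder", "rich")[n_rich_ends + 1L]
  len <- if (is.null(distances)) rep(NA_real_, nrow(el))
         else as.matrix(distances)[el]
  edges <- data.frame(i = el[, 1L], j = el[, 2L], class = cls, length = len)
  summary <- data.frame(class = c("rich", "feeder", "local"))
  summary$count <- vapply(summary$class, function(cl) sum(cls == cl), 0L)
  summary$mean_length <- vapply(summary$class, function(cl) {
    v <- len[cls == cl]
    if (length(v)) mean(v) else NA_real_
  }, 0.0)
  list(edges = edges, summary = summary)
}
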