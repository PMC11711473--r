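#' Node geometry for a spatially embedded network
#'
#' Bundles parcel labels, 3D coordinates (mm) and hemisphere assignments,
#' and precomputes the Euclidean distance matrix used as the wiring cost.
#'
#' @param coords numeric matrix with one row per node and columns x, y, z
#'   (millimetres).
#' @param hemisphere character vector of "L"/"R" labels, one per node.
#' @param node_ids optional node labels; defaults to `n1..nN`.
#'
#' @return An object of class `node_geometry`: a list with elements
#'   `node_ids`, `coords`, `hemisphere` and `dist` (the N x N Euclidean
#'   distance matrix).
#' @export
node_geometry <- function(coords, hemisphere, node_ids = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 4L) stop("at least 4 nodes are required")
  if (ncol(coords) != 3L) stop("coords must have three columns (x, y, z)")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  hemisphere <- as.character(hemisphere)
  if (length(hemisphere) != n || !all(hemisphere %in% c("L", "R")))
    stop("hemisphere must be 'L'/'R', one per node")
  if (is.null(node_ids)) node_ids <- paste0("n", seq_len(n))
  d <- as.matrix(stats::dist(coords))
  if (any(d[upper.tri(d)] <= 0))
    stop("duplicated coordinates: all off-diagonal distances must be positive")
  dimnames(d) <- list(node_ids, node_ids)
  rownames(coords) <- node_ids
  colnames(coords) <- c("x", "y", "z")
  structure(list(node_ids = node_ids, coords = coords,
                 hemisphere = hemisphere, dist = d),
            class = "node_geometry")
}

#' @export
print.node_geometry <- function(x, ...) {
  cat("Node geometry:", length(x$node_ids), "nodes (",
      sum(x$hemisphere == "L"), "left /", sum(x$hemisphere == "R"),
      "right )\n")
  cat("Distance range:", round(min(x$dist[upper.tri(x$dist)]), 1), "-",
      round(max(x$dist), 1), "mm\n")
  invisible(x)
}

#' Euclidean distance matrix of a geometry or network
#'
#' @param x a `node_geometry` or any object carrying one in `$geometry`.
#' @return The N x N symmetric distance matrix (mm).
#' @export
distance_matrix <- function(x) {
  if (inherits(x, "node_geometry")) return(x$dist)
  if (!is.null(x$geometry) && inherits(x$geometry, "node_geometry"))
    return(x$geometry$dist)
  stop("no node geometry found")
}

#' Generate a bilateral synthetic node geometry
#'
#' Samples `n_nodes / 2` positions for the right hemisphere and mirrors
#' them through the midsagittal plane (x -> -x), giving two symmetric
#' hemispheric clusters like a bilateral parcellation. Coordinates are in
#' millimetres with a spatial extent comparable to a neonatal brain atlas.
#'
#' @param n_nodes even number of nodes (default 90, a standard whole-brain
#'   parcellation size).
#' @param hemi_offset mean distance (mm) of a hemisphere cluster from the
#'   midline; default 25.
#' @param spread per-axis standard deviations (mm) of node positions,
#'   `c(x, y, z)`; default `c(12, 35, 22)`.
#' @param seed optional integer; when given, generation is reproducible and
#'   the session RNG is left untouched.
#'
#' @return A [node_geometry()] object.
#' @export
generate_geometry <- function(n_nodes = 90L, hemi_offset = 25,
                              spread = c(12, 35, 22), seed = NULL) {
  n_nodes <- as.integer(n_nodes)
  if (n_nodes %% 2L != 0L) stop("n_nodes must be even (bilateral geometry)")
  if (n_nodes < 4L) stop("at least 4 nodes are required")
  if (any(spread <= 0) || hemi_offset <= 0)
    stop("hemi_offset and spread must be positive")
  with_seed(seed, {
    nh <- n_nodes %/% 2L
    repeat {
      x <- abs(rnorm(nh, mean = hemi_offset, sd = spread[1]))
      x <- pmax(x, 1.0)  # keep hemispheres strictly lateralised
      y <- rnorm(nh, 0, spread[2])
      z <- rnorm(nh, 0, spread[3])
      right <- cbind(x, y, z)
      left <- cbind(-x, y, z)
      coords <- rbind(right, left)
      if (!anyDuplicated(coords)) break
    }
    hemisphere <- rep(c("R", "L"), each = nh)
    ids <- c(paste0("R", seq_len(nh)), paste0("L", seq_len(nh)))
    node_geometry(coords, hemisphere, ids)
  })
}
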