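#' Binary network
#'
#' The unit of all topological computation: a symmetric 0/1 adjacency
#' matrix with zero diagonal, optionally carrying its node geometry.
#'
#' @param adjacency square numeric/integer matrix of 0s and 1s; symmetrised
#'   entries must agree.
#' @param geometry optional [node_geometry()].
#' @return An object of class `binary_network` with elements `adjacency`
#'   (integer matrix) and `geometry`.
#' @export
binary_network <- function(adjacency, geometry = NULL) {
  a <- as.matrix(adjacency)
  if (nrow(a) != ncol(a)) stop("adjacency must be square")
  if (!all(a %in% c(0, 1))) stop("adjacency entries must be 0 or 1")
  if (!isTRUE(all.equal(a, t(a)))) stop("adjacency must be symmetric")
  if (any(diag(a) != 0)) stop("adjacency diagonal must be zero")
  if (!is.null(geometry)) {
    if (!inherits(geometry, "node_geometry")) stop("invalid geometry")
    if (nrow(a) != length(geometry$node_ids))
      stop("adjacency size does not match geometry")
  }
  storage.mode(a) <- "integer"
  structure(list(adjacency = a, geometry = geometry),
            class = "binary_network")
}

# Accept a binary_network or a raw adjacency matrix.
as_adjacency <- function(x) {
  if (inherits(x, "binary_network")) return(x$adjacency)
  a <- as.matrix(x)
  storage.mode(a) <- "integer"
  a
}

#' Number of edges of a binary network
#' @param x a `binary_network` or adjacency matrix.
#' @export
edge_count <- function(x) {
  a <- as_adjacency(x)
  sum(a[upper.tri(a)])
}

#' Edge density of a binary network
#' @param x a `binary_network` or adjacency matrix.
#' @return Fraction of realised node pairs, in `[0, 1]`.
#' @export
network_density <- function(x) {
  a <- as_adjacency(x)
  n <- nrow(a)
  edge_count(a) / (n * (n - 1) / 2)
}

#' @export
print.binary_network <- function(x, ...) {
  n <- nrow(x$adjacency)
  cat("Binary network:", n, "nodes,", edge_count(x), "edges (density",
      sprintf("%.3f", network_density(x)), ")\n")
  invisible(x)
}

# Upper-triangle edge list (i < j) of an adjacency matrix.
edge_list <- function(x) {
  a <- as_adjacency(x)
  idx <- which(upper.tri(a) & a == 1L, arr.ind = TRUE)
  idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
}

as_igraph <- function(x) {
  igraph::graph_from_adjacency_matrix(as_adjacency(x), mode = "undirected",
                                      diag = FALSE)
}

#' Weighted streamline-count connectome for one subject
#'
#' @param weights symmetric nonnegative integer matrix of streamline
#'   counts, zero diagonal.
#' @param covariates a [subject_covariates()] object (or NULL).
#' @export
weighted_connectome <- function(weights, covariates = NULL) {
  w <- as.matrix(weights)
  if (nrow(w) != ncol(w)) stop("weights must be square")
  if (any(w < 0)) stop("weights must be nonnegative")
  if (!isTRUE(all.equal(w, t(w)))) stop("weights must be symmetric")
  if (any(diag(w) != 0)) stop("weights diagonal must be zero")
  structure(list(weights = w, covariates = covariates),
            class = "weighted_connectome")
}

#' @export
print.weighted_connectome <- function(x, ...) {
  cat("Weighted connectome:", nrow(x$weights), "nodes,",
      sum(x$weights[upper.tri(x$weights)] > 0), "nonzero edges\n")
  if (!is.null(x$covariates))
    cat("Subject:", x$covariates$subject_id, "(", x$covariates$group,
        ", PMA", x$covariates$pma_weeks, "w )\n")
  invisible(x)
}

#' Subject covariates
#'
#' Scan and birth ages in postmenstrual weeks. Group is derived from
#' gestational age at birth: infants born before 37 weeks are preterm.
#'
#' @param subject_id identifier string.
#' @param pma_weeks postmenstrual age at scan (weeks).
#' @param ga_birth_weeks gestational age at birth (weeks).
#' @param sex "F" or "M".
#' @export
subject_covariates <- function(subject_id, pma_weeks, ga_birth_weeks, sex) {
  if (ga_birth_weeks > pma_weeks)
    stop("gestational age at birth cannot exceed scan age")
  if (!sex %in% c("F", "M")) stop("sex must be 'F' or 'M'")
  structure(list(subject_id = as.character(subject_id),
                 pma_weeks = pma_weeks,
                 ga_birth_weeks = ga_birth_weeks,
                 sex = sex,
                 group = if (ga_birth_weeks >= 37) "term" else "preterm"),
            class = "subject_covariates")
}
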