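#' Write a cohort to plain-text files
#'
#' The on-disk layout is also the ingest contract for real data:
#' `coordinates.tsv` (node_id, x, y, z, hemisphere), `covariates.csv`
#' (subject_id, pma, ga_birth, sex, group) and one whitespace-delimited
#' square count matrix per subject (`<subject_id>.txt`).
#'
#' @param cohort a `cohort` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  geo <- cohort$geometry
  coords <- data.frame(node_id = geo$node_ids, geo$coords,
                       hemisphere = geo$hemisphere)
  write.table(coords, file.path(dir, "coordinates.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.csv(covariate_table(cohort), file.path(dir, "covariates.csv"),
            row.names = FALSE, quote = FALSE)
  for (s in cohort$subjects) {
    write.table(s$weights,
                file.path(dir, paste0(s$covariates$subject_id, ".txt")),
                row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' Read a cohort from plain-text files
#'
#' Inverse of [write_cohort()].
#'
#' @param dir directory produced by [write_cohort()] (or hand-assembled
#'   in the same layout).
#' @return A `cohort` object (without a generative `spec`).
#' @export
read_cohort <- function(dir) {
  coords <- read.table(file.path(dir, "coordinates.tsv"), sep = "\t",
                       header = TRUE, stringsAsFactors = FALSE)
  geo <- node_geometry(as.matrix(coords[, c("x", "y", "z")]),
                       coords$hemisphere, coords$node_id)
  cov <- read.csv(file.path(dir, "covariates.csv"),
                  stringsAsFactors = FALSE)
  subjects <- lapply(seq_len(nrow(cov)), function(i) {
    w <- as.matrix(read.table(file.path(dir, paste0(cov$subject_id[i],
                                                    ".txt"))))
    dimnames(w) <- NULL
    weighted_connectome(w, subject_covariates(cov$subject_id[i],
                                              cov$pma[i], cov$ga_birth[i],
                                              cov$sex[i]))
  })
  structure(list(geometry = geo, seed_network = NULL, subjects = subjects,
                 spec = NULL),
            class = "cohort")
}

#' Write a binary network as a TSV edge list
#'
#' @param network a `binary_network`.
#' @param path output file; columns node_i, node_j (indices, i < j).
#' @export
write_edge_list <- function(network, path) {
  el <- edge_list(network)
  write.table(data.frame(node_i = el[, 1L], node_j = el[, 2L]), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a threshold report as JSON
#'
#' @param report list of per-step reports (see the construction
#'   functions).
#' @param path output JSON path.
#' @export
write_threshold_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
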