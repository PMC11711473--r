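#' Pipeline configuration
#'
#' Declarative description of an end-to-end run. Every study constant
#' (60% consensus, 325-count threshold, 10% density, 95% seed prevalence,
#' 1000 rich-club nulls, alpha 0.05, grid bounds) is a named default
#' here, never hard-coded downstream.
#'
#' @param synthetic a [cohort_spec()] to simulate, or `NULL` to read a
#'   cohort from `input_dir`.
#' @param input_dir directory in the [write_cohort()] layout (used when
#'   `synthetic` is `NULL`).
#' @param out_dir output directory.
#' @param consensus_proportion consensus-mask prevalence (default 0.6).
#' @param absolute_threshold streamline-count threshold for the
#'   variable-density analysis; `NULL` tunes it to `target_density` via
#'   [find_absolute_threshold_for_mean_density()] (default 325).
#' @param target_density density for the density-controlled analysis and
#'   for threshold tuning (default 0.10).
#' @param seed_prevalence seed-network prevalence (default 0.95).
#' @param consensus_bins distance bins for the group consensus network.
#' @param rich_nulls,rich_alpha rich-club null count and level.
#' @param fit_rule,fit_grid rule and [make_grid()] for per-subject fits;
#'   `fit_subjects` caps how many subjects are fit (`Inf` = all);
#'   `fit_enabled` turns the stage off.
#' @param group_runs runs per group for the representative experiment
#'   (default 1000); `group_enabled` turns the stage off.
#' @param rng_seed master seed for all stochastic stages.
#' @return An object of class `run_config`.
#' @export
run_config <- function(synthetic = cohort_spec(), input_dir = NULL,
                       out_dir = tempfile("wiregrow-run-"),
                       consensus_proportion = 0.6,
                       absolute_threshold = 325,
                       target_density = 0.10,
                       seed_prevalence = 0.95,
                       consensus_bins = 10L,
                       rich_nulls = 1000L, rich_alpha = 0.05,
                       fit_rule = "matching",
                       fit_grid = make_grid(c(-3, 0), c(0.1, 0.6), 10L, 10L),
                       fit_subjects = Inf, fit_enabled = TRUE,
                       group_runs = 1000L, group_enabled = TRUE,
                       rng_seed = 1L) {
  if (is.null(synthetic) && is.null(input_dir))
    stop("either a synthetic spec or an input directory is required")
  if (!is.null(input_dir) && !dir.exists(input_dir))
    stop("input_dir does not exist: ", input_dir)
  structure(as.list(environment()), class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Stages: cohort (synthesize or load) -> consensus mask -> variable- and
#' controlled-density thresholding -> group consensus network -> rich
#' club -> per-subject topology tables -> per-subject model fits ->
#' representative group experiment. Stage outputs are written as
#' TSV/CSV/JSON under `config$out_dir` together with a manifest recording
#' parameters, seeds and file checksums; reruns of the same config are
#' byte-identical.
#'
#' @param config a [run_config()].
#' @return The manifest list, invisibly; all artifacts on disk.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("wiregrow")),
                   rng_seed = config$rng_seed,
                   parameters = config[setdiff(names(config),
                                               c("synthetic", "fit_grid"))])

  # --- stage: cohort ------------------------------------------------------
  cohort <- if (!is.null(config$synthetic)) generate_cohort(config$synthetic)
            else read_cohort(config$input_dir)
  write_cohort(cohort, file.path(out, "cohort"))
  geometry <- cohort$geometry
  d <- geometry$dist

  with_seed(config$rng_seed, {
    report <- list()

    # --- stage: consensus mask + thresholding -----------------------------
    masked <- consensus_mask(cohort, config$consensus_proportion)
    report$consensus_mask <- threshold_report(cohort$subjects, masked$cohort,
                                              "consensus_mask",
                                              config$consensus_proportion)
    abs_thr <- config$absolute_threshold
    if (is.null(abs_thr)) {
      tuned <- find_absolute_threshold_for_mean_density(masked$cohort,
                                                        config$target_density)
      abs_thr <- tuned$min_count
    }
    nets_var <- lapply(masked$cohort, threshold_absolute, min_count = abs_thr,
                       geometry = geometry)
    nets_ctrl <- lapply(masked$cohort, threshold_to_density,
                        target_density = config$target_density,
                        geometry = geometry)
    report$absolute <- threshold_report(masked$cohort, nets_var,
                                        "threshold_absolute", abs_thr)
    report$density <- threshold_report(masked$cohort, nets_ctrl,
                                       "threshold_to_density",
                                       config$target_density)
    write_threshold_report(report, file.path(out, "threshold_report.json"))

    # --- stage: consensus network + rich club -----------------------------
    consensus <- build_consensus_network(nets_var, d, config$consensus_bins)
    write_edge_list(consensus, file.path(out, "consensus_network.tsv"))
    rc <- rich_club(consensus, n_nulls = config$rich_nulls,
                    alpha = config$rich_alpha)
    write.csv(rc$levels, file.path(out, "rich_club_levels.csv"),
              row.names = FALSE)
    manifest$rich_club <- list(k_star = rc$k_star,
                               n_rich_nodes = length(rc$rich_nodes))

    # --- stage: topology tables -------------------------------------------
    cov <- covariate_table(cohort)
    metrics <- list(variable = nets_var, controlled = nets_ctrl)
    for (an in names(metrics)) {
      glob <- do.call(rbind, lapply(seq_along(metrics[[an]]), function(i) {
        gm <- global_measures(metrics[[an]][[i]], d, rc$rich_nodes)
        data.frame(subject_id = cov$subject_id[i],
                   density = gm$density, modularity_q = gm$modularity_q,
                   characteristic_path_length = gm$characteristic_path_length,
                   global_efficiency = gm$global_efficiency,
                   n_rich = gm$n_rich, n_feeder = gm$n_feeder,
                   n_local = gm$n_local,
                   mean_length_rich = gm$mean_length_rich)
      }))
      write.csv(glob, file.path(out, paste0("global_measures_", an, ".csv")),
                row.names = FALSE)
      loc <- do.call(rbind, lapply(seq_along(metrics[[an]]), function(i)
        cbind(subject_id = cov$subject_id[i],
              local_measures(metrics[[an]][[i]], d))))
      write.csv(loc, file.path(out, paste0("local_measures_", an, ".csv")),
                row.names = FALSE)
    }

    # --- stage: per-subject model fits ------------------------------------
    seed_net <- derive_seed_network(nets_ctrl, config$seed_prevalence)
    if (isTRUE(config$fit_enabled)) {
      n_fit <- min(length(nets_ctrl), config$fit_subjects)
      fits <- lapply(seq_len(n_fit), function(i)
        gnm_fit(nets_ctrl[[i]], d, seed = seed_net, rule = config$fit_rule,
                grid = config$fit_grid))
      best <- do.call(rbind, lapply(seq_len(n_fit), function(i)
        cbind(subject_id = cov$subject_id[i], fits[[i]]$best,
              tf_dissimilarity = fits[[i]]$tf_dissimilarity)))
      write.csv(best, file.path(out, "best_fits.csv"), row.names = FALSE)
      emb <- do.call(rbind, lapply(seq_len(n_fit), function(i) {
        se <- fits[[i]]$spatial_embedding
        data.frame(subject_id = cov$subject_id[i], measure = names(se),
                   r = as.numeric(se))
      }))
      write.csv(emb, file.path(out, "spatial_embedding.csv"),
                row.names = FALSE)
      manifest$fit <- list(n_subjects = n_fit,
                           grid_points = nrow(config$fit_grid),
                           rule = config$fit_rule)
    }

    # --- stage: group experiment ------------------------------------------
    if (isTRUE(config$group_enabled)) {
      m_target <- round_half_up(mean(vapply(nets_ctrl, edge_count, 0L)))
      gconf <- group_model_config(n_runs = config$group_runs,
                                  m_target = m_target,
                                  rule = config$fit_rule,
                                  seed_network = seed_net)
      st <- run_group(gconf, "term", d, rc$rich_nodes)
      sp <- run_group(gconf, "preterm", d, rc$rich_nodes)
      write.csv(group_experiment_table(list(st, sp)),
                file.path(out, "group_experiment.csv"), row.names = FALSE)
      cmp <- compare_groups(st, sp)
      write.csv(cmp$final, file.path(out, "group_comparison.csv"),
                row.names = FALSE)
      manifest$group <- list(m_target = m_target, n_runs = config$group_runs)
    }
  })

  # --- manifest -----------------------------------------------------------
  files <- sort(setdiff(list.files(out, recursive = TRUE), "manifest.json"))
  manifest$files <- lapply(files, function(f)
    list(path = f, md5 = unname(tools::md5sum(file.path(out, f)))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Descriptive cohort summary
#'
#' Per-group descriptive statistics of the topology tables plus
#' density-versus-age data, ready for external inferential modelling
#' (e.g. penalized-spline GAMs); no inference is performed here.
#'
#' @param metrics data frame of per-subject global measures (with a
#'   `subject_id` column, as written by [run_pipeline()]).
#' @param covariates data frame from [covariate_table()].
#' @return List with `by_group` (mean/sd per measure and group) and
#'   `density_vs_age` (subject-level table).
#' @export
summarize_cohort <- function(metrics, covariates) {
  if (nrow(metrics) == 0L) stop("empty metrics table")
  merged <- merge(metrics, covariates, by = "subject_id")
  if (nrow(merged) < nrow(metrics))
    warning("dropped ", nrow(metrics) - nrow(merged),
            " subjects with missing covariates")
  if (nrow(merged) == 0L) stop("no subjects with covariates")
  num <- names(merged)[vapply(merged, is.numeric, TRUE)]
  num <- setdiff(num, c("pma", "ga_birth"))
  by_group <- do.call(rbind, lapply(split(merged, merged$group), function(g)
    data.frame(group = g$group[1L], n = nrow(g),
               measure = num,
               mean = vapply(num, function(v) mean(g[[v]], na.rm = TRUE), 0.0),
               sd = vapply(num, function(v) sd(g[[v]], na.rm = TRUE), 0.0),
               row.names = NULL)))
  list(by_group = by_group,
       density_vs_age = merged[, c("subject_id", "group", "pma", "ga_birth",
                                   intersect("density", names(merged)))])
}
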