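#' Configuration for the representative group experiment
#'
#' Two growth models, one per group, run many times at fixed parameters
#' with every iteration recorded. Defaults are the representative term
#' (eta = -1.74, gamma = 0.32) and preterm (eta = -1.85, gamma = 0.34)
#' wiring parameters under the matching rule.
#'
#' @param term,preterm named numeric vectors `c(eta = , gamma = )`.
#' @param n_runs growth runs per group (default 1000).
#' @param m_target total edge count each run grows to.
#' @param rule value rule, one of [gnm_rules()].
#' @param seed_network seed `binary_network` shared by all runs.
#' @param epsilon value-term offset, see [gnm_spec()].
#' @return An object of class `group_model_config`.
#' @export
group_model_config <- function(term = c(eta = -1.74, gamma = 0.32),
                               preterm = c(eta = -1.85, gamma = 0.34),
                               n_runs = 1000L, m_target, rule = "matching",
                               seed_network = NULL, epsilon = 1e-5) {
  if (n_runs < 1L) stop("n_runs must be >= 1")
  if (!all(is.finite(c(term, preterm)))) stop("parameters must be finite")
  rule <- match.arg(rule, gnm_rules())
  structure(list(term = term, preterm = preterm,
                 n_runs = as.integer(n_runs), m_target = as.integer(m_target),
                 rule = rule, seed_network = seed_network, epsilon = epsilon),
            class = "group_model_config")
}

#' Run one group's growth models and summarise per iteration
#'
#' Grows `n_runs` networks at the group's parameters, classifies every
#' added connection against a fixed rich-node set (derived once from the
#' group consensus network, not per simulation), and reduces the traces
#' to per-iteration cumulative class counts and mean connection lengths
#' (cumulative over added edges; per-iteration added lengths are kept
#' too). Counts include the seed edges as the iteration-0 baseline, so
#' rich + feeder + local equals the total edge count at every step.
#'
#' @param config a [group_model_config()].
#' @param group `"term"` or `"preterm"`.
#' @param distances Euclidean distance matrix.
#' @param rich_nodes integer indices of the fixed rich-club nodes.
#' @return An object of class `iteration_summary`: `by_iteration` (data
#'   frame of means and SDs over runs), `final` (per-run final-state data
#'   frame) and metadata.
#' @export
run_group <- function(config, group = c("term", "preterm"), distances,
                      rich_nodes) {
  group <- match.arg(group)
  pars <- config[[group]]
  spec <- gnm_spec(config$rule, pars[["eta"]], pars[["gamma"]],
                   config$epsilon)
  seed <- config$seed_network
  if (is.null(seed)) stop("config must carry a seed network")
  a_seed <- as_adjacency(seed)
  n <- nrow(a_seed)
  d <- as.matrix(distances)

  seed_cls <- classify_edges(a_seed, rich_nodes, d)
  seed_counts <- c(rich = sum(seed_cls$edges$class == "rich"),
                   feeder = sum(seed_cls$edges$class == "feeder"),
                   local = sum(seed_cls$edges$class == "local"))

  n_iter <- config$m_target - edge_count(a_seed)
  if (n_iter < 0) stop("m_target below seed edge count")
  is_rich <- rep(FALSE, n)
  is_rich[rich_nodes] <- TRUE

  counts <- array(0L, dim = c(n_iter, 3L, config$n_runs),
                  dimnames = list(NULL, c("rich", "feeder", "local"), NULL))
  cum_len <- matrix(NA_real_, n_iter, config$n_runs)      # all added edges
  cls_len <- array(NA_real_, dim = c(n_iter, 3L, config$n_runs),
                   dimnames = list(NULL, c("rich", "feeder", "local"), NULL))
  add_len <- matrix(NA_real_, n_iter, config$n_runs)      # per-iteration
  final <- vector("list", config$n_runs)

  for (r in seq_len(config$n_runs)) {
    tr <- grow_network(a_seed, d, spec, config$m_target)
    ends <- is_rich[tr$trace$from] + is_rich[tr$trace$to]
    cls <- c("local", "feeder", "rich")[ends + 1L]
    len <- tr$trace$length
    for (ci in 1:3) {
      cn <- c("rich", "feeder", "local")[ci]
      hit <- cls == cn
      counts[, ci, r] <- seed_counts[[cn]] + cumsum(hit)
      csum <- cumsum(ifelse(hit, len, 0))
      ccount <- cumsum(hit)
      cls_len[, ci, r] <- ifelse(ccount > 0, csum / ccount, NA_real_)
    }
    cum_len[, r] <- cumsum(len) / seq_along(len)
    add_len[, r] <- len
    final[[r]] <- data.frame(run = r,
                             n_rich = counts[n_iter, 1L, r],
                             n_feeder = counts[n_iter, 2L, r],
                             n_local = counts[n_iter, 3L, r],
                             mean_length = cum_len[n_iter, r],
                             mean_length_rich = cls_len[n_iter, 1L, r],
                             mean_length_feeder = cls_len[n_iter, 2L, r],
                             mean_length_local = cls_len[n_iter, 3L, r])
  }

  by_iter <- data.frame(iteration = seq_len(n_iter))
  for (ci in 1:3) {
    cn <- c("rich", "feeder", "local")[ci]
    by_iter[[paste0("count_", cn)]] <- rowMeans(counts[, ci, , drop = FALSE], dims = 1)
    by_iter[[paste0("count_", cn, "_sd")]] <-
      apply(counts[, ci, , drop = FALSE], 1L, sd)
    by_iter[[paste0("length_", cn)]] <-
      rowMeans(cls_len[, ci, , drop = FALSE], dims = 1, na.rm = TRUE)
    by_iter[[paste0("length_", cn, "_sd")]] <-
      apply(cls_len[, ci, , drop = FALSE], 1L, sd, na.rm = TRUE)
  }
  by_iter$length_all <- rowMeans(cum_len)
  by_iter$length_all_sd <- apply(cum_len, 1L, sd)
  by_iter$added_length <- rowMeans(add_len)

  structure(list(group = group, by_iteration = by_iter,
                 final = do.call(rbind, final),
                 n_runs = config$n_runs, m_target = config$m_target,
                 m_seed = edge_count(a_seed), params = pars,
                 rich_nodes = rich_nodes),
            class = "iteration_summary")
}

#' @export
print.iteration_summary <- function(x, ...) {
  cat(sprintf("Group growth summary ('%s'): %d runs to %d edges (seed %d)\n",
              x$group, x$n_runs, x$m_target, x$m_seed))
  fin <- x$final
  cat(sprintf("  final counts (mean): rich %.1f, feeder %.1f, local %.1f\n",
              mean(fin$n_rich), mean(fin$n_feeder), mean(fin$n_local)))
  cat(sprintf("  final mean connection length: %.2f mm\n",
              mean(fin$mean_length)))
  invisible(x)
}

#' Compare term and preterm growth summaries
#'
#' Per-iteration difference curves (term minus preterm) for class counts
#' and cumulative mean lengths, run-level permutation tests of the
#' final-state differences (group labels shuffled across runs), and
#' standardized group effects over generative time. The standardized
#' effect of a variable is its mean term-minus-preterm difference across
#' iterations divided by its pooled standard deviation over runs and
#' iterations; because class counts at matched iterations sum to the same
#' total, raw count differences are constrained, and it is on this
#' standardized scale that per-class effects are comparable.
#'
#' @param summary_term,summary_preterm [run_group()] results with equal
#'   `m_target` and rich-node sets.
#' @param n_perm permutation resamples (default 1000).
#' @return An object of class `group_comparison`: `difference`
#'   (per-iteration curves), `final` (data frame of final-state effects
#'   with permutation p values), and `standardized` (per-variable
#'   standardized effects).
#' @export
compare_groups <- function(summary_term, summary_preterm, n_perm = 1000L) {
  if (summary_term$m_target != summary_preterm$m_target)
    stop("summaries have different m_target")
  if (!identical(sort(summary_term$rich_nodes),
                 sort(summary_preterm$rich_nodes)))
    stop("summaries use different rich-node sets")
  bt <- summary_term$by_iteration
  bp <- summary_preterm$by_iteration
  keep <- c("count_rich", "count_feeder", "count_local",
            "length_rich", "length_feeder", "length_local", "length_all")
  diff <- data.frame(iteration = bt$iteration)
  for (v in keep) diff[[v]] <- bt[[v]] - bp[[v]]

  vars <- c("n_rich", "n_feeder", "n_local", "mean_length",
            "mean_length_rich", "mean_length_feeder", "mean_length_local")
  ft <- summary_term$final
  fp <- summary_preterm$final
  pooled <- rbind(ft[vars], fp[vars])
  n_t <- nrow(ft)
  lab <- c(rep(TRUE, n_t), rep(FALSE, nrow(fp)))
  obs_diff <- colMeans(ft[vars], na.rm = TRUE) -
    colMeans(fp[vars], na.rm = TRUE)
  perm <- matrix(NA_real_, n_perm, length(vars),
                 dimnames = list(NULL, vars))
  for (b in seq_len(n_perm)) {
    sh <- sample(lab)
    perm[b, ] <- colMeans(pooled[sh, , drop = FALSE], na.rm = TRUE) -
      colMeans(pooled[!sh, , drop = FALSE], na.rm = TRUE)
  }
  pval <- vapply(seq_along(vars), function(i)
    mean(abs(perm[, i]) >= abs(obs_diff[i])), 0.0)
  final <- data.frame(variable = vars, term_mean = colMeans(ft[vars], na.rm = TRUE),
                      preterm_mean = colMeans(fp[vars], na.rm = TRUE),
                      difference = as.numeric(obs_diff), p_perm = pval,
                      row.names = NULL)

  std_vars <- c("count_rich", "count_feeder", "count_local",
                "length_rich", "length_feeder", "length_local",
                "length_all")
  std <- vapply(std_vars, function(v) {
    sdv <- paste0(v, "_sd")
    mt <- bt[[v]]; mp <- bp[[v]]
    st <- bt[[sdv]]; sp <- bp[[sdv]]
    # pooled variance over runs x iterations x groups:
    # within-cell variance plus variance of the cell means
    pooled <- mean(c(st^2, sp^2), na.rm = TRUE) +
      stats::var(c(mt, mp), na.rm = TRUE)
    if (!is.finite(pooled) || pooled <= 0) return(NA_real_)
    mean(mt - mp, na.rm = TRUE) / sqrt(pooled)
  }, 0.0)
  standardized <- data.frame(variable = std_vars, effect = as.numeric(std),
                             row.names = NULL)

  structure(list(difference = diff, final = final,
                 standardized = standardized, n_perm = n_perm,
                 m_target = summary_term$m_target),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Term vs preterm growth comparison (final state, term - preterm):\n")
  df <- x$final
  df$term_mean <- round(df$term_mean, 3)
  df$preterm_mean <- round(df$preterm_mean, 3)
  df$difference <- round(df$difference, 3)
  print(df, row.names = FALSE)
  cat("Standardized effects over generative time (term - preterm):\n")
  se <- x$standardized
  se$effect <- round(se$effect, 3)
  print(se, row.names = FALSE)
  invisible(x)
}

#' Long-format export of a group experiment
#'
#' @param summaries list of [run_group()] results.
#' @return data frame: group, iteration, class, count, mean_length.
#' @export
group_experiment_table <- function(summaries) {
  do.call(rbind, lapply(summaries, function(s) {
    bi <- s$by_iteration
    do.call(rbind, lapply(c("rich", "feeder", "local"), function(cl)
      data.frame(group = s$group, iteration = bi$iteration, class = cl,
                 count = bi[[paste0("count_", cl)]],
                 mean_length = bi[[paste0("length_", cl)]])))
  }))
}
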