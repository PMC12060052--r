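#' Default pipeline configuration
#'
#' Every analysis decision the pipeline makes appears here and is echoed
#' into the results manifest, so a manifest can always be regenerated from
#' its configuration and seed.
#'
#' @param experiment `"exp1"` (central presentation) or `"exp2"` (moving,
#'   spatially cued stimuli).
#' @param n_observers cohort size to simulate (defaults: 60 for exp1, 10
#'   for exp2, matching the study cohorts).
#' @param n_blocks,trials_per_block session geometry (defaults 16 x 24 for
#'   exp1, 48 x 24 for exp2).
#' @param seed master seed for design, simulation, and permutations.
#' @param accuracy_threshold speeded-accuracy exclusion cut-off.
#' @param n_bins violation bins for the tuning analysis.
#' @param n_perm cluster-test permutations.
#' @param violation_split_deg pupil split magnitude (deg).
#' @param pupil whether to simulate and analyze pupil data.
#' @param population_sds between-observer SDs passed to
#'   [simulate_cohort()].
#' @param params population-mean [observer_params()].
#' @return a `run_config` list.
#' @export
run_config <- function(experiment = c("exp1", "exp2"),
                       n_observers = NULL,
                       n_blocks = NULL, trials_per_block = 24,
                       seed = 1,
                       accuracy_threshold = 0.75,
                       n_bins = 8, n_perm = 1000,
                       violation_split_deg = 30,
                       pupil = TRUE,
                       population_sds = list(rt_base = 60, repro_sd_base = 1.5,
                                             rt_seq_gain = 12,
                                             repro_sd_seq_gain = 1,
                                             rt_pred_amp = 15,
                                             repro_sd_pred_amp = 1.5,
                                             pupil_surprise_gain = 0.15),
                       params = observer_params()) {
  experiment <- match.arg(experiment)
  if (is.null(n_observers)) n_observers <- if (experiment == "exp1") 60 else 10
  if (is.null(n_blocks)) n_blocks <- if (experiment == "exp1") 16 else 48
  structure(list(experiment = experiment, n_observers = n_observers,
                 n_blocks = n_blocks, trials_per_block = trials_per_block,
                 seed = as.integer(seed),
                 accuracy_threshold = accuracy_threshold,
                 n_bins = n_bins, n_perm = n_perm,
                 violation_split_deg = violation_split_deg,
                 pupil = pupil, population_sds = population_sds,
                 params = params),
            class = "run_config")
}

#' Run the full simulate-and-analyze pipeline
#'
#' Generates a session design and simulated cohort under `config`, applies
#' the behavioral exclusions and correct-trial filter, and computes the
#' headline statistics: the aggregate paired t-tests on response time and
#' precision, the condition x violation-bin repeated-measures ANOVAs for
#' both measures, the large-violation pupil condition difference with the
#' cluster-mass permutation test, and the skipped Pearson correlations
#' between (and within) the behavioral and pupillary effects. For the cued
#' experiment the manifest adds the sequence x cue-validity analysis.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, the behavioral table,
#'   per-observer summaries, and a JSON manifest are written there.
#' @return list of class `pipeline_result`: `manifest` (named list of
#'   headline statistics), `summaries`, `tuning`, `bias`, `cluster`
#'   (a `cluster_result` or `NULL`), `behavior`, `config`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  design <- if (config$experiment == "exp1") {
    generate_session_exp1(config$n_blocks, config$trials_per_block,
                          seed = config$seed)
  } else {
    generate_session_exp2(config$n_blocks, config$trials_per_block,
                          seed = config$seed)
  }
  cohort <- simulate_cohort(config$n_observers, design,
                            population_means = config$params,
                            population_sds = config$population_sds,
                            seed = config$seed + 1L,
                            pupil = config$pupil)

  excl <- exclude_by_accuracy(cohort$behavior, config$accuracy_threshold)
  beh <- correct_trials_only(excl$kept)
  retention <- attr(beh, "retention")

  summaries <- condition_summaries(beh)
  wide_rt <- .to_wide(summaries, "mean_rt")
  wide_prec <- .to_wide(summaries, "precision")
  rt_t <- paired_t(wide_rt$random, wide_rt$sequential)
  prec_t <- paired_t(wide_prec$random, wide_prec$sequential)

  tuning <- tuning_by_violation(beh, config$n_bins)
  anova_rt <- rm_anova_2way(tuning, "mean_rt", "observer_id",
                            "condition", "bin")
  anova_prec <- rm_anova_2way(tuning, "precision", "observer_id",
                              "condition", "bin")
  bias <- bias_by_violation(beh, config$n_bins)

  manifest <- list(
    experiment = config$experiment,
    seed = config$seed,
    n_observers_simulated = config$n_observers,
    n_observers_included = length(unique(beh$observer_id)),
    n_excluded_accuracy = nrow(excl$excluded),
    prop_correct_retained = retention,
    rt_ttest = rt_t,
    precision_ttest = prec_t,
    anova_rt_condition = as.list(anova_rt[1, c("F", "df1", "df2", "p")]),
    anova_rt_interaction = as.list(anova_rt[3, c("F", "df1", "df2", "p")]),
    anova_precision_condition = as.list(anova_prec[1, c("F", "df1", "df2", "p")]),
    anova_precision_interaction = as.list(anova_prec[3, c("F", "df1", "df2", "p")]),
    corr_rt_precision_random = .cor_entry(wide_rt$random, wide_prec$random),
    corr_rt_precision_sequential = .cor_entry(wide_rt$sequential,
                                              wide_prec$sequential),
    corr_diff_rt_precision = .cor_entry(wide_rt$random - wide_rt$sequential,
                                        wide_prec$random - wide_prec$sequential)
  )

  cluster <- NULL
  if (config$pupil) {
    kept_ids <- as.integer(unique(beh$observer_id))
    pupil_res <- .pupil_stage(cohort, kept_ids, config)
    cluster <- pupil_res$cluster
    manifest <- c(manifest, pupil_res$manifest)
    # pupil-behavior correlations over the significant window
    if (!is.null(pupil_res$window_means)) {
      ids <- pupil_res$observer_ids
      pos <- match(ids, wide_rt$observer_id)
      ok <- !is.na(pos)
      rt_diff <- (wide_rt$random - wide_rt$sequential)[pos[ok]]
      prec_diff <- (wide_prec$random - wide_prec$sequential)[pos[ok]]
      wm <- pupil_res$window_means[ok]
      manifest$corr_pupil_rt <- .cor_entry(wm, rt_diff)
      manifest$corr_pupil_precision <- .cor_entry(wm, prec_diff)
    }
  }

  if (config$experiment == "exp2") {
    manifest$cue_validity <- .cue_validity_stage(beh, design)
  }

  res <- structure(list(manifest = manifest, summaries = summaries,
                        tuning = tuning, bias = bias, cluster = cluster,
                        behavior = beh, config = config),
                   class = "pipeline_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_session(cohort$behavior, file.path(out_dir, "behavior.tsv"))
    utils::write.table(summaries, file.path(out_dir, "summaries.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}

.to_wide <- function(summaries, col) {
  r <- summaries[summaries$condition == "random", ]
  s <- summaries[summaries$condition == "sequential", ]
  stopifnot(identical(r$observer_id, s$observer_id))
  data.frame(observer_id = r$observer_id, random = r[[col]],
             sequential = s[[col]])
}

.cor_entry <- function(x, y) {
  if (sum(stats::complete.cases(x, y)) < 10) {
    return(list(r = NA_real_, p = NA_real_, n_used = 0L, n_outliers = 0L))
  }
  sc <- skipped_pearson(x, y)
  list(r = sc$r, p = sc$p_value, n_used = sc$n_used,
       n_outliers = sc$n - sc$n_used)
}

.pupil_stage <- function(cohort, kept_ids, config) {
  # pupil-size outlier exclusion on the raw grand means
  gm <- vapply(cohort$pupil, function(tr) mean(tr$d, na.rm = TRUE),
               numeric(1))
  keep_mask <- exclude_pupil_outlier_observers(gm)
  keep_ids <- intersect(which(keep_mask), kept_ids)
  sub <- cohort
  sub$pupil <- cohort$pupil[keep_ids]
  epochs <- preprocess_cohort_pupil(sub, violation_split = "large",
                                    split_deg = config$violation_split_deg)
  course <- condition_difference_course(epochs)
  cl <- cluster_permutation_test(course$diff, times = course$t_rel,
                                 n_perm = config$n_perm, tail = "greater",
                                 seed = config$seed + 2L)
  sig <- cl$clusters[cl$clusters$significant & cl$clusters$sign > 0, ]
  man <- list(n_excluded_pupil = sum(!keep_mask),
              cluster_window_ms = if (nrow(sig)) {
                c(sig$start[which.max(sig$mass)], sig$end[which.max(sig$mass)])
              } else NULL,
              cluster_mass = if (nrow(sig)) max(sig$mass) else NULL)
  window_means <- NULL
  if (nrow(sig)) {
    w <- c(sig$start[which.max(sig$mass)], sig$end[which.max(sig$mass)])
    window_means <- window_average(course, w)
    pt <- paired_t(window_means, rep(0, length(window_means)),
                   tail = "greater")
    man$pupil_window_ttest <- pt
  }
  list(cluster = cl, manifest = man, window_means = window_means,
       observer_ids = keep_ids[match(course$observer_ids,
                                     seq_along(keep_ids))])
}

.cue_validity_stage <- function(beh, design) {
  vt <- design$cue_valid[match(beh$trial_id, design$trial_id)]
  beh$cue_valid <- vt
  out <- list()
  for (valid in c(TRUE, FALSE)) {
    sm <- condition_summaries(beh[beh$cue_valid == valid, , drop = FALSE])
    wr <- .to_wide(sm, "mean_rt"); wp <- .to_wide(sm, "precision")
    key <- if (valid) "valid" else "invalid"
    out[[paste0("rt_ttest_", key)]] <- paired_t(wr$random, wr$sequential)
    out[[paste0("precision_ttest_", key)]] <- paired_t(wp$random,
                                                       wp$sequential)
  }
  # 2 x 2 sequence x cue-validity ANOVA per measure
  cell <- stats::aggregate(cbind(rt, ok = as.numeric(choice_correct)) ~
                             observer_id + condition + cue_valid,
                           data = beh, FUN = mean, na.rm = TRUE)
  prec <- stats::aggregate(repro_error ~ observer_id + condition + cue_valid,
                           data = beh, FUN = angular_sd)
  cell$precision <- prec$repro_error[match(
    paste(cell$observer_id, cell$condition, cell$cue_valid),
    paste(prec$observer_id, prec$condition, prec$cue_valid))]
  out$anova_rt <- as.data.frame(rm_anova_2way(cell, "rt", "observer_id",
                                              "condition", "cue_valid"))
  out$anova_precision <- as.data.frame(
    rm_anova_2way(cell, "precision", "observer_id", "condition", "cue_valid"))
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("Pipeline result (%s, seed %d): %d/%d observers included\n",
              m$experiment, m$seed, m$n_observers_included,
              m$n_observers_simulated))
  cat(sprintf("  RT: t(%d) = %.2f, p = %.3g; precision: t(%d) = %.2f, p = %.3g\n",
              m$rt_ttest$df, m$rt_ttest$t, m$rt_ttest$p,
              m$precision_ttest$df, m$precision_ttest$t, m$precision_ttest$p))
  if (!is.null(m$cluster_window_ms)) {
    cat(sprintf("  pupil cluster: %.0f-%.0f ms (mass %.1f)\n",
                m$cluster_window_ms[1], m$cluster_window_ms[2],
                m$cluster_mass))
  }
  invisible(x)
}
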