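#' Drop observers with poor speeded-task accuracy
#'
#' Observers whose proportion correct on the speeded clockwise /
#' counterclockwise task falls strictly below `threshold` (default .75)
#' across all scored trials are removed. Missed responses (no speeded
#' response within the 2 s window) are dropped before the accuracy
#' denominator is formed.
#'
#' @param behavior long-format behavioral table (one row per trial) with at
#'   least `observer_id`, `choice_correct`, and (optionally) `missed`.
#' @param threshold accuracy cut-off; strict `<` excludes.
#' @return list with `kept` (the filtered table), `excluded` (data frame of
#'   excluded observers with their accuracy), and `accuracy` (per-observer
#'   proportion correct).
#' @export
exclude_by_accuracy <- function(behavior, threshold = 0.75) {
  if (!is.data.frame(behavior) || nrow(behavior) == 0) {
    stop("empty behavioral dataset")
  }
  if ("missed" %in% names(behavior)) {
    behavior <- behavior[!behavior$missed, , drop = FALSE]
  }
  if (nrow(behavior) == 0) stop("no scored trials after dropping misses")
  acc <- tapply(behavior$choice_correct, behavior$observer_id, mean)
  drop_ids <- names(acc)[acc < threshold]
  excluded <- data.frame(observer_id = drop_ids,
                         prop_correct = as.numeric(acc[drop_ids]),
                         reason = rep("accuracy", length(drop_ids)),
                         stringsAsFactors = FALSE)
  kept <- behavior[!behavior$observer_id %in% drop_ids, , drop = FALSE]
  list(kept = kept, excluded = excluded,
       accuracy = data.frame(observer_id = names(acc),
                             prop_correct = as.numeric(acc),
                             stringsAsFactors = FALSE))
}

#' Restrict to trials with a correct speeded response
#'
#' Reproduction precision and bias (and, by default, the response-time
#' summaries) are computed only on trials where the speeded judgment was
#' answered correctly. The retained fraction is attached as attribute
#' `retention` so pipelines can log it.
#'
#' @param behavior behavioral table with `choice_correct`.
#' @return the filtered table, attribute `retention` = fraction kept.
#' @export
correct_trials_only <- function(behavior) {
  stopifnot("choice_correct" %in% names(behavior))
  keep <- behavior$choice_correct %in% TRUE
  out <- behavior[keep, , drop = FALSE]
  if (nrow(out) == 0) warning("no correct trials retained")
  attr(out, "retention") <- mean(keep)
  out
}

#' Per-observer condition summaries
#'
#' Mean response time and reproduction precision (angular SD of the signed
#' reproduction error) per observer and condition.
#'
#' @param behavior filtered behavioral table (see [exclude_by_accuracy()]
#'   and [correct_trials_only()]).
#' @return data frame with one row per observer x condition: `observer_id`,
#'   `condition`, `n_trials`, `mean_rt` (ms), `precision` (deg; `NA` with a
#'   flag when a condition has no trials).
#' @export
condition_summaries <- function(behavior) {
  need <- c("observer_id", "condition", "rt", "repro_error")
  miss <- setdiff(need, names(behavior))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  obs <- sort(unique(behavior$observer_id))
  conds <- c("random", "sequential")
  grid <- expand.grid(observer_id = obs, condition = conds,
                      stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    rows <- behavior$observer_id == grid$observer_id[i] &
      behavior$condition == grid$condition[i]
    n <- sum(rows)
    if (n == 0) {
      warning("observer ", grid$observer_id[i], " has no ",
              grid$condition[i], " trials")
      return(data.frame(grid[i, ], n_trials = 0L, mean_rt = NA_real_,
                        precision = NA_real_))
    }
    prec <- if (n >= 2) angular_sd(behavior$repro_error[rows]) else {
      warning("observer ", grid$observer_id[i],
              ": single-trial condition, precision undefined")
      NA_real_
    }
    data.frame(grid[i, ], n_trials = n,
               mean_rt = mean(behavior$rt[rows], na.rm = TRUE),
               precision = prec)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Violation bin edges
#'
#' Signed bins partition `(-90, 90]` into `n_bins` half-open intervals
#' `(lo, hi]`; unsigned bins partition `[0, 90]` the same way with the
#' first bin closed at 0.
#' @param n_bins number of bins (default 8).
#' @param signed signed (default) or folded unsigned magnitudes.
#' @return numeric vector of `n_bins + 1` edges.
#' @export
violation_bins <- function(n_bins = 8, signed = TRUE) {
  if (signed) seq(-90, 90, length.out = n_bins + 1)
  else seq(0, 90, length.out = n_bins + 1)
}

.assign_bin <- function(v, edges) {
  b <- findInterval(v, edges, left.open = TRUE, rightmost.closed = FALSE)
  # values exactly at the lowest edge (possible only for unsigned 0) join bin 1
  b[v == edges[1]] <- 1L
  b[b < 1 | b > length(edges) - 1] <- NA_integer_
  b
}

#' Tuning curves over expectation-violation magnitude
#'
#' Bins trials by the signed expectation violation (sequential: target
#' versus expected orientation; random: target versus penultimate) into
#' `n_bins` equal-width bins and summarizes mean response time and
#' reproduction precision per observer, condition, and bin.
#'
#' @param behavior filtered behavioral table with `violation`.
#' @param n_bins number of bins (default 8, each 22.5 deg wide when signed).
#' @param signed bin the signed violation over `(-90, 90]` (default) or its
#'   magnitude over `[0, 90]`.
#' @return object of class `tuning_curve`: data frame `observer_id`,
#'   `condition`, `bin`, `bin_center`, `n_trials`, `mean_rt`, `precision`;
#'   attributes `edges`, `signed`.
#' @export
tuning_by_violation <- function(behavior, n_bins = 8, signed = TRUE) {
  stopifnot("violation" %in% names(behavior))
  edges <- violation_bins(n_bins, signed)
  v <- if (signed) behavior$violation else abs(behavior$violation)
  behavior$bin <- .assign_bin(v, edges)
  if (anyNA(behavior$bin)) stop("violations outside the bin range")
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  obs <- sort(unique(behavior$observer_id))
  grid <- expand.grid(observer_id = obs,
                      condition = c("random", "sequential"),
                      bin = seq_len(n_bins), stringsAsFactors = FALSE)
  rows <- split(seq_len(nrow(behavior)),
                list(behavior$observer_id, behavior$condition, behavior$bin))
  out <- grid
  out$bin_center <- centers[out$bin]
  out$n_trials <- 0L
  out$mean_rt <- NA_real_
  out$precision <- NA_real_
  for (i in seq_len(nrow(out))) {
    idx <- rows[[paste(out$observer_id[i], out$condition[i], out$bin[i],
                       sep = ".")]]
    if (is.null(idx) || length(idx) == 0) next
    out$n_trials[i] <- length(idx)
    out$mean_rt[i] <- mean(behavior$rt[idx], na.rm = TRUE)
    if (length(idx) >= 2) {
      out$precision[i] <- angular_sd(behavior$repro_error[idx])
    }
  }
  structure(out, class = c("tuning_curve", "data.frame"),
            edges = edges, signed = signed)
}

#' Signed reproduction bias per violation bin
#'
#' Axial mean of the signed reproduction error in each violation bin, per
#' observer and condition. A repulsive bias away from the expected
#' orientation appears as per-bin bias whose sign matches the sign of the
#' bin center near zero violation.
#'
#' @inheritParams tuning_by_violation
#' @return data frame `observer_id`, `condition`, `bin`, `bin_center`,
#'   `n_trials`, `bias` (deg, axial mean of signed errors).
#' @export
bias_by_violation <- function(behavior, n_bins = 8) {
  edges <- violation_bins(n_bins, signed = TRUE)
  behavior$bin <- .assign_bin(behavior$violation, edges)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  obs <- sort(unique(behavior$observer_id))
  grid <- expand.grid(observer_id = obs,
                      condition = c("random", "sequential"),
                      bin = seq_len(n_bins), stringsAsFactors = FALSE)
  grid$bin_center <- centers[grid$bin]
  grid$n_trials <- 0L
  grid$bias <- NA_real_
  rows <- split(seq_len(nrow(behavior)),
                list(behavior$observer_id, behavior$condition, behavior$bin))
  for (i in seq_len(nrow(grid))) {
    idx <- rows[[paste(grid$observer_id[i], grid$condition[i], grid$bin[i],
                       sep = ".")]]
    if (is.null(idx) || !length(idx)) next
    grid$n_trials[i] <- length(idx)
    grid$bias[i] <- axial_mean(behavior$repro_error[idx])
  }
  grid
}

#' Median split by initial-sequence length
#'
#' Splits each observer's trials at their median number of initial gratings
#' (ties go to the short half) and summarizes mean RT and precision per
#' half and condition. Faster responses on the long half in both conditions
#' indicate motor priming by the longer foreperiod rather than an
#' expectation effect.
#'
#' @param behavior filtered behavioral table with `n_initial`.
#' @return data frame `observer_id`, `condition`, `half`
#'   (`"short"`/`"long"`), `n_trials`, `mean_rt`, `precision`.
#' @export
median_split_by_length <- function(behavior) {
  stopifnot("n_initial" %in% names(behavior))
  if (length(unique(behavior$n_initial)) < 2) {
    stop("n_initial is constant: median split undefined")
  }
  pieces <- lapply(split(behavior, behavior$observer_id), function(b) {
    med <- stats::median(b$n_initial)
    b$half <- ifelse(b$n_initial <= med, "short", "long")
    b
  })
  behavior <- do.call(rbind, pieces)
  grid <- expand.grid(observer_id = sort(unique(behavior$observer_id)),
                      condition = c("random", "sequential"),
                      half = c("short", "long"), stringsAsFactors = FALSE)
  grid$n_trials <- 0L
  grid$mean_rt <- NA_real_
  grid$precision <- NA_real_
  rows <- split(seq_len(nrow(behavior)),
                list(behavior$observer_id, behavior$condition, behavior$half))
  for (i in seq_len(nrow(grid))) {
    idx <- rows[[paste(grid$observer_id[i], grid$condition[i], grid$half[i],
                       sep = ".")]]
    if (is.null(idx) || !length(idx)) next
    grid$n_trials[i] <- length(idx)
    grid$mean_rt[i] <- mean(behavior$rt[idx], na.rm = TRUE)
    if (length(idx) >= 2) grid$precision[i] <- angular_sd(behavior$repro_error[idx])
  }
  grid
}
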