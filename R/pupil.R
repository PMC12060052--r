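#' Normalize pupil traces to the observer's grand mean
#'
#' Divisive normalization: every sample is divided by the observer's mean
#' diameter over all non-missing samples of the session, making traces
#' dimensionless with mean ~1 and removing between-observer differences in
#' absolute pupil size. A subtractive variant (grand mean subtracted,
#' units preserved) is available for sensitivity analyses.
#'
#' @param d numeric vector or matrix (time x trial) of diameters; `NA` =
#'   missing.
#' @param method `"divisive"` (default) or `"subtractive"`.
#' @return normalized data of the same shape; attribute `grand_mean`.
#' @export
normalize_to_observer_mean <- function(d, method = c("divisive", "subtractive")) {
  method <- match.arg(method)
  m <- mean(d, na.rm = TRUE)
  if (!is.finite(m)) stop("observer grand mean undefined: all samples missing")
  out <- if (method == "divisive") d / m else d - m
  attr(out, "grand_mean") <- m
  out
}

#' Epoch a trace around target onset and regress out the baseline
#'
#' Extracts the window from 500 ms before to 1500 ms after target onset
#' (2001 samples at 1 kHz, both endpoints included), fits an ordinary
#' least-squares line to the 500 pre-onset samples (non-missing only), and
#' subtracts that line, extrapolated across the whole epoch. This removes
#' both the local pupil level and any linear drift at stimulus onset, so a
#' purely linear input comes out identically zero.
#'
#' @param t time stamps (ms, 1 ms steps) of the trace.
#' @param d diameters (`NA` = missing), same length as `t`.
#' @param target_onset_ms onset time on the `t` axis.
#' @param pre_ms,post_ms epoch half-widths (defaults 500 / 1500).
#' @return list of class `pupil_epoch`: `t_rel` (-pre..post), `d`
#'   (baseline-corrected), `missing`, `baseline_fit` (intercept and slope
#'   on the `t_rel` axis), `valid` (`FALSE` when fewer than 2 non-missing
#'   baseline samples were available).
#' @export
epoch_and_baseline <- function(t, d, target_onset_ms,
                               pre_ms = 500, post_ms = 1500) {
  stopifnot(length(t) == length(d))
  idx <- match(seq(target_onset_ms - pre_ms, target_onset_ms + post_ms), t)
  if (anyNA(idx)) stop("trace does not cover [onset-", pre_ms, ", onset+",
                       post_ms, "] ms")
  t_rel <- seq(-pre_ms, post_ms)
  y <- d[idx]
  missing <- is.na(y)
  base_idx <- which(t_rel < 0 & !missing)
  if (length(base_idx) < 2) {
    return(structure(list(t_rel = t_rel, d = rep(NA_real_, length(t_rel)),
                          missing = missing,
                          baseline_fit = c(intercept = NA_real_, slope = NA_real_),
                          valid = FALSE),
                     class = "pupil_epoch"))
  }
  x <- t_rel[base_idx]
  yb <- y[base_idx]
  slope <- stats::cov(x, yb) / stats::var(x)
  intercept <- mean(yb) - slope * mean(x)
  structure(list(t_rel = t_rel,
                 d = y - (intercept + slope * t_rel),
                 missing = missing,
                 baseline_fit = c(intercept = intercept, slope = slope),
                 valid = TRUE),
            class = "pupil_epoch")
}

#' Linearly interpolate missing samples of an epoch
#'
#' Internal gaps (blinks) are filled by linear interpolation between the
#' flanking measured samples; leading and trailing gaps are held at the
#' nearest measured value. The filled positions are recorded in
#' `interpolated_mask`.
#'
#' @param epoch a `pupil_epoch` (or any list with `d` and `missing`).
#' @return the epoch with gaps filled, `missing` all `FALSE`, and a new
#'   `interpolated_mask` marking filled samples.
#' @export
interpolate_missing <- function(epoch) {
  d <- epoch$d
  missing <- epoch$missing | is.na(d)
  if (all(missing)) {
    epoch$valid <- FALSE
    warning("fully missing epoch cannot be interpolated")
    return(epoch)
  }
  if (any(missing)) {
    obs <- which(!missing)
    d[missing] <- stats::approx(obs, d[obs], xout = which(missing),
                                method = "linear", rule = 2)$y
  }
  epoch$d <- d
  epoch$interpolated_mask <- missing
  epoch$missing <- rep(FALSE, length(missing))
  epoch
}

#' Flag observers with outlying average pupil diameter
#'
#' Observers whose session-average diameter lies strictly more than
#' `n_sd` group standard deviations from the group mean are excluded, in a
#' single pass (no re-iteration after removal).
#'
#' @param observer_means numeric vector of per-observer average diameters.
#' @param n_sd exclusion radius in group SDs (default 3).
#' @return logical keep-mask of the same length; attribute `z` holds the
#'   z-scores. A zero group SD keeps everyone, with a warning.
#' @export
exclude_pupil_outlier_observers <- function(observer_means, n_sd = 3) {
  if (length(observer_means) < 3) stop("need at least 3 observers")
  s <- stats::sd(observer_means)
  if (s == 0) {
    warning("zero group SD: no observers excluded")
    keep <- rep(TRUE, length(observer_means))
    attr(keep, "z") <- rep(0, length(observer_means))
    return(keep)
  }
  z <- (observer_means - mean(observer_means)) / s
  keep <- abs(z) <= n_sd
  attr(keep, "z") <- z
  keep
}

#' Preprocess a cohort's pupil traces into condition-mean epochs
#'
#' Runs the full preprocessing chain on each observer's trial-by-trial
#' traces: divisive normalization to the observer's grand mean, epoching to
#' -500..1500 ms around target onset with linear-baseline regression on the
#' pre-onset samples, and interpolation of blink gaps, then averages epochs
#' per condition (optionally restricted by violation magnitude).
#'
#' @param cohort a [simulate_cohort()] result (or any list whose `pupil`
#'   element matches its layout).
#' @param violation_split `"all"`, `"large"` (`|violation| > split_deg`), or
#'   `"small"` (`|violation| <= split_deg`).
#' @param split_deg magnitude defining the split (default 30).
#' @return list of class `pupil_epochs`: `t_rel` (-500..1500), `random` and
#'   `sequential` (observer x time matrices of mean normalized,
#'   baseline-corrected diameter), `observer_ids`, `grand_means`.
#' @export
preprocess_cohort_pupil <- function(cohort,
                                    violation_split = c("all", "large", "small"),
                                    split_deg = 30) {
  violation_split <- match.arg(violation_split)
  if (is.null(cohort$pupil)) stop("cohort has no pupil traces")
  n_obs <- length(cohort$pupil)
  t_rel <- seq(-500, 1500)
  rnd <- seq_mat <- matrix(NA_real_, n_obs, length(t_rel))
  gm <- numeric(n_obs)
  for (i in seq_len(n_obs)) {
    tr <- cohort$pupil[[i]]
    d <- normalize_to_observer_mean(tr$d)
    gm[i] <- attr(d, "grand_mean")
    keep <- switch(violation_split,
                   all = rep(TRUE, nrow(tr$trials)),
                   large = abs(tr$trials$violation) > split_deg,
                   small = abs(tr$trials$violation) <= split_deg)
    ep <- .epoch_matrix(tr$t_rel, d, keep)
    for (cond in c("random", "sequential")) {
      sel <- keep & tr$trials$condition == cond
      sel_in_keep <- tr$trials$condition[keep] == cond
      if (!any(sel)) {
        warning("observer ", i, " has no ", cond, " trials in this split")
        next
      }
      m <- rowMeans(ep[, sel_in_keep, drop = FALSE], na.rm = TRUE)
      if (cond == "random") rnd[i, ] <- m else seq_mat[i, ] <- m
    }
  }
  structure(list(t_rel = t_rel, random = rnd, sequential = seq_mat,
                 observer_ids = seq_len(n_obs), grand_means = gm),
            class = "pupil_epochs")
}

# Epoch + baseline + interpolate all kept trials of one observer's
# peri-target trace matrix (time x trial, t_rel covering at least
# [-500, 1500]). Returns a 2001 x n_kept matrix.
.epoch_matrix <- function(t_rel_trace, d_mat, keep) {
  idx <- match(seq(-500, 1500), t_rel_trace)
  if (anyNA(idx)) stop("cohort traces do not cover the -500..1500 ms epoch")
  sub <- d_mat[idx, keep, drop = FALSE]
  t_rel <- seq(-500, 1500)
  pre <- which(t_rel < 0)
  x <- t_rel[pre]
  n_tr <- ncol(sub)
  out <- matrix(NA_real_, length(t_rel), n_tr)
  # closed-form OLS for complete baselines, per-trial fallback otherwise
  xc <- x - mean(x)
  denom <- sum(xc^2)
  for (j in seq_len(n_tr)) {
    y <- sub[, j]
    yb <- y[pre]
    ok <- !is.na(yb)
    if (sum(ok) < 2) next
    if (all(ok)) {
      slope <- sum(xc * yb) / denom
      intercept <- mean(yb) - slope * mean(x)
    } else {
      xo <- x[ok]; yo <- yb[ok]
      slope <- stats::cov(xo, yo) / stats::var(xo)
      intercept <- mean(yo) - slope * mean(xo)
    }
    y <- y - (intercept + slope * t_rel)
    miss <- is.na(y)
    if (any(miss)) {
      obs <- which(!miss)
      y[miss] <- stats::approx(obs, y[obs], xout = which(miss),
                               method = "linear", rule = 2)$y
    }
    out[, j] <- y
  }
  out
}

#' Per-observer condition-difference time course
#'
#' Sequential-minus-random difference of the condition-mean epochs, the
#' series on which the cluster-mass permutation test is run.
#'
#' @param epochs a `pupil_epochs` object (see [preprocess_cohort_pupil()]).
#' @return list: `t_rel`, `diff` (observer x time matrix), `observer_ids`.
#'   Observers missing either condition are dropped with a warning.
#' @export
condition_difference_course <- function(epochs) {
  ok <- stats::complete.cases(epochs$sequential) &
    stats::complete.cases(epochs$random)
  if (!all(ok)) {
    warning(sum(!ok), " observer(s) dropped: missing a condition mean")
  }
  list(t_rel = epochs$t_rel,
       diff = epochs$sequential[ok, , drop = FALSE] -
         epochs$random[ok, , drop = FALSE],
       observer_ids = epochs$observer_ids[ok])
}

#' Average a difference series over a time window
#'
#' Mean of each observer's difference series over `window` (inclusive,
#' ms relative to target onset), e.g. over the significant cluster found by
#' [cluster_permutation_test()].
#'
#' @param course a [condition_difference_course()] result.
#' @param window length-2 numeric, `c(start_ms, end_ms)`.
#' @return numeric vector, one window-mean per observer.
#' @export
window_average <- function(course, window) {
  stopifnot(length(window) == 2, window[1] <= window[2])
  sel <- course$t_rel >= window[1] & course$t_rel <= window[2]
  if (!any(sel)) stop("window contains no samples of the epoch")
  rowMeans(course$diff[, sel, drop = FALSE])
}
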