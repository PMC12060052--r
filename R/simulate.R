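#' Observer model parameters
#'
#' Parameter set for the generative observer used to synthesize behavioral
#' records and pupil traces with the effect structure expected from
#' expectation-violation experiments: suppressive response-time and
#' precision tuning centered on zero violation in sequential sequences
#' (slower, noisier responses when the expectation is satisfied), temporal
#' integration (faster, more precise responses when penultimate and target
#' are similar, in both conditions), motor priming (faster responses after
#' longer sequences), a repulsive reproduction bias away from the expected
#' orientation, and a surprise-locked pupil dilation that grows with the
#' violation magnitude on sequential trials.
#'
#' Tuning shapes: `G(x; w) = exp(-x^2 / (2 w^2))` is a unit-height Gaussian
#' of the relevant angular difference; the bias uses a unit-peak
#' derivative-of-Gaussian `DoG(x; w) = (x / w) exp(1/2 - x^2 / (2 w^2))`,
#' whose sign matches the sign of the violation (repulsion).
#'
#' @param rt_base baseline median response time, ms.
#' @param rt_sigma scale of the (lognormal, right-skewed) RT noise, ms.
#' @param rt_seq_gain condition-level RT speed-up (ms) on sequential
#'   trials. Together with the suppressive bump this yields the
#'   characteristic pattern: slower than random when the expectation is
#'   satisfied, faster than random when it is strongly violated, and faster
#'   on aggregate.
#' @param rt_pred_amp,rt_pred_width amplitude (ms) and width (deg) of the
#'   suppressive RT tuning on sequential trials: RT is slowed by
#'   `rt_pred_amp * G(violation; rt_pred_width)`.
#' @param rt_integration_amp,rt_integration_width RT speed-up (ms) when
#'   `|target - penultimate|` is small, both conditions.
#' @param rt_len_slope RT decrease per initial grating beyond five
#'   (ms/grating; motor priming from the longer foreperiod).
#' @param choice_sd sensory noise SD (deg) on the speeded clockwise /
#'   counterclockwise judgment.
#' @param lapse_rate probability of a random flip of the speeded choice,
#'   in `[0, 0.5]`.
#' @param repro_sd_base baseline reproduction noise SD, deg.
#' @param repro_sd_seq_gain condition-level reduction of reproduction SD
#'   (deg) on sequential trials, the precision analogue of `rt_seq_gain`.
#' @param repro_sd_pred_amp,repro_sd_pred_width extra reproduction SD (deg)
#'   near zero violation on sequential trials.
#' @param repro_sd_integration_amp reduction of reproduction SD (deg) for
#'   small `|target - penultimate|` (shares `rt_integration_width`).
#' @param bias_amp,bias_width amplitude (deg) and width (deg) of the
#'   repulsive reproduction bias away from the expected orientation.
#' @param pupil_base mean pupil diameter, arbitrary tracker units.
#' @param pupil_drift_sd per-sample (1 ms) SD of the random-walk drift, a.u.
#' @param pupil_event_amp peak amplitude of the stimulus-evoked dilation
#'   kernel per grating, a.u.
#' @param pupil_surprise_gain extra target-locked dilation per degree of
#'   absolute violation on sequential trials, a.u./deg.
#' @param pupil_latency_ms time-to-peak of the dilation kernel, ms.
#' @param pupil_width_ms width of the dilation kernel, ms.
#' @param blink_rate blink rate, Hz.
#' @param blink_dur_ms blink (missing-data) duration, ms.
#' @return an object of class `observer_params` (a named list).
#' @export
observer_params <- function(rt_base = 550, rt_sigma = 80,
                            rt_seq_gain = 30,
                            rt_pred_amp = 50, rt_pred_width = 30,
                            rt_integration_amp = 30,
                            rt_integration_width = 30,
                            rt_len_slope = 5,
                            choice_sd = 3, lapse_rate = 0.02,
                            repro_sd_base = 8, repro_sd_seq_gain = 3,
                            repro_sd_pred_amp = 4, repro_sd_pred_width = 30,
                            repro_sd_integration_amp = 2,
                            bias_amp = 3, bias_width = 30,
                            pupil_base = 1000, pupil_drift_sd = 0.25,
                            pupil_event_amp = 20,
                            pupil_surprise_gain = 0.6,
                            pupil_latency_ms = 800, pupil_width_ms = 450,
                            blink_rate = 0.1, blink_dur_ms = 100) {
  p <- as.list(environment())
  .validate_observer_params(p)
  structure(p, class = "observer_params")
}

# Scales, widths, and rates must be non-negative; effect amplitudes and
# gains may carry either sign so that null and reversed-effect observers
# are expressible.
.validate_observer_params <- function(p) {
  nonneg <- c("rt_sigma", "rt_pred_width", "rt_integration_width",
              "choice_sd", "repro_sd_base", "repro_sd_pred_width",
              "bias_width", "pupil_drift_sd",
              "pupil_width_ms", "blink_rate", "blink_dur_ms")
  for (nm in nonneg) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || p[[nm]] < 0) {
      stop("observer parameter '", nm, "' must be a non-negative scalar")
    }
  }
  if (p$lapse_rate < 0 || p$lapse_rate > 0.5) {
    stop("lapse_rate must lie in [0, 0.5]")
  }
  if (p$rt_base <= 0) stop("rt_base must be positive")
  if (p$pupil_latency_ms <= 0) stop("pupil_latency_ms must be positive")
  invisible(TRUE)
}

# Unit-height Gaussian tuning of an angular difference.
.gauss_tuning <- function(x, width) {
  if (width <= 0) return(rep(0, length(x)))
  exp(-x^2 / (2 * width^2))
}

# Unit-peak derivative-of-Gaussian; sign(x) == sign of output.
.dog_tuning <- function(x, width) {
  if (width <= 0) return(rep(0, length(x)))
  (x / width) * exp(0.5 - x^2 / (2 * width^2))
}

#' Simulate speeded choices, response times, and reproductions
#'
#' Applies the observer model to one or more trial specifications.
#' Response time is `rt_base - rt_len_slope * (n_initial - 5) +
#' rt_pred_amp * G(violation) * [sequential] -
#' rt_integration_amp * G(target - penultimate)` plus lognormal noise of
#' scale `rt_sigma`; responses slower than the 2000 ms speeded window are
#' recorded as missed (`rt = NA`). The speeded choice is the sign of the
#' target orientation plus sensory noise relative to vertical, flipped with
#' probability `lapse_rate`. The reproduction is the target plus the
#' repulsive bias term plus wrapped-normal noise (normal noise on the axial
#' scale, wrapped to `[0, 180)`) whose SD carries the precision tuning.
#'
#' @param trials a `session_design` or data frame of trial specifications.
#' @param params an [observer_params()] object.
#' @param observer_id identifier copied into the output.
#' @return data frame with one row per trial: `observer_id`, `trial_id`,
#'   `condition`, `n_initial`, `violation`, `dp` (wrapped target minus
#'   penultimate), `choice` ("cw"/"ccw"), `choice_correct`, `rt` (ms, `NA`
#'   when missed), `missed`, `reproduction` (deg on `[0, 180)`),
#'   `repro_error` (signed deg in `(-90, 90]`).
#' @export
simulate_behavior <- function(trials, params = observer_params(),
                              observer_id = 1L) {
  stopifnot(is.data.frame(trials))
  .validate_observer_params(params)
  need <- c("condition", "n_initial", "violation", "penultimate", "target")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stop("trials lack columns: ", paste(miss, collapse = ", "))
  n <- nrow(trials)
  is_seq <- trials$condition == "sequential"
  dp <- axial_wrap(trials$target - trials$penultimate)
  v <- trials$violation

  rt_det <- params$rt_base -
    params$rt_len_slope * (trials$n_initial - 5) -
    params$rt_seq_gain * is_seq +
    params$rt_pred_amp * .gauss_tuning(v, params$rt_pred_width) * is_seq -
    params$rt_integration_amp * .gauss_tuning(dp, params$rt_integration_width)
  rt <- rt_det + params$rt_sigma * stats::rlnorm(n, 0, 0.5)
  missed <- rt > 2000
  rt[missed] <- NA_real_

  percept <- axial_wrap(trials$target + stats::rnorm(n, 0, params$choice_sd))
  choice_cw <- percept > 0
  lapse <- stats::runif(n) < params$lapse_rate
  choice_cw <- xor(choice_cw, lapse)
  truth_cw <- axial_wrap(trials$target) > 0

  sd_rep <- params$repro_sd_base -
    params$repro_sd_seq_gain * is_seq +
    params$repro_sd_pred_amp * .gauss_tuning(v, params$repro_sd_pred_width) * is_seq -
    params$repro_sd_integration_amp * .gauss_tuning(dp, params$rt_integration_width)
  sd_rep <- pmax(sd_rep, 0.5)
  bias <- params$bias_amp * .dog_tuning(v, params$bias_width) * is_seq
  reproduction <- wrap_orientation(trials$target + bias +
                                     stats::rnorm(n, 0, sd_rep))

  data.frame(
    observer_id = observer_id,
    trial_id = if ("trial_id" %in% names(trials)) trials$trial_id else seq_len(n),
    condition = trials$condition,
    n_initial = trials$n_initial,
    violation = v,
    dp = dp,
    choice = ifelse(choice_cw, "cw", "ccw"),
    choice_correct = choice_cw == truth_cw,
    rt = rt,
    missed = missed,
    reproduction = reproduction,
    repro_error = axial_wrap(reproduction - trials$target),
    stringsAsFactors = FALSE
  )
}

# Gamma-shaped (Erlang-like) dilation impulse response, unit peak at
# `latency` ms; `width` controls the kernel's spread.
.pupil_kernel <- function(t_ms, latency, width) {
  k <- numeric(length(t_ms))
  pos <- t_ms > 0
  shape <- max((latency / max(width, 1))^2, 1.05)
  tm <- t_ms[pos] / latency
  # (t/L)^s exp(s (1 - t/L)): unit peak exactly at t == latency
  k[pos] <- tm^shape * exp(shape * (1 - tm))
  k
}

#' Simulate a full-trial 1 kHz pupil trace
#'
#' Diameter = baseline + random-walk drift + one dilation kernel per grating
#' onset + a surprise component at target onset whose amplitude is
#' `pupil_surprise_gain * |violation|` on sequential trials. Blinks arrive
#' as a Poisson process and mark `blink_dur_ms` of samples missing
#' (diameter `NA`).
#'
#' @param trial one-row trial specification (see [generate_trial()]).
#' @param params an [observer_params()] object.
#' @param post_target_ms trace duration after target onset (default 1600).
#' @param observer_id identifier copied into the output.
#' @return data frame with columns `observer_id`, `trial_id`, `t` (ms from
#'   trial start, 1 ms steps), `d` (diameter, `NA` when missing), `missing`,
#'   and attribute `target_onset_ms`.
#' @export
simulate_pupil <- function(trial, params = observer_params(),
                           post_target_ms = 1600, observer_id = 1L) {
  stopifnot(is.data.frame(trial), nrow(trial) == 1)
  .validate_observer_params(params)
  soa <- 250 + 32
  n_gratings <- trial$n_initial + 2L
  onsets <- soa * (seq_len(n_gratings) - 1)
  target_onset <- onsets[n_gratings]
  t <- seq(0, target_onset + post_target_ms)
  n <- length(t)

  drift <- cumsum(stats::rnorm(n, 0, params$pupil_drift_sd))
  d <- params$pupil_base + drift
  for (k in seq_len(n_gratings - 1)) {
    d <- d + params$pupil_event_amp *
      .pupil_kernel(t - onsets[k], params$pupil_latency_ms,
                    params$pupil_width_ms)
  }
  amp <- params$pupil_event_amp +
    params$pupil_surprise_gain * abs(trial$violation) *
    (trial$condition == "sequential")
  d <- d + amp * .pupil_kernel(t - target_onset, params$pupil_latency_ms,
                               params$pupil_width_ms)

  missing <- .blink_mask(n, params)
  d[missing] <- NA_real_
  out <- data.frame(observer_id = observer_id,
                    trial_id = if ("trial_id" %in% names(trial)) trial$trial_id else 1L,
                    t = t, d = d, missing = missing)
  attr(out, "target_onset_ms") <- target_onset
  out
}

.blink_mask <- function(n, params) {
  missing <- rep(FALSE, n)
  if (params$blink_rate > 0 && params$blink_dur_ms > 0) {
    n_blinks <- stats::rpois(1, params$blink_rate * n / 1000)
    if (n_blinks > 0) {
      starts <- sample.int(n, n_blinks)
      for (s in starts) {
        missing[s:min(n, s + params$blink_dur_ms - 1)] <- TRUE
      }
    }
  }
  missing
}

# Fast path used by simulate_cohort(): peri-target traces for all trials of
# one observer at once, as a (pre+post+1) x n_trials matrix. Grating events
# at multiples of the 282 ms SOA before target onset are included when they
# fall inside the window; earlier events only shift the local baseline and
# are absorbed by the epoch baseline regression downstream.
.simulate_pupil_matrix <- function(trials, params, pre_ms = 700,
                                   post_ms = 1600) {
  n_tr <- nrow(trials)
  t_rel <- seq(-pre_ms, post_ms)
  nt <- length(t_rel)
  soa <- 282
  base_kernel <- numeric(nt)
  k_prev <- 1
  while (k_prev * soa <= pre_ms + 0) {
    base_kernel <- base_kernel + params$pupil_event_amp *
      .pupil_kernel(t_rel + k_prev * soa, params$pupil_latency_ms,
                    params$pupil_width_ms)
    k_prev <- k_prev + 1
  }
  target_kernel <- .pupil_kernel(t_rel, params$pupil_latency_ms,
                                 params$pupil_width_ms)
  amp <- params$pupil_event_amp +
    params$pupil_surprise_gain * abs(trials$violation) *
    (trials$condition == "sequential")

  noise <- matrix(stats::rnorm(nt * n_tr, 0, params$pupil_drift_sd), nt, n_tr)
  drift <- apply(noise, 2, cumsum)
  d <- params$pupil_base + drift + base_kernel +
    outer(target_kernel, amp)

  missing <- matrix(FALSE, nt, n_tr)
  if (params$blink_rate > 0 && params$blink_dur_ms > 0) {
    n_blinks <- stats::rpois(n_tr, params$blink_rate * nt / 1000)
    for (j in which(n_blinks > 0)) {
      starts <- sample.int(nt, n_blinks[j])
      for (s in starts) {
        missing[s:min(nt, s + params$blink_dur_ms - 1), j] <- TRUE
      }
    }
    d[missing] <- NA_real_
  }
  list(t_rel = t_rel, d = d, missing = missing)
}

#' Simulate a cohort of observers
#'
#' Draws per-observer parameters from a truncated-normal population around
#' `population_means` (an [observer_params()] object) with SDs
#' `population_sds` (a named list; parameters not named there are fixed at
#' the population mean), then simulates behavior for every trial of
#' `design` and, optionally, peri-target pupil traces.
#'
#' @param n_observers number of observers (>= 2).
#' @param design a `session_design`.
#' @param population_means [observer_params()] giving population means.
#' @param population_sds named list of population SDs; e.g.
#'   `list(rt_base = 60, repro_sd_base = 1.5)`.
#' @param seed integer seed; the cohort is a deterministic function of it.
#' @param trait_cor correlation (in `[0, 1)`) induced within two observer
#'   trait groups: general performance (`rt_base`, `repro_sd_base`) and
#'   surprise sensitivity (the sequential gains, suppressive amplitudes,
#'   and pupil surprise gain). Produces realistic between-observer
#'   correlations of the speed, precision, and pupil effects.
#' @param pupil simulate pupil traces (`TRUE`) or behavior only.
#' @param pupil_pre_ms,pupil_post_ms peri-target trace window (ms before /
#'   after target onset) used for the cohort traces.
#' @return list of class `cohort` with elements `behavior` (long data
#'   frame), `pupil` (`NULL`, or per-observer list with `t_rel`, diameter
#'   matrix `d` (time x trial), `missing` mask, and the trial metadata),
#'   `params` (per-observer parameter data frame), `design`, `seed`.
#' @export
simulate_cohort <- function(n_observers, design,
                            population_means = observer_params(),
                            population_sds = list(),
                            seed = 1, trait_cor = 0.4, pupil = TRUE,
                            pupil_pre_ms = 700, pupil_post_ms = 1600) {
  if (n_observers < 2) stop("n_observers must be >= 2")
  if (trait_cor < 0 || trait_cor >= 1) stop("trait_cor must lie in [0, 1)")
  .validate_observer_params(population_means)
  if (length(population_sds)) {
    bad <- setdiff(names(population_sds), names(population_means))
    if (length(bad)) stop("unknown population_sds: ", paste(bad, collapse = ", "))
    if (any(unlist(population_sds) < 0)) stop("population SDs must be >= 0")
  }
  set.seed(as.integer(seed))

  par_rows <- vector("list", n_observers)
  beh <- vector("list", n_observers)
  pup <- if (pupil) vector("list", n_observers) else NULL
  for (i in seq_len(n_observers)) {
    p <- .draw_observer(population_means, population_sds, trait_cor)
    par_rows[[i]] <- as.data.frame(unclass(p))
    beh[[i]] <- simulate_behavior(design, p, observer_id = i)
    if (pupil) {
      tr <- .simulate_pupil_matrix(design, p, pupil_pre_ms, pupil_post_ms)
      tr$trials <- data.frame(trial_id = design$trial_id,
                              condition = design$condition,
                              violation = design$violation)
      pup[[i]] <- tr
    }
  }
  params_df <- do.call(rbind, par_rows)
  params_df$observer_id <- seq_len(n_observers)
  structure(list(behavior = do.call(rbind, beh), pupil = pup,
                 params = params_df, design = design,
                 seed = as.integer(seed)),
            class = "cohort")
}

# Truncated-normal draw of one observer's parameters; truncation keeps each
# parameter inside its validity domain (amplitudes may be negative only
# where the model allows it -- effect amplitudes are left unconstrained in
# sign so null and reversed-effect populations can be simulated).
# `trait_cor` induces positive correlations within two trait groups: a
# general-performance factor (slow observers are also imprecise) and a
# surprise-sensitivity factor (shared by the condition-level gains, the
# suppressive tuning amplitudes, and the pupil surprise gain), which is
# what makes the between-observer effect correlations non-trivial.
.trait_groups <- list(
  general = c("rt_base", "repro_sd_base"),
  surprise = c("rt_seq_gain", "repro_sd_seq_gain", "rt_pred_amp",
               "repro_sd_pred_amp", "pupil_surprise_gain"))

.draw_observer <- function(means, sds, trait_cor = 0) {
  p <- unclass(means)
  signed_ok <- c("rt_seq_gain", "rt_pred_amp", "rt_integration_amp",
                 "rt_len_slope", "repro_sd_seq_gain", "repro_sd_pred_amp",
                 "repro_sd_integration_amp", "bias_amp",
                 "pupil_surprise_gain")
  shared <- lapply(.trait_groups, function(g) stats::rnorm(1))
  for (nm in names(sds)) {
    grp <- names(.trait_groups)[vapply(.trait_groups, function(g) nm %in% g,
                                       TRUE)]
    z <- if (length(grp) && trait_cor > 0) {
      sqrt(trait_cor) * shared[[grp[1]]] +
        sqrt(1 - trait_cor) * stats::rnorm(1)
    } else {
      stats::rnorm(1)
    }
    val <- p[[nm]] + sds[[nm]] * z
    if (!nm %in% signed_ok) {
      lim <- if (nm == "lapse_rate") c(0, 0.5) else c(0, Inf)
      val <- min(max(val, lim[1]), lim[2])
    }
    p[[nm]] <- val
  }
  # keep the derived SD floor sane
  p$repro_sd_base <- max(p$repro_sd_base, 1)
  structure(p, class = "observer_params")
}
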