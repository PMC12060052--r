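test_that("divisive normalization is scale-invariant with unit mean", {
  set.seed(1)
  d <- 900 + rnorm(5000, 0, 20)
  n1 <- normalize_to_observer_mean(d)
  expect_equal(mean(n1), 1, tolerance = 1e-12)
  expect_equal(as.numeric(normalize_to_observer_mean(3 * d)),
               as.numeric(n1), tolerance = 1e-12)
  cst <- rep(42, 100)
  expect_equal(as.numeric(normalize_to_observer_mean(cst)), rep(1, 100))
  # subtractive variant centers instead
  expect_equal(mean(normalize_to_observer_mean(d, "subtractive")), 0,
               tolerance = 1e-12)
  expect_error(normalize_to_observer_mean(rep(NA_real_, 10)), "missing")
})

test_that("baseline regression cancels linear trends exactly", {
  t <- 0:4000
  onset <- 2000
  ramp <- 5 + 0.01 * t
  ep <- epoch_and_baseline(t, ramp, onset)
  expect_s3_class(ep, "pupil_epoch")
  expect_equal(length(ep$d), 2001)
  expect_lt(max(abs(ep$d)), 1e-9)
  cst <- rep(7, length(t))
  expect_lt(max(abs(epoch_and_baseline(t, cst, onset)$d)), 1e-12)
  # ramp + post-onset boxcar passes the boxcar through untouched
  h <- 0.35
  box <- ramp + h * (t >= onset + 300 & t <= onset + 800)
  epb <- epoch_and_baseline(t, box, onset)
  expected <- h * (ep$t_rel >= 300 & ep$t_rel <= 800)
  expect_equal(epb$d, expected, tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(epoch_and_baseline(t, ramp, 100), "cover")
})

test_that("pre-onset residuals vanish by construction on noisy epochs", {
  set.seed(2)
  t <- 0:3000
  for (i in 1:20) {
    d <- 1000 + cumsum(rnorm(length(t), 0, 0.3))
    ep <- epoch_and_baseline(t, d, 1200)
    pre <- ep$d[ep$t_rel < 0]
    expect_lt(abs(mean(pre)), 1e-9)
    expect_lt(abs(coef(lm(pre ~ seq_along(pre)))[2]), 1e-11)
  }
})

test_that("baselining is idempotent", {
  set.seed(3)
  t <- 0:3000
  d <- 1000 + cumsum(rnorm(length(t), 0, 0.3))
  ep1 <- epoch_and_baseline(t, d, 1000)
  ep2 <- epoch_and_baseline(ep1$t_rel + 500, ep1$d, 500)
  expect_equal(ep2$d, ep1$d, tolerance = 1e-9)
  expect_lt(abs(ep2$baseline_fit["slope"]), 1e-12)
})

test_that("gap interpolation is linear inside, flat at the edges", {
  ep <- list(d = c(1.0, NA, 2.0, NA, NA, 5.0), missing = rep(FALSE, 6))
  out <- interpolate_missing(ep)
  expect_equal(out$d, c(1, 1.5, 2, 3, 4, 5))
  expect_equal(out$interpolated_mask, c(FALSE, TRUE, FALSE, TRUE, TRUE, FALSE))
  # identity when nothing is missing
  ep2 <- list(d = 1:5 / 2, missing = rep(FALSE, 5))
  expect_equal(interpolate_missing(ep2)$d, 1:5 / 2)
  # leading/trailing gaps held at the nearest value
  ep3 <- list(d = c(NA, NA, 3, 4, NA), missing = rep(FALSE, 5))
  expect_equal(interpolate_missing(ep3)$d, c(3, 3, 3, 4, 4))
  ep4 <- list(d = rep(NA_real_, 4), missing = rep(FALSE, 4), valid = TRUE)
  expect_warning(out4 <- interpolate_missing(ep4), "fully missing")
  expect_false(out4$valid)
})

test_that("interpolating a blink over a smooth kernel stays within the curvature bound", {
  t <- 0:3000
  lat <- 800; wid <- 450
  shape <- (lat / wid)^2
  kern <- function(x) ifelse(x > 0, (x / lat)^shape * exp(shape * (1 - x / lat)), 0)
  d <- 1000 + 30 * kern(t - 1000)
  onset <- 1000
  ep <- epoch_and_baseline(t, d, onset)
  truth <- ep$d
  # plant a 100 ms blink around the kernel's rise
  blink <- ep$t_rel >= 300 & ep$t_rel < 400
  ep$d[blink] <- NA
  out <- interpolate_missing(ep)
  err <- max(abs(out$d[blink] - truth[blink]))
  # Taylor bound: |f''|max * (L/2)^2 / 2 over the gap
  curv <- max(abs(diff(diff(truth))))
  expect_lt(err, curv * 50^2 / 2 + 1e-9)
})

test_that("pupil-size outlier exclusion is single-pass and strict at 3 SD", {
  m <- rep(1000, 30)
  expect_warning(keep <- exclude_pupil_outlier_observers(m), "zero group SD")
  expect_true(all(keep))
  set.seed(4)
  m2 <- rnorm(30, 1000, 10)
  m2[7] <- 1000 + 10 * sd(m2[-7]) * 3  # a far outlier
  keep2 <- exclude_pupil_outlier_observers(m2)
  expect_false(keep2[7])
  expect_equal(sum(!keep2), 1)
  # exactly 3.0 SD is kept (strict >): with 17 zeros and a +-a pair the
  # extremes sit at exactly 3 group SDs
  x <- c(6, -6, rep(0, 17))
  expect_equal(max(abs(attr(exclude_pupil_outlier_observers(x), "z"))), 3)
  expect_true(all(exclude_pupil_outlier_observers(x)))
  expect_error(exclude_pupil_outlier_observers(c(1, 2)), "3 observers")
})

test_that("condition differences and window averages behave as integrals", {
  co <- small_cohort(4, seed = 8, pupil = TRUE)
  ep <- preprocess_cohort_pupil(co, "all")
  course <- condition_difference_course(ep)
  expect_equal(dim(course$diff), c(4, 2001))
  # identical conditions give a zero series
  ep0 <- ep
  ep0$random <- ep0$sequential
  c0 <- condition_difference_course(ep0)
  expect_equal(max(abs(c0$diff)), 0)
  # boxcar window mean: direct integration oracle
  h <- 0.2
  c0$diff[] <- 0
  box <- c0$t_rel >= 600 & c0$t_rel <= 1100
  c0$diff[, box] <- h
  win <- c0$t_rel >= 563 & c0$t_rel <= 1100
  expected <- h * sum(box & win) / sum(win)
  expect_equal(unname(window_average(c0, c(563, 1100))),
               rep(expected, 4), tolerance = 1e-12)
  # constant series returns the constant; single-sample window that sample
  c0$diff[] <- 0.7
  expect_equal(unname(window_average(c0, c(-500, 1500))), rep(0.7, 4))
  c0$diff[2, c0$t_rel == 1000] <- 9
  expect_equal(window_average(c0, c(1000, 1000))[2], 9)
  expect_error(window_average(c0, c(1600, 1700)), "window")
})

test_that("large-violation split carries the surprise effect, small split attenuates it", {
  d <- generate_session_exp1(seed = 41)
  co <- simulate_cohort(10, d, seed = 41, pupil = TRUE,
                        population_means = observer_params(
                          pupil_drift_sd = 0.1, pupil_surprise_gain = 0.8))
  large <- preprocess_cohort_pupil(co, "large")
  small <- preprocess_cohort_pupil(co, "small")
  win <- large$t_rel >= 500 & large$t_rel <= 1100
  eff_large <- mean((large$sequential - large$random)[, win])
  eff_small <- mean((small$sequential - small$random)[, win])
  expect_gt(eff_large, 0)
  expect_gt(eff_large, eff_small)
})
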