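make_beh <- function(acc_by_obs, n_trials = 40) {
  do.call(rbind, lapply(seq_along(acc_by_obs), function(i) {
    n_ok <- round(acc_by_obs[i] * n_trials)
    data.frame(observer_id = i, trial_id = seq_len(n_trials),
               condition = rep(c("random", "sequential"),
                               length.out = n_trials),
               n_initial = rep(5:12, length.out = n_trials),
               violation = seq(-89, 90, length.out = n_trials),
               choice_correct = rep(c(TRUE, FALSE),
                                    c(n_ok, n_trials - n_ok)),
               rt = 500 + seq_len(n_trials),
               missed = FALSE,
               repro_error = rnorm(n_trials, 0, 5))
  }))
}

test_that("accuracy exclusion is strict at the threshold", {
  set.seed(1)
  beh <- make_beh(c(0.74, 0.75, 0.90), n_trials = 100)
  res <- exclude_by_accuracy(beh)
  expect_equal(res$excluded$observer_id, "1")
  expect_setequal(unique(res$kept$observer_id), c(2, 3))
  expect_equal(res$excluded$reason, "accuracy")
  expect_error(exclude_by_accuracy(beh[0, ]), "empty")
})

test_that("missed trials are dropped before the accuracy denominator", {
  set.seed(2)
  beh <- make_beh(0.8, n_trials = 100)
  # 20 incorrect of 100; marking 10 incorrect trials as missed lifts
  # accuracy to 80/90
  beh$missed[beh$choice_correct == FALSE][1:10] <- TRUE
  res <- exclude_by_accuracy(beh, threshold = 0.85)
  expect_equal(res$accuracy$prop_correct, 80 / 90)
})

test_that("correct-trial filter logs retention and warns when empty", {
  set.seed(3)
  beh <- make_beh(c(0.8, 1.0))
  out <- correct_trials_only(beh)
  expect_true(all(out$choice_correct))
  expect_equal(attr(out, "retention"), mean(beh$choice_correct))
  allwrong <- make_beh(0)
  expect_warning(out0 <- correct_trials_only(allwrong), "no correct")
  expect_equal(nrow(out0), 0)
})

test_that("condition summaries are permutation-invariant and flag empties", {
  co <- small_cohort(5, seed = 4)
  beh <- correct_trials_only(co$behavior)
  s1 <- condition_summaries(beh)
  s2 <- condition_summaries(beh[sample(nrow(beh)), ])
  expect_equal(s1, s2)
  expect_equal(nrow(s1), 10)
  # single-trial condition exercises the undefined-precision path
  one <- beh[beh$observer_id == 1, ]
  one <- one[c(which(one$condition == "random")[1],
               which(one$condition == "sequential")), ]
  expect_warning(s3 <- condition_summaries(one), "single-trial")
  expect_true(is.na(s3$precision[s3$condition == "random"]))
})

test_that("violation bins tile the range and conserve trials", {
  expect_equal(diff(violation_bins(8)), rep(22.5, 8))
  expect_equal(diff(violation_bins(8, signed = FALSE)), rep(11.25, 8))
  co <- small_cohort(4, seed = 6)
  beh <- correct_trials_only(co$behavior)
  tc <- tuning_by_violation(beh)
  expect_s3_class(tc, "tuning_curve")
  expect_equal(sum(tc$n_trials), nrow(beh))
  # per observer x condition conservation
  agg <- tapply(tc$n_trials, list(tc$observer_id, tc$condition), sum)
  cnt <- table(beh$observer_id, beh$condition)
  expect_equal(unclass(agg), unclass(cnt)[, c("random", "sequential")],
               ignore_attr = TRUE)
  # unsigned folding keeps every trial too
  tu <- tuning_by_violation(beh, signed = FALSE)
  expect_equal(sum(tu$n_trials), nrow(beh))
})

test_that("suppressive RT tuning surfaces as a peak at zero violation", {
  d <- generate_session_exp1(seed = 31)
  set.seed(31)
  b <- do.call(rbind, lapply(1:6, function(i) {
    simulate_behavior(d, observer_params(rt_sigma = 20), observer_id = i)
  }))
  tc <- tuning_by_violation(correct_trials_only(b))
  seq_rt <- tapply(tc$mean_rt[tc$condition == "sequential"],
                   tc$bin[tc$condition == "sequential"], mean)
  expect_true(which.max(seq_rt) %in% c(4, 5))
})

test_that("repulsive bias has the sign of the violation near zero", {
  d <- generate_session_exp1(seed = 32)
  set.seed(32)
  b <- do.call(rbind, lapply(1:8, function(i) {
    simulate_behavior(d, observer_params(bias_amp = 4), observer_id = i)
  }))
  bias <- bias_by_violation(correct_trials_only(b))
  grp <- tapply(bias$bias[bias$condition == "sequential"],
                bias$bin_center[bias$condition == "sequential"], mean)
  ctr <- as.numeric(names(grp))
  near <- abs(ctr) < 30
  expect_true(all(sign(grp[near]) == sign(ctr[near])))
})

test_that("median split assigns ties to the short half", {
  beh <- data.frame(observer_id = 1,
                    condition = rep(c("random", "sequential"), each = 6),
                    n_initial = rep(c(5, 6, 7, 8, 9, 10), 2),
                    rt = rep(c(600, 590, 580, 570, 560, 550), 2),
                    repro_error = rep(c(1, -1, 2, -2, 3, -3), 2))
  ms <- median_split_by_length(beh)
  # median 7.5: 5-7 short, 8-10 long
  expect_equal(ms$n_trials, rep(3L, 4))
  expect_lt(ms$mean_rt[ms$half == "long"][1],
            ms$mean_rt[ms$half == "short"][1])
  beh2 <- beh
  beh2$n_initial <- rep(c(5, 6, 7, 8, 9, 9), 2)
  # median 7.5 -> same split; constant length errors out
  behc <- beh
  behc$n_initial <- 7
  expect_error(median_split_by_length(behc), "constant")
})
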