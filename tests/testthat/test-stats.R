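test_that("paired t handles equality, degeneracy, and direction", {
  x <- c(1, 2, 3, 4)
  res <- paired_t(x, x)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  expect_equal(res$df, 3)
  expect_warning(inf <- paired_t(x + 1, x), "infinite")
  expect_identical(inf$t, Inf)
  expect_equal(inf$df, 3)
  # one-tailed halves the symmetric p on the favorable side
  set.seed(1)
  a <- rnorm(20); b <- 0.8 * a - 0.5
  two <- paired_t(a, b, "two")
  one <- paired_t(a, b, "greater")
  expect_equal(one$p, two$p / 2, tolerance = 1e-12)
  expect_error(paired_t(1, 1), "2 complete pairs")
})

test_that("paired t rejection rate is calibrated under the null", {
  set.seed(2)
  n <- 52
  reps <- 10000
  x <- matrix(rnorm(n * reps), reps, n)
  # vectorized equivalent of paired_t(x_i, 0): validated against the
  # function on a subsample below
  tv <- rowMeans(x) / (apply(x, 1, sd) / sqrt(n))
  rate <- mean(abs(tv) > qt(0.975, n - 1))
  expect_lt(abs(rate - 0.05), 0.01)
  for (i in 1:25) {
    expect_equal(paired_t(x[i, ], rep(0, n))$t, tv[i], tolerance = 1e-10)
  }
})

test_that("RM-ANOVA reproduces a hand-computed partition", {
  set.seed(3)
  d <- expand.grid(s = factor(1:3), a = c("x", "y"), b = factor(1:4))
  d$y <- rnorm(nrow(d)) + (d$a == "x") * 2 + as.numeric(d$b) * 0.5
  res <- rm_anova_2way(d, "y", "s", "a", "b")
  # oracle: direct sums-of-squares computation
  am <- tapply(d$y, list(d$s, d$a), mean)
  ss_a <- 4 * 3 * sum((colMeans(am) - mean(am))^2)
  ss_sa <- 4 * sum((am - outer(rowMeans(am), rep(1, 2)) -
                      outer(rep(1, 3), colMeans(am)) + mean(am))^2)
  F_a <- (ss_a / 1) / (ss_sa / 2)
  expect_equal(res$F[1], F_a, tolerance = 1e-10)
  expect_equal(res$df1, c(1, 3, 3))
  expect_equal(res$df2, c(2, 6, 6))

  bm <- tapply(d$y, list(d$s, d$b), mean)
  ss_b <- 2 * 3 * sum((colMeans(bm) - mean(bm))^2)
  ss_sb <- 2 * sum((bm - outer(rowMeans(bm), rep(1, 4)) -
                      outer(rep(1, 3), colMeans(bm)) + mean(bm))^2)
  expect_equal(res$F[2], (ss_b / 3) / (ss_sb / 6), tolerance = 1e-10)
})

test_that("RM-ANOVA degenerates and deletes listwise as specified", {
  d <- expand.grid(s = 1:4, a = c("x", "y"), b = 1:3)
  d$y <- 5
  res <- rm_anova_2way(d, "y", "s", "a", "b")
  expect_equal(res$F, rep(0, 3), tolerance = 1e-10)
  d2 <- d
  d2$y <- rnorm(nrow(d2))
  d2$y[d2$s == 4 & d2$a == "x" & d2$b == 1] <- NA
  expect_warning(res2 <- rm_anova_2way(d2, "y", "s", "a", "b"), "listwise")
  expect_equal(attr(res2, "n_observers"), 3)
  # Greenhouse-Geisser epsilon bounded in [1/(k-1), 1]
  set.seed(4)
  d3 <- expand.grid(s = 1:6, a = c("x", "y"), b = 1:4)
  d3$y <- rnorm(nrow(d3))
  res3 <- rm_anova_2way(d3, "y", "s", "a", "b", gg = TRUE)
  expect_true(all(res3$eps >= c(1, 1 / 3, 1 / 3) - 1e-9))
  expect_true(all(res3$eps <= 1 + 1e-9))
  # a two-level factor has a single contrast: no correction possible
  expect_equal(res3$eps[1], 1)
  # shrinking the dfs is conservative wherever F exceeds 1
  big <- res3$F > 1
  expect_true(all(res3$p_gg[big] >= res3$p[big] - 1e-9))
})

test_that("RM-ANOVA keeps the nominal rate on null tuning tables", {
  set.seed(5)
  rej <- replicate(400, {
    d <- expand.grid(s = 1:10, a = c("r", "q"), b = 1:4)
    d$y <- rnorm(nrow(d))
    rm_anova_2way(d, "y", "s", "a", "b")$p[3] < 0.05
  })
  expect_lt(abs(mean(rej) - 0.05), 0.025)
})

test_that("cluster test finds nothing when conditions are identical", {
  set.seed(6)
  x <- matrix(rnorm(10 * 80), 10, 80)
  res <- cluster_permutation_test(x, x, n_perm = 200)
  expect_equal(nrow(res$clusters), 0)
  # constant difference series: zero variance handled without clusters
  res2 <- cluster_permutation_test(matrix(0, 5, 40), n_perm = 120)
  expect_equal(sum(res2$clusters$significant), 0)
})

test_that("Monte-Carlo null matches an independently coded exhaustive oracle", {
  set.seed(7)
  n <- 8
  D <- matrix(rnorm(n * 50), n, 50)
  # independent oracle: enumerate all 2^8 sign patterns with separate code
  tcrit <- qt(0.975, n - 1)
  oracle_max_pos <- function(tv) {
    sig <- abs(tv) > tcrit
    if (!any(sig)) return(0)
    lab <- sig * sign(tv)
    r <- rle(lab)
    e <- cumsum(r$lengths); s <- e - r$lengths + 1
    masses <- sapply(which(r$values == 1),
                     function(i) sum(tv[s[i]:e[i]]))
    if (!length(masses)) 0 else max(masses)
  }
  signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  null <- apply(signs, 1, function(sg) {
    Ds <- sg * D
    tv <- colMeans(Ds) / (apply(Ds, 2, sd) / sqrt(n))
    oracle_max_pos(tv)
  })
  thr_oracle <- quantile(null, 0.975, names = FALSE)
  res <- cluster_permutation_test(D, n_perm = 1000, tail = "two", seed = 1)
  expect_true(res$exhaustive)  # 2^8 <= 1000: the null is enumerated exactly
  expect_lt(abs(res$threshold_pos - thr_oracle) / thr_oracle, 0.05)
  # forced Monte-Carlo sampling approximates the same threshold
  mc <- cluster_permutation_test(D, n_perm = 4000, tail = "two", seed = 2,
                                 enumerate = "never")
  expect_lt(abs(mc$threshold_pos - thr_oracle) / thr_oracle, 0.1)
})

test_that("cluster threshold is symmetric under a global sign flip", {
  set.seed(8)
  D <- matrix(rnorm(12 * 60), 12, 60)
  a <- cluster_permutation_test(D, n_perm = 500, seed = 5)
  b <- cluster_permutation_test(-D, n_perm = 500, seed = 5)
  expect_equal(a$threshold_pos, b$threshold_neg, tolerance = 1e-9)
  expect_equal(a$threshold_neg, b$threshold_pos, tolerance = 1e-9)
  # determinism: same seed, identical result
  c1 <- cluster_permutation_test(D, n_perm = 500, seed = 5,
                                 enumerate = "never")
  c2 <- cluster_permutation_test(D, n_perm = 500, seed = 5,
                                 enumerate = "never")
  expect_identical(c1, c2)
})

test_that("an injected boxcar effect is localized by the cluster test", {
  set.seed(9)
  hits <- overlaps <- logical(25)
  for (i in 1:25) {
    D <- matrix(rnorm(30 * 200), 30, 200)
    D[, 60:100] <- D[, 60:100] + 1   # d ~ 1 boxcar
    res <- cluster_permutation_test(D, n_perm = 500, seed = i)
    sig <- res$clusters[res$clusters$significant & res$clusters$sign > 0, ]
    hits[i] <- nrow(sig) > 0
    if (hits[i]) {
      j <- which.max(sig$mass)
      ov <- max(0, min(sig$end[j], 100) - max(sig$start[j], 60) + 1)
      overlaps[i] <- ov >= 0.8 * 41
    }
  }
  expect_gte(mean(hits), 0.95)
  expect_gte(mean(overlaps), 0.95)
})

test_that("skipped correlation equals Pearson on clean data", {
  set.seed(10)
  x <- 1:50 / 10
  y <- 2 * x + 1
  res <- skipped_pearson(x, y)
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_equal(length(res$outlier_ids), 0)
  n <- 500
  x2 <- rnorm(n); y2 <- 0.5 * x2 + rnorm(n) * sqrt(0.75)
  res2 <- skipped_pearson(x2, y2)
  expect_lt(abs(res2$r - cor(x2, y2)), 0.05)
  expect_lt((n - res2$n_used) / n, 0.08)
  expect_error(skipped_pearson(1:5, 1:5), "at least 10")
})

test_that("planted leverage points are flagged and the estimate recovers", {
  set.seed(11)
  n <- 500
  x <- rnorm(n); y <- 0.5 * x + rnorm(n) * sqrt(0.75)
  xo <- c(x, rnorm(25, 10, 0.5))
  yo <- c(y, rnorm(25, -10, 0.5))
  naive <- cor(xo, yo)
  res <- skipped_pearson(xo, yo)
  expect_gte(mean((n + 1):(n + 25) %in% res$outlier_ids), 0.9)
  expect_lt(abs(res$r - 0.5), 0.1)
  expect_lt(naive, 0.2)  # contamination destroys the naive estimate
  # MCD center route agrees on this configuration
  res_mcd <- skipped_pearson(xo, yo, center = "mcd")
  expect_equal(res_mcd$r, res$r, tolerance = 0.05)
})
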