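#' Paired t-test
#'
#' Classical paired t-test with `df = n - 1`. A one-tailed
#' (`tail = "greater"`) variant is used for directional hypotheses such as
#' increased pupil dilation on surprising trials.
#'
#' @param x,y equal-length paired samples (`n >= 2`).
#' @param tail `"two"` (default) or `"greater"` (mean of `x - y` > 0).
#' @return list `t`, `df`, `p`, `mean_diff`, `tail`. Zero-variance
#'   differences give `t = 0, p = 1` when all differences are zero, and a
#'   signed infinite `t` (with a warning) otherwise.
#' @export
paired_t <- function(x, y, tail = c("two", "greater")) {
  tail <- match.arg(tail)
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2) stop("need at least 2 complete pairs")
  d <- x - y
  if (stats::sd(d) <= 1e-12 * max(abs(mean(d)), max(abs(d)), 1e-100)) {
    if (all(d == 0)) {
      return(list(t = 0, df = n - 1, p = 1, mean_diff = 0, tail = tail))
    }
    warning("zero-variance non-zero differences: t is infinite")
    tv <- sign(mean(d)) * Inf
    p <- if (tail == "two") 0 else if (tv > 0) 0 else 1
    return(list(t = tv, df = n - 1, p = p, mean_diff = mean(d), tail = tail))
  }
  alt <- if (tail == "two") "two.sided" else "greater"
  ht <- stats::t.test(x, y, paired = TRUE, alternative = alt)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_diff = unname(ht$estimate), tail = tail)
}

#' Two-way repeated-measures ANOVA
#'
#' Fully within-subjects two-factor ANOVA (e.g. condition x violation bin)
#' via the classical sums-of-squares partition, with each effect tested
#' against its subject-by-effect interaction stratum. Observers missing any
#' cell are dropped listwise with a warning. An optional Greenhouse-Geisser
#' correction adjusts the degrees of freedom of each effect by the
#' sphericity estimate computed from the covariance of the within-subject
#' contrasts.
#'
#' @param data data frame in long format.
#' @param dv,observer,f1,f2 column names of the response, subject
#'   identifier, and the two within-subject factors.
#' @param gg apply the Greenhouse-Geisser correction.
#' @return object of class `rm_anova`: data frame with rows for `f1`,
#'   `f2`, and `f1:f2`; columns `effect`, `F`, `df1`, `df2`, `p` (and
#'   `eps`, `p_gg` when `gg = TRUE`); attribute `n_observers`.
#' @export
rm_anova_2way <- function(data, dv, observer, f1, f2, gg = FALSE) {
  d <- data.frame(y = data[[dv]],
                  s = factor(data[[observer]]),
                  a = factor(data[[f1]]),
                  b = factor(data[[f2]]))
  if (anyNA(d$y)) {
    bad <- unique(d$s[is.na(d$y)])
    warning("listwise deletion of ", length(bad),
            " observer(s) with missing cells")
    d <- d[!d$s %in% bad, , drop = FALSE]
    d$s <- droplevels(d$s)
  }
  tab <- table(d$s, d$a, d$b)
  if (any(tab == 0)) {
    bad <- rownames(tab)[apply(tab == 0, 1, any)]
    warning("listwise deletion of ", length(bad),
            " observer(s) with empty cells")
    d <- d[!d$s %in% bad, , drop = FALSE]
    d$s <- droplevels(d$s)
  }
  if (nlevels(d$s) < 2) stop("fewer than 2 complete observers")
  if (any(table(d$s, d$a, d$b) != 1)) {
    # average replicates within cells so the partition is balanced
    d <- stats::aggregate(y ~ s + a + b, data = d, FUN = mean)
  }
  if (stats::var(d$y) == 0) {
    out <- data.frame(effect = c(f1, f2, paste0(f1, ":", f2)),
                      F = 0, df1 = c(nlevels(d$a) - 1, nlevels(d$b) - 1,
                                     (nlevels(d$a) - 1) * (nlevels(d$b) - 1)),
                      df2 = NA_real_, p = 1)
    if (gg) { out$eps <- 1; out$p_gg <- 1 }
    return(structure(out, class = c("rm_anova", "data.frame"),
                     n_observers = nlevels(d$s)))
  }
  fit <- stats::aov(y ~ a * b + Error(s / (a * b)), data = d)
  sm <- summary(fit)
  pull <- function(stratum, term) {
    tabs <- sm[[stratum]][[1]]
    i <- match(term, trimws(rownames(tabs)))
    c(F = tabs[i, "F value"], df1 = tabs[i, "Df"],
      df2 = tabs[nrow(tabs), "Df"], p = tabs[i, "Pr(>F)"])
  }
  rows <- rbind(pull("Error: s:a", "a"),
                pull("Error: s:b", "b"),
                pull("Error: s:a:b", "a:b"))
  out <- data.frame(effect = c(f1, f2, paste0(f1, ":", f2)),
                    F = rows[, "F"], df1 = rows[, "df1"],
                    df2 = rows[, "df2"], p = rows[, "p"])
  if (gg) {
    out$eps <- c(.gg_epsilon(d, "a"), .gg_epsilon(d, "b"),
                 .gg_epsilon(d, "ab"))
    out$p_gg <- stats::pf(out$F, out$eps * out$df1, out$eps * out$df2,
                          lower.tail = FALSE)
  }
  structure(out, class = c("rm_anova", "data.frame"),
            n_observers = nlevels(d$s))
}

# Greenhouse-Geisser epsilon of an effect, from the covariance of its
# orthonormal within-subject contrast variables: with Sc = C' S C (S the
# cell covariance, C the effect's d orthonormal contrasts),
# eps = tr(Sc)^2 / (d * sum(Sc^2)), bounded in [1/d, 1].
.gg_epsilon <- function(d, which) {
  orthonorm_contr <- function(k) {
    C <- stats::contr.helmert(k)
    sweep(C, 2, sqrt(colSums(C^2)), "/")
  }
  ka <- nlevels(d$a); kb <- nlevels(d$b)
  if (which == "a") {
    m <- tapply(d$y, list(d$s, d$a), mean)
    C <- orthonorm_contr(ka)
  } else if (which == "b") {
    m <- tapply(d$y, list(d$s, d$b), mean)
    C <- orthonorm_contr(kb)
  } else {
    # interaction cells ordered a-fastest (interaction() level order)
    m <- tapply(d$y, list(d$s, interaction(d$a, d$b)), mean)
    C <- kronecker(orthonorm_contr(kb), orthonorm_contr(ka))
  }
  dd <- ncol(C)
  if (dd < 2) return(1)
  Sc <- t(C) %*% stats::cov(m) %*% C
  den <- dd * sum(Sc^2)
  if (den <= 0) return(1)
  min(max(sum(diag(Sc))^2 / den, 1 / dd), 1)
}

#' @export
print.rm_anova <- function(x, ...) {
  cat("Repeated-measures ANOVA (", attr(x, "n_observers"),
      " observers)\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Cluster-mass permutation test for paired time series
#'
#' Familywise-error-controlled test of a condition difference across time.
#' A paired t-statistic is computed at every sample; contiguous runs of
#' pointwise-significant samples of one sign form clusters scored by their
#' summed t (cluster mass). The null distribution of the maximum cluster
#' mass is simulated by randomly swapping condition labels within observers
#' (equivalently, sign-flipping each observer's difference series), with
#' positive and negative masses tracked separately; clusters whose mass
#' does not exceed the 95th percentile of the matching null are discarded
#' as spurious.
#'
#' @param x,y observer x time matrices of the two conditions (paired rows),
#'   or pass a precomputed difference matrix as `x` with `y = NULL`.
#' @param times optional time stamps (ms) for cluster boundary reporting;
#'   defaults to sample indices.
#' @param alpha_pointwise pointwise alpha forming clusters (default 0.05,
#'   same tail as the final test).
#' @param n_perm number of permutations (default 1000); `"all"` enumerates
#'   every sign-flip pattern exhaustively. With `enumerate = "auto"` (the
#'   default) enumeration also happens automatically whenever the number of
#'   distinct sign-flip patterns `2^n` does not exceed `n_perm`, in which
#'   case the null is exact rather than Monte-Carlo.
#' @param tail `"two"` or `"greater"` (one-tailed: positive clusters only).
#' @param seed integer seed for the permutation draws.
#' @param cluster_alpha familywise level of the cluster threshold (default
#'   0.05). One-tailed tests use the `1 - cluster_alpha` percentile of the
#'   positive max-mass null; two-tailed tests use the
#'   `1 - cluster_alpha / 2` percentile on each side, so the two-sided
#'   familywise error stays at the nominal level.
#' @param enumerate `"auto"` (enumerate exactly when `2^n <= n_perm`),
#'   `"never"` (always Monte-Carlo), or `"always"`.
#' @return object of class `cluster_result`: `clusters` (data frame
#'   `start`, `end`, `mass`, `sign`, `significant`), `pointwise_t`,
#'   `times`, `threshold_pos`, `threshold_neg`, `null_pos`, `null_neg`,
#'   `n_perm`, `seed`, `tail`.
#' @export
cluster_permutation_test <- function(x, y = NULL, times = NULL,
                                     alpha_pointwise = 0.05,
                                     n_perm = 1000,
                                     tail = c("two", "greater"),
                                     seed = 1, cluster_alpha = 0.05,
                                     enumerate = c("auto", "never", "always")) {
  tail <- match.arg(tail)
  enumerate <- match.arg(enumerate)
  D <- if (is.null(y)) as.matrix(x) else as.matrix(x) - as.matrix(y)
  n <- nrow(D); nt <- ncol(D)
  if (n < 2) stop("need at least 2 observers")
  if (is.null(times)) times <- seq_len(nt)
  exhaustive <- identical(n_perm, "all") || enumerate == "always" ||
    (enumerate == "auto" && is.numeric(n_perm) && n <= 30 &&
       2^n <= n_perm)
  if (!exhaustive && n_perm < 100) warning("n_perm < 100 is unreliable")

  tcrit <- if (tail == "two") {
    stats::qt(1 - alpha_pointwise / 2, n - 1)
  } else {
    stats::qt(1 - alpha_pointwise, n - 1)
  }
  S2 <- colSums(D^2)

  tvec_of <- function(m) {
    v <- (S2 - n * m^2) / (n - 1)
    v[v < .Machine$double.eps] <- .Machine$double.eps
    m / sqrt(v / n)
  }
  tobs <- tvec_of(colMeans(D))

  # maximum positive / negative cluster masses of a t series
  max_masses <- function(tv) {
    sig <- if (tail == "two") abs(tv) > tcrit else tv > tcrit
    pos_max <- 0; neg_max <- 0
    if (any(sig)) {
      lab <- sig * sign(tv)
      r <- rle(lab)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      for (i in which(r$values != 0)) {
        m <- sum(tv[starts[i]:ends[i]])
        if (m > pos_max) pos_max <- m
        if (m < neg_max) neg_max <- m
      }
    }
    c(pos_max, neg_max)
  }

  # observed clusters
  sig <- if (tail == "two") abs(tobs) > tcrit else tobs > tcrit
  clusters <- data.frame(start = numeric(0), end = numeric(0),
                         mass = numeric(0), sign = integer(0))
  if (any(sig)) {
    lab <- sig * sign(tobs)
    r <- rle(lab)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (i in which(r$values != 0)) {
      clusters <- rbind(clusters, data.frame(
        start = times[starts[i]], end = times[ends[i]],
        mass = sum(tobs[starts[i]:ends[i]]), sign = as.integer(r$values[i])))
    }
  }

  if (exhaustive) {
    flips <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  } else {
    # draw permutations from a private stream, leaving the caller's
    # RNG state untouched
    if (exists(".Random.seed", envir = globalenv())) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()),
              add = TRUE)
    }
    set.seed(as.integer(seed))
    flips <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                    nrow = n_perm, ncol = n)
  }
  M <- (flips %*% D) / n
  null_pos <- numeric(nrow(flips))
  null_neg <- numeric(nrow(flips))
  for (b in seq_len(nrow(flips))) {
    mm <- max_masses(tvec_of(M[b, ]))
    null_pos[b] <- mm[1]
    null_neg[b] <- mm[2]
  }
  side_alpha <- if (tail == "two") cluster_alpha / 2 else cluster_alpha
  threshold_pos <- stats::quantile(null_pos, 1 - side_alpha, names = FALSE)
  threshold_neg <- stats::quantile(-null_neg, 1 - side_alpha, names = FALSE)

  if (nrow(clusters)) {
    clusters$significant <- ifelse(clusters$sign > 0,
                                   clusters$mass > threshold_pos,
                                   -clusters$mass > threshold_neg)
  } else {
    clusters$significant <- logical(0)
  }

  structure(list(clusters = clusters, pointwise_t = tobs, times = times,
                 threshold_pos = threshold_pos,
                 threshold_neg = threshold_neg,
                 null_pos = null_pos, null_neg = null_neg,
                 n_perm = if (exhaustive) nrow(flips) else n_perm,
                 exhaustive = exhaustive,
                 seed = as.integer(seed), tail = tail,
                 alpha_pointwise = alpha_pointwise,
                 cluster_alpha = cluster_alpha),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("Cluster-mass permutation test (%s-tailed, %d permutations%s)\n",
              x$tail, x$n_perm, if (x$exhaustive) ", exhaustive" else ""))
  if (x$tail == "greater") {
    cat(sprintf("  null threshold: +%.2f\n", x$threshold_pos))
  } else {
    cat(sprintf("  null thresholds: +%.2f / -%.2f\n",
                x$threshold_pos, x$threshold_neg))
  }
  if (nrow(x$clusters) == 0) {
    cat("  no pointwise-significant clusters\n")
  } else {
    print.data.frame(x$clusters, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

# Ideal-fourths (interpolated) quartiles, the estimator behind the boxplot
# rule used for outlier fences.
ideal_fourths <- function(x) {
  x <- sort(x)
  n <- length(x)
  j <- floor(n / 4 + 5 / 12)
  h <- n / 4 + 5 / 12 - j
  q1 <- (1 - h) * x[j] + h * x[j + 1]
  k <- n - j + 1
  q3 <- (1 - h) * x[k] + h * x[k - 1]
  c(q1, q3)
}

#' Skipped Pearson correlation
#'
#' Robust correlation that removes bivariate outliers before computing a
#' Pearson correlation. Outliers are found by the projection method: the
#' cloud is centered on a robust center (coordinatewise median by default,
#' or the minimum-covariance-determinant center), every point is projected
#' onto the line through the center and each data point in turn, and a
#' point is flagged if it falls outside the boxplot fences
#' (ideal-fourths quartiles +/- 1.5 IQR) on any projection. The correlation
#' and its t-based p-value are then computed on the retained points.
#'
#' @param x,y paired numeric vectors, `n >= 10`.
#' @param center `"median"` (default, deterministic) or `"mcd"`.
#' @return object of class `skipped_cor`: `r`, `p_value`, `n_used`,
#'   `outlier_ids` (indices into the input), `center`, `n`.
#' @export
skipped_pearson <- function(x, y, center = c("median", "mcd")) {
  center <- match.arg(center)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 10) stop("need at least 10 complete pairs")
  X <- cbind(x, y)
  ctr <- if (center == "median") {
    apply(X, 2, stats::median)
  } else {
    MASS::cov.mcd(X)$center
  }
  Xc <- sweep(X, 2, ctr)
  flagged <- rep(FALSE, n)
  for (j in seq_len(n)) {
    v <- Xc[j, ]
    nv <- sqrt(sum(v^2))
    if (nv < .Machine$double.eps) next
    proj <- Xc %*% (v / nv)
    q <- ideal_fourths(proj)
    iqr <- q[2] - q[1]
    flagged <- flagged | proj < q[1] - 1.5 * iqr | proj > q[2] + 1.5 * iqr
  }
  if (mean(flagged) > 0.5) {
    stop("more than half the points flagged as outliers (",
         sum(flagged), "/", n, "); data unsuitable for a skipped correlation")
  }
  keep <- !flagged
  r <- stats::cor(x[keep], y[keep])
  m <- sum(keep)
  tstat <- r * sqrt((m - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), m - 2, lower.tail = FALSE)
  structure(list(r = r, p_value = p, n = n, n_used = m,
                 outlier_ids = which(ok)[flagged], center = center),
            class = "skipped_cor")
}

#' @export
print.skipped_cor <- function(x, ...) {
  cat(sprintf("Skipped Pearson correlation (%s center): r = %.3f, p = %.3g\n",
              x$center, x$r, x$p_value))
  cat(sprintf("  %d of %d points retained (%d outliers removed)\n",
              x$n_used, x$n, x$n - x$n_used))
  invisible(x)
}
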