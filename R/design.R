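#' Build a single trial specification
#'
#' One trial of the dual-report task: an initial sequence of 5-12 gratings
#' followed by a penultimate and a target grating. In the sequential
#' condition the initial orientations rotate consistently by +-30 degrees
#' per grating from a random start and the penultimate continues the
#' rotation, so the expected target orientation is the penultimate rotated
#' one further step. In the random condition every initial orientation is
#' drawn independently and the "expected" orientation is defined as the
#' penultimate grating (the reference used when binning random-condition
#' trials by angular offset). The target orientation is drawn at random in
#' both conditions, so the signed expectation violation
#' `axial_wrap(target - expected)` is uniform on `(-90, 90]`.
#'
#' @param condition `"sequential"` or `"random"`.
#' @param n_initial number of gratings in the initial sequence, 5-12.
#' @param rotation_dir `+1` (clockwise) or `-1`; ignored for random trials.
#' @param start optional start orientation in degrees; drawn uniform on
#'   `[0, 180)` when `NULL`.
#' @param target optional target orientation; drawn uniform when `NULL`.
#' @param penultimate optional penultimate orientation for random trials
#'   (sequential trials derive it from the rotation).
#' @param integer_target draw target orientations on the integer degrees
#'   1..180 instead of the continuous uniform.
#' @return a one-row data frame with columns `condition`, `n_initial`,
#'   `rotation_dir`, `initial_orientations` (semicolon-joined degrees),
#'   `penultimate`, `target`, `expected`, `violation`.
#' @export
generate_trial <- function(condition = c("sequential", "random"),
                           n_initial,
                           rotation_dir = NULL,
                           start = NULL, target = NULL, penultimate = NULL,
                           integer_target = FALSE) {
  condition <- match.arg(condition)
  if (!is.numeric(n_initial) || length(n_initial) != 1 ||
      n_initial < 5 || n_initial > 12 || n_initial != round(n_initial)) {
    stop("n_initial must be an integer in [5, 12]")
  }
  if (is.null(target)) {
    target <- if (integer_target) sample.int(180, 1) else runif(1, 0, 180)
    target <- wrap_orientation(target)
  }
  if (condition == "sequential") {
    if (is.null(rotation_dir) || !rotation_dir %in% c(-1, 1)) {
      stop("sequential trials need rotation_dir in {+1, -1}")
    }
    if (is.null(start)) start <- runif(1, 0, 180)
    init <- wrap_orientation(start + rotation_dir * 30 * (seq_len(n_initial) - 1))
    penultimate <- wrap_orientation(init[n_initial] + rotation_dir * 30)
    expected <- wrap_orientation(penultimate + rotation_dir * 30)
  } else {
    rotation_dir <- 0
    init <- runif(n_initial, 0, 180)
    if (is.null(penultimate)) penultimate <- runif(1, 0, 180)
    expected <- wrap_orientation(penultimate)
  }
  data.frame(
    condition = condition,
    n_initial = as.integer(n_initial),
    rotation_dir = rotation_dir,
    initial_orientations = paste(formatC(init, digits = 6, format = "f"),
                                 collapse = ";"),
    penultimate = penultimate,
    target = wrap_orientation(target),
    expected = expected,
    violation = axial_wrap(wrap_orientation(target) - expected),
    stringsAsFactors = FALSE
  )
}

#' Generate a full session of trials (central-presentation experiment)
#'
#' Constructs `n_blocks * trials_per_block` trials, half sequential and half
#' random, interleaved pseudorandomly with equal condition counts in every
#' block. Initial-sequence length (5-12) and rotation direction are
#' counterbalanced across the session within the sequential condition, and
#' independently within the random condition. Every sequential trial has a
#' matched random trial with the same penultimate and target orientations,
#' so the two conditions are stimulus-matched at the decisive gratings.
#'
#' @param n_blocks number of blocks (default 16).
#' @param trials_per_block trials per block (default 24; must be even).
#' @param seed integer seed; the session is a deterministic function of it.
#' @param integer_target see [generate_trial()].
#' @return a `session_design`: a data frame with one row per trial (columns
#'   `trial_id`, `block`, plus the [generate_trial()] fields) and attributes
#'   `timing` (grating 250 ms, ISI 32 ms, speeded window 2000 ms), `seed`,
#'   and `experiment = "exp1"`.
#' @examples
#' d <- generate_session_exp1(seed = 1)
#' nrow(d)            # 384
#' table(d$condition) # 192 / 192
#' @export
generate_session_exp1 <- function(n_blocks = 16, trials_per_block = 24,
                                  seed = 1, integer_target = FALSE) {
  .check_session_args(n_blocks, trials_per_block)
  set.seed(as.integer(seed))
  n_per_cond <- n_blocks * trials_per_block / 2

  seq_tab <- .sequential_trials(n_per_cond, integer_target)
  rnd_tab <- .matched_random_trials(seq_tab)
  trials <- .interleave_blocks(seq_tab, rnd_tab, n_blocks, trials_per_block)

  structure(trials,
            class = c("session_design", "data.frame"),
            timing = list(grating_ms = 250, isi_ms = 32,
                          speeded_window_ms = 2000),
            seed = as.integer(seed), experiment = "exp1")
}

#' Generate a session for the moving-stimulus, spatially cued experiment
#'
#' Same orientation structure as [generate_session_exp1()], but the gratings
#' traverse an imaginary circle (radius 6 degrees of visual angle, 12.85
#' degrees of polar angle per grating, direction counterbalanced across
#' trials). A cue axis (above / below / left / right of fixation, mapped to
#' polar angles 90 / 270 / 180 / 0; 0 = right, counterclockwise positive)
#' is fixed within a block and randomized between blocks. On half of the
#' trials in each block the target grating lands exactly on the cue axis
#' (`cue_valid = TRUE`); on the other half the target is presented 1-4
#' steps before the sequence reaches the axis (`cue_valid = FALSE`).
#'
#' @param n_blocks number of blocks, 48-60.
#' @param trials_per_block trials per block (must be even; default 24).
#' @param seed integer seed.
#' @param integer_target see [generate_trial()].
#' @return a `session_design` with the extra columns `positions`
#'   (semicolon-joined polar angles in degrees, one per grating),
#'   `direction`, `cue_axis`, `cue_valid`, and attribute
#'   `experiment = "exp2"`.
#' @export
generate_session_exp2 <- function(n_blocks = 48, trials_per_block = 24,
                                  seed = 1, integer_target = FALSE) {
  if (n_blocks < 48 || n_blocks > 60) {
    stop("n_blocks must lie in [48, 60]")
  }
  .check_session_args(n_blocks, trials_per_block)
  if (trials_per_block %% 4 != 0) {
    stop("trials_per_block must be divisible by 4 to counterbalance ",
         "condition x cue validity within blocks")
  }
  set.seed(as.integer(seed))
  n_per_cond <- n_blocks * trials_per_block / 2

  seq_tab <- .sequential_trials(n_per_cond, integer_target)
  rnd_tab <- .matched_random_trials(seq_tab)
  trials <- .interleave_blocks(seq_tab, rnd_tab, n_blocks, trials_per_block,
                               balance_validity = TRUE)

  axes <- c(up = 90, down = 270, left = 180, right = 0)
  block_axis <- sample(names(axes), n_blocks, replace = TRUE)
  n <- nrow(trials)
  trials$direction <- sample(rep(c(-1, 1), length.out = n))
  trials$cue_axis <- block_axis[trials$block]
  step <- 12.85
  positions <- character(n)
  for (i in seq_len(n)) {
    n_gratings <- trials$n_initial[i] + 2L
    axis_deg <- axes[[trials$cue_axis[i]]]
    lag <- if (trials$cue_valid[i]) 0L else sample(1:4, 1)
    dir <- trials$direction[i]
    final <- axis_deg - dir * step * lag
    pos <- (final - dir * step * ((n_gratings - 1):0)) %% 360
    positions[i] <- paste(formatC(pos, digits = 4, format = "f"),
                          collapse = ";")
  }
  trials$positions <- positions

  structure(trials,
            class = c("session_design", "data.frame"),
            timing = list(grating_ms = 250, isi_ms = 32,
                          speeded_window_ms = 2000),
            seed = as.integer(seed), experiment = "exp2")
}

#' @export
print.session_design <- function(x, ...) {
  cat(sprintf("Session design (%s): %d trials, %d blocks, seed %d\n",
              attr(x, "experiment"), nrow(x), max(x$block),
              attr(x, "seed")))
  cat(sprintf("  conditions: %s\n",
              paste(sprintf("%s=%d", names(table(x$condition)),
                            table(x$condition)), collapse = ", ")))
  invisible(x)
}

#' Split a semicolon-joined orientation list back into numbers
#'
#' @param x character vector as stored in the `initial_orientations` or
#'   `positions` columns of a `session_design`.
#' @return list of numeric vectors.
#' @export
parse_angle_list <- function(x) {
  lapply(strsplit(x, ";", fixed = TRUE), as.numeric)
}

.check_session_args <- function(n_blocks, trials_per_block) {
  if (trials_per_block %% 2 != 0) {
    stop("trials_per_block must be even (equal condition counts per block)")
  }
  n_per_cond <- n_blocks * trials_per_block / 2
  # 8 sequence lengths x 2 rotation directions must tile the condition count
  if (n_per_cond %% 16 != 0) {
    stop("cannot counterbalance sequence length (5-12) and rotation ",
         "direction: trials per condition (", n_per_cond,
         ") is not a multiple of 16")
  }
  invisible(TRUE)
}

.sequential_trials <- function(n, integer_target) {
  lengths <- rep(5:12, each = n / 8)
  dirs <- rep(c(-1, 1), length.out = n)  # 50/50 within each length
  out <- vector("list", n)
  for (i in seq_len(n)) {
    out[[i]] <- generate_trial("sequential", lengths[i], dirs[i],
                               integer_target = integer_target)
  }
  do.call(rbind, out)
}

# For each sequential trial, a random trial sharing penultimate and target.
.matched_random_trials <- function(seq_tab) {
  n <- nrow(seq_tab)
  lengths <- sample(rep(5:12, each = n / 8))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    out[[i]] <- generate_trial("random", lengths[i],
                               target = seq_tab$target[i],
                               penultimate = seq_tab$penultimate[i])
  }
  do.call(rbind, out)
}

# Pseudorandom interleave: equal condition counts within every block (and,
# for the cued experiment, equal counts of each condition x validity cell).
.interleave_blocks <- function(seq_tab, rnd_tab, n_blocks, trials_per_block,
                               balance_validity = FALSE) {
  half <- trials_per_block / 2
  seq_tab <- seq_tab[sample(nrow(seq_tab)), ]
  rnd_tab <- rnd_tab[sample(nrow(rnd_tab)), ]
  seq_tab$block <- rep(seq_len(n_blocks), each = half)
  rnd_tab$block <- rep(seq_len(n_blocks), each = half)
  if (balance_validity) {
    seq_tab$cue_valid <- as.logical(rep(c(TRUE, FALSE), length.out = nrow(seq_tab)))
    rnd_tab$cue_valid <- as.logical(rep(c(TRUE, FALSE), length.out = nrow(rnd_tab)))
  }
  trials <- rbind(seq_tab, rnd_tab)
  ord <- order(trials$block, sample(nrow(trials)))
  trials <- trials[ord, ]
  trials$trial_id <- seq_len(nrow(trials))
  rownames(trials) <- NULL
  trials[, c("trial_id", "block",
             setdiff(names(trials), c("trial_id", "block")))]
}
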