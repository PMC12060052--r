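---
title: "Models and methods behind expectviol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind expectviol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical machinery of the package: the
conventions and models it commits to, the defaults and why they were
chosen, the numerical edge cases, and what the simulation-based tests do
and do not establish about real data.

## Orientation conventions

Gratings are axial stimuli: θ and θ + 180° are the same percept. The
package stores orientations in degrees on [0, 180), with 0° vertical and
positive angles clockwise, so that the sign of the wrapped orientation is
exactly the clockwise/counterclockwise category of the speeded task.
Differences (reproduction errors, expectation violations) are wrapped to
(−90°, 90°] by `axial_wrap()`, with the boundary mapped to +90°.

All axial statistics double the angles onto the full circle, work there,
and halve the result back. "Precision" is the angular standard deviation
`0.5 * sqrt(-2 * log(R))` (converted to degrees) of the doubled errors,
where R is the mean resultant length — the circular-SD convention of the
common circular-statistics toolboxes. The alternative angular deviation
`0.5 * sqrt(2 * (1 - R))` is available via `angular_sd(variant =
"angular_deviation")` because toolboxes return both and published analyses
do not always say which one they used; for the dispersions in this task
(5–15°) the two differ by far less than the between-observer variability.
Lower values mean more precise reproduction; no layer of the package
inverts the scale.

Degenerate cases: a one-point sample has SD 0; a resultant length
numerically indistinguishable from zero (e.g. errors at exactly 0°, 45°,
90°, 135°) yields `Inf` with a warning in the circular-SD convention, and
the axial mean of an antipodal pair is refused as undefined.

## Trial-sequence construction

The central-presentation session is 16 blocks × 24 trials, half
sequential, half random, interleaved at random subject to equal condition
counts within every block (the pseudorandomization constraint is not
otherwise specified, so block balance was chosen as the weakest useful
one). Sequential sequences are ±30° staircases from a uniform random
start; the penultimate grating continues the rotation and the expected
orientation is one further step. Initial-sequence length (5–12 gratings)
and rotation direction are counterbalanced across the session (length
counterbalancing within blocks would be impossible: 8 lengths × 2
directions do not tile a 12-trial half-block). Each sequential trial has a
matched random trial with identical penultimate and target orientations,
so any penultimate/target stimulus confound is identical across
conditions.

The random condition has no defined expectation; following the way such
trials are binned in published analyses, its "expected" orientation is
defined as the penultimate grating, which makes the violation axis
comparable across conditions (for the random condition it is simply the
penultimate-to-target offset).

Target orientations are continuous-uniform by default; integer-degree
sampling (1°–180°) is available via `integer_target = TRUE` for exact
emulation of stimulus tables quantized to whole degrees. Because target
and expected orientation are independent, the signed violation is uniform
on (−90°, 90°] in both conditions — a property the test suite checks with
a chi-square goodness-of-fit test.

For the moving-stimulus variant, stimuli advance 12.85° of polar angle per
grating around a radius-6° circle, direction counterbalanced. The polar
convention is 0° = right, counterclockwise positive (none is imposed by
the task itself); the cue axes above/below/left/right map to 90°, 270°,
180°, 0°. The cue axis is fixed within a block and random between blocks;
on valid trials the target lands exactly on the axis, on invalid trials it
appears 1–4 steps earlier.

## The generative observer

The simulator exists so that every analysis stage has input with known
ground truth. Its effect structure mirrors what this class of experiment
reports; its specific functional forms are modeling choices, not
measurements:

* **Response time.** Deterministic part: a baseline, minus a motor-priming
  slope per extra initial grating (longer foreperiods speed responses),
  minus a condition-level sequential gain, plus a suppressive bump
  `rt_pred_amp * G(Δ; rt_pred_width)` on sequential trials (G a
  unit-height Gaussian), minus a temporal-integration speed-up when the
  penultimate and target orientations are similar (both conditions).
  Multiplicand-free lognormal noise (scale `rt_sigma`) is added, and
  responses beyond the 2-second window are recorded as missed and dropped
  before the accuracy denominator (the treatment of misses is not
  otherwise constrained; the choice is logged here and in the code).
  The combination of the condition-level gain (default 30 ms) and the
  suppressive bump (default 50 ms, width 30°) produces the characteristic
  crossover: sequential slower than random when the expectation is
  satisfied, faster when it is strongly violated, faster on aggregate.
  The true generative shape of human RT tuning is unknown; Gaussian
  tuning is a convenience.
* **Speeded choice.** Sign of the target orientation plus Gaussian sensory
  noise (`choice_sd`, default 3°), flipped with a lapse probability
  (default 0.02). These defaults give cohort accuracies in the low-to-mid
  90s, comfortably above the .75 exclusion threshold for typical
  observers.
* **Reproduction.** Target plus a repulsive bias
  `bias_amp * DoG(Δ; bias_width)` (unit-peak derivative-of-Gaussian, so
  the error sign matches the violation sign — repulsion away from the
  expected orientation), plus wrapped-normal noise. Wrapped normal was
  chosen over von Mises because its SD parameter is directly the angular
  SD the analysis measures (the two are practically identical at these
  concentrations). The SD carries the precision tuning: a condition-level
  sequential improvement plus a suppressive worsening near Δ = 0, minus an
  integration improvement for similar penultimate/target pairs.
* **Pupil.** Diameter = baseline + Gaussian random-walk drift + one
  gamma-shaped dilation kernel per grating onset + a target-locked kernel
  whose amplitude grows with |Δ| on sequential trials
  (`pupil_surprise_gain`, a.u./deg). The kernel `(t/L)^s exp(s (1 − t/L))`
  has unit peak exactly at the latency parameter L (default 800 ms, inside
  the empirically typical dilation window); `s = (L/width)^2` sets its
  spread. Only the latency window of the real effect is constrained by
  data; the kernel shape is a standard pupillometric impulse-response
  idealization. Blinks arrive as a Poisson process (default 0.1 Hz,
  100 ms) and mark samples missing.

Scales, widths, and rates are validated non-negative; effect amplitudes
and gains may take either sign so that null populations (all amplitudes
zero — used for the calibration tests) and reversed-effect populations
remain expressible, and so that between-observer normal draws around
small means are not silently truncated into half-normals.

`simulate_cohort()` draws observer parameters from a normal population
(SDs chosen per parameter; non-amplitude parameters are clamped to their
domains). A single correlation knob (`trait_cor`, default 0.4) ties
parameters within two latent groups — general performance (baseline RT and
reproduction noise) and surprise sensitivity (sequential gains,
suppressive amplitudes, pupil surprise gain) — because with fully
independent draws every between-observer correlation the pipeline
estimates would be structurally zero, which real cohorts are not.

Cohort pupil traces are generated on a peri-target window (default 700 ms
before to 1600 ms after target onset) rather than the full trial: dilation
kernels of gratings before that window contribute only a locally
near-linear trend at epoch time, which the baseline regression removes by
construction. The single-trial `simulate_pupil()` still produces the
complete 1 kHz trial trace for users who need it.

What the simulator deliberately does not model: biophysically detailed
pupil dynamics, eye position and gaze-contingent artifacts, inter-trial
sequential dependencies, learning or fatigue across blocks, and swap/guess
mixtures in reproduction. Passing the recovery tests therefore shows that
the pipeline correctly extracts the effect structure it was built for, not
that it is robust to every artifact of real recordings.

## Behavioral pipeline decisions

* Observers below .75 proportion correct (strict inequality) across all
  scored trials are excluded; missed speeded responses are dropped before
  the denominator.
* Precision, bias, and (by default) RT summaries use correct-choice trials
  only; the retained fraction is logged. Analyses on all trials are
  available by simply skipping `correct_trials_only()`.
* Violation tuning uses 8 equal-width signed bins on (−90°, 90°], edges
  half-open (lo, hi]. An unsigned-magnitude variant (8 × 11.25° on
  [0, 90], first bin closed at 0) is available; equal widths were kept
  there because a 0-centered first bin cannot coexist with 8 equal bins on
  [0, 90].
* The median split by sequence length assigns ties to the short half.
* Empty observer × condition × bin cells surface as missing values and are
  handled by listwise deletion in the ANOVA layer (no imputation).

## Inference engines

* **Paired t** is the classical test (df = n − 1), two-tailed by default;
  the directional pupil hypothesis (dilation increases with surprise) uses
  `tail = "greater"`. Zero-variance differences return t = 0, p = 1 when
  all differences are zero, and a flagged infinite t otherwise.
* **Two-way repeated-measures ANOVA** uses the classical within-subject
  sums-of-squares partition, each effect tested against its
  subject × effect stratum; replicates within cells are averaged first so
  the partition is balanced. The Greenhouse–Geisser option computes
  epsilon from the covariance of the effect's orthonormal contrast
  variables (interaction contrasts via the Kronecker product of the
  factors' contrasts) and rescales both degrees of freedom.
* **Cluster-mass permutation test.** Pointwise paired t statistics;
  contiguous runs of pointwise-significant samples (alpha 0.05, same tail
  as the final test) of one sign form clusters scored by summed t; the
  null of the maximum cluster mass is built by sign-flipping each
  observer's difference series independently (the paired-design equivalent
  of swapping condition labels within observers), positive and negative
  masses tracked separately. One-tailed tests threshold positive clusters
  at the 95th percentile of the positive max-mass null. Two-tailed tests
  use the 97.5th percentile per side: per-side 95th percentiles would let
  the two-sided familywise error drift toward 10%, and the package's
  calibration tests (500 null cohorts) hold the empirical rate at
  0.05 ± 0.02 under this convention. When the number of distinct sign
  patterns 2^n does not exceed `n_perm`, the null is enumerated completely
  and is exact (Monte-Carlo sampling can be forced with
  `enumerate = "never"`). Cluster boundaries are reported as the first and
  last pointwise-significant sample. All permutation draws come from a
  private RNG stream seeded by the `seed` argument, so results are
  byte-reproducible and the caller's RNG state is untouched.
* **Skipped Pearson correlation.** Bivariate outliers by the projection
  method: center the cloud on the coordinatewise median (deterministic
  default; the minimum-covariance-determinant center is available), project
  all points onto the direction of each data point in turn, and flag any
  point beyond the ideal-fourths boxplot fences (quartiles ± 1.5 IQR) on
  any projection; then Pearson r with its t-based p on the retained
  points. If more than half the points are flagged the estimate is
  refused. With no outliers the estimate reduces exactly to Pearson.

## Pupillometry preprocessing

Order of operations: divisive normalization to the observer's session
mean (dimensionless traces, mean ≈ 1; a subtractive variant exists for
sensitivity analyses) → epoch to −500..1500 ms around target onset (2001
samples at 1 kHz, both endpoints kept) → ordinary least-squares line fit
to the 500 pre-onset samples, using measured samples only, extrapolated
across the epoch and subtracted → linear interpolation of blink gaps
(edge gaps held at the nearest value). Interpolation is deliberately last
so that the baseline fit never uses fabricated samples. Baselining is
exactly idempotent and annihilates any linear input; a post-onset boxcar
rides through it unchanged — both facts are tested as closed forms.
Epochs with fewer than two measured baseline samples, or no measured
samples at all, are flagged invalid rather than silently filled. No
padding is applied around tracker-flagged gaps (none is specified for
this class of data; a padding step would sit naturally before
interpolation). Observers whose session-mean diameter lies strictly more
than 3 group SDs from the group mean are excluded in a single pass.

The condition-difference time course (sequential − random, optionally
restricted to |Δ| above or below 30°) feeds the one-tailed cluster test;
the average difference over the significant window is the per-observer
pupil effect correlated with the behavioral effects.

## Problem sizes used by the tests

The test suite's Monte-Carlo checks use sizes chosen to give stable
verdicts at desk scale: 500 null cohorts (20 observers × 200 samples) for
cluster-test calibration; 10,000 replicates for paired-t calibration;
100 simulated 52-observer cohorts for behavioral effect recovery and 20
such cohorts for pupil-cluster recovery (the pupil stage dominates the
computational cost; at the default signal-to-noise the detection rate is
effectively at ceiling, so 20 replicates bound it well above the 95%
requirement); n = 50,000 for the small-dispersion equivalence of angular
and linear SD; and n = 500 with 5% planted 10-SD leverage points for the
skipped correlation. All seeds are fixed in the tests.

## Known limitations

* The suppressive Gaussian tuning, DoG bias, and gamma dilation kernel
  are idealizations; parameter recovery results transfer to real data
  only insofar as real effects resemble these shapes.
* The RM-ANOVA assumes complete cells after listwise deletion and offers
  only the Greenhouse–Geisser sphericity correction.
* The skipped-correlation p-value is the plain t-based p on the retained
  points; it does not adjust for the outlier-removal step.
* `load_osf_deposit()` maps external long-format tables into the package
  schema via an explicit column mapping but cannot validate semantics the
  deposit does not declare (e.g. units).
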