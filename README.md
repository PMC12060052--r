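# expectviol

Behavioral and pupillometric analysis of expectation-violation
psychophysics experiments, together with a generative simulator that makes
every stage of the analysis testable without human data.

## The problem

In a dual-report orientation task, observers watch a rapid sequence of
gratings (each 250 ms, separated by 32 ms blanks). The sequence either
rotates consistently by ±30° per grating (*sequential* condition, which
establishes an expectation about the next orientation) or is random. The
final *target* grating has a random orientation, so in sequential
sequences it violates the established expectation by a signed angle
Δ = wrap(θ_target − θ_expected) ∈ (−90°, 90°]. Observers first make a
speeded clockwise/counterclockwise judgment about the target (response
time), then reproduce its orientation by rotating a bar (precision), while
pupil diameter is recorded at 1 kHz as a physiological index of surprise.

The scientific questions the analysis answers: are unexpected targets
responded to faster and reproduced more precisely than expected or
unpredictable ones; how do speed and precision vary with |Δ| (the *tuning*
of the expectation); is there a repulsive reproduction bias away from the
expected orientation; and does the pupil dilate more after strongly
violating targets, in a time window identified without
multiple-comparison inflation?

## What the package provides

* **Design** — `generate_session_exp1()` / `generate_session_exp2()`
  build counterbalanced trial sequences (384 trials = 16 blocks × 24; the
  spatially cued variant adds a moving stimulus on a radius-6° circle,
  12.85° polar steps, and a cue axis valid on half the trials). Every
  sequential trial has a matched random trial with identical penultimate
  and target orientations.
* **Simulation** — `observer_params()`, `simulate_behavior()`,
  `simulate_pupil()`, `simulate_cohort()`: a generative observer with
  suppressive response-time/precision tuning centered on Δ = 0, temporal
  integration, motor priming, a derivative-of-Gaussian repulsive bias, and
  1 kHz pupil traces with random-walk drift, per-grating dilation kernels,
  blinks, and a surprise component scaling with |Δ|.
* **Circular statistics** — `axial_wrap()`, `axial_mean()`,
  `angular_sd()`: axial (180°-periodic) statistics computed by doubling
  angles onto the full circle; precision is the angular standard deviation
  ½·√(−2 ln R) (in degrees) of the doubled reproduction errors.
* **Behavior** — accuracy-based observer exclusion (< .75 correct),
  correct-trial filtering, per-condition summaries, 8-bin violation tuning
  curves, signed bias curves, and a median split by sequence length.
* **Pupillometry** — divisive normalization to the observer's mean,
  −500..1500 ms epochs with a linear baseline regressed out of each epoch
  (fit on the 500 pre-onset samples), linear blink interpolation, > 3 SD
  observer exclusion, condition-difference time courses, and window
  averages.
* **Inference** — `paired_t()`, `rm_anova_2way()` (with a
  Greenhouse–Geisser option), `cluster_permutation_test()` (cluster-mass
  statistics with a within-observer sign-flip null; exact enumeration when
  2^n ≤ n_perm), and `skipped_pearson()` (projection-based bivariate
  outlier rejection with ideal-fourths boxplot fences, then Pearson).
* **Pipeline** — `run_config()` + `run_pipeline()` execute
  simulate → exclude → summarize → tuning ANOVAs → pupil cluster test →
  brain-behavior correlations and emit a machine-readable manifest.
  `inst/scripts/run_pipeline.R` is a shell wrapper.

## Worked example

```r
library(expectviol)

d <- generate_session_exp1(seed = 1)
d
#> Session design (exp1): 384 trials, 16 blocks, seed 1
#>   conditions: random=192, sequential=192

cfg <- run_config("exp1", n_observers = 20, seed = 7, n_perm = 1000)
res <- run_pipeline(cfg)
res
#> Pipeline result (exp1, seed 7): 20/20 observers included
#>   RT: t(19) = 4.06, p = 0.000665; precision: t(19) = 2.29, p = 0.0339
#>   pupil cluster: 59-1500 ms (mass 27226.5)
```

The positive t statistics say that, on aggregate, responses in sequential
sequences were faster (random − sequential mean RT difference > 0) and
reproductions more precise (random − sequential angular SD difference
> 0) — the signature of prioritized processing of expectation-violating
stimuli, since most sequential targets violate the expectation. The
cluster line reports the time window (relative to target onset) in which
pupil diameter was significantly larger after large (> 30°) violations in
sequential than in random sequences, controlled for familywise error by
the max-cluster-mass permutation null. `res$tuning` holds the per-observer
8-bin tuning curves behind the ANOVAs (`res$manifest` has the F tests:
condition and condition × violation-magnitude interaction for both
measures), and `res$manifest$corr_*` hold the skipped Pearson correlations
between the speed and precision effects and the pupil response.

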