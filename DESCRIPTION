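Package: expectviol
Title: Behavioral and Pupillometric Analysis of Expectation-Violation
    Psychophysics Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dual-report orientation-judgment experiments in which
    a target grating either violates an expectation established by a rotating
    stimulus sequence or follows a random sequence. Provides trial-sequence
    construction with matched penultimate/target pairs, a generative observer
    model (response times, orientation reproductions, and 1 kHz pupil traces
    with blinks and a surprise-locked dilation), axial circular statistics
    (wrapped differences, axial mean, angular standard deviation),
    behavioral summaries and violation-magnitude tuning curves, pupillometry
    preprocessing (divisive normalization, epoching, linear-baseline
    regression, blink interpolation, outlier exclusion), and inference
    engines: paired t-tests, two-way repeated-measures ANOVA, a cluster-mass
    permutation test for time series, and the skipped Pearson correlation
    with projection-based bivariate outlier rejection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
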