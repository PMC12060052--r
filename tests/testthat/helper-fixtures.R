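# Small shared fixtures, built in code at test time.

# A compact session: 2 blocks x 16 trials = 32 trials (16 per condition),
# the smallest geometry that still counterbalances 8 sequence lengths x 2
# rotation directions.
small_session <- function(seed = 1) {
  generate_session_exp1(n_blocks = 2, trials_per_block = 16, seed = seed)
}

# Behavior-only cohort on the small session.
small_cohort <- function(n_observers = 6, seed = 1, pupil = FALSE, ...) {
  simulate_cohort(n_observers, small_session(seed), seed = seed,
                  pupil = pupil, ...)
}

# Null observer: every effect amplitude zero, conditions exchangeable.
null_params <- function(...) {
  observer_params(rt_seq_gain = 0, rt_pred_amp = 0, rt_integration_amp = 0,
                  rt_len_slope = 0, repro_sd_seq_gain = 0,
                  repro_sd_pred_amp = 0, repro_sd_integration_amp = 0,
                  bias_amp = 0, pupil_surprise_gain = 0, ...)
}
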