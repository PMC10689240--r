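# Small in-code fixtures shared across the test files.

# An fz_trace directly from a numeric vector (already in Fz units).
make_fz <- function(values, fs = 25) {
  structure(list(time = (seq_along(values) - 1L) / fs,
                 fz = as.numeric(values), fs = fs),
            class = "fz_trace")
}

make_bouts <- function(onset, offset, behavior = "investigation",
                       stimulus = "male", session = "s1") {
  bout_table(data.frame(session = session, stimulus = stimulus,
                        behavior = behavior, onset_s = onset,
                        offset_s = offset))
}

# Zero-amplitude (null) freely-moving session of modest size; bouts sit away
# from the trace edges so the baseline estimator works in its interior regime.
null_session <- function(seed, noise_sd = 0.3) {
  sim_config(seed = seed, paradigm = "freely_moving", stimuli = "male",
             amplitude = c(male = 0), response_prob = c(male = 0.5),
             stimulus_duration = 240, intro_time = 30, tail = 20,
             mean_gap = 10, mean_bout = 3, attack_prob = 0,
             noise_sd = noise_sd)
}

# Median-quantile baseline settings, the unbiased configuration for
# transient-free traces.
median_baseline <- function() baseline_config(quantile = 0.5)
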