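# Small designs keep filtering and GLM costs low in unit tests; the
# full-size study design is exercised in the acceptance tests.
tiny_design <- function(trials = 6, blocks = 1, lead_in = 60,
                        lead_out = 60) {
  design_spec(n_blocks = blocks, trials_per_condition_per_block = trials,
              lead_in = lead_in, lead_out = lead_out)
}

# Noise-free amplitude vectors: CS+ trials get `csp`, CS− get `csm`.
flat_amps <- function(events, csp, csm) {
  ifelse(events$condition == "CS+", csp, csm)
}

# A noiseless cohort_spec with everything stochastic switched off.
noiseless_cohort <- function(n = 2, delta = 0.6, seed = 1L) {
  zero <- list(spectrum = "white", sd = 0)
  cohort_spec(
    n_participants = n, delta = delta, between_sd = 0, trial_sd = 0,
    channels = list(
      heart = list(base = 10, scale = 15, us_amp = 8, noise = zero,
                   rate = 100),
      scr = list(base = 0.3, scale = 0.3, us_amp = 0.5, noise = zero,
                 rate = 100),
      pupil = list(base = 0.1, scale = 0.1, us_amp = 0, noise = zero,
                   rate = 100),
      resp = list(base = 0.1, scale = 0.1, us_amp = 0.05, noise = zero,
                  rate = 20)),
    blink_rate_per_min = 0, gaze_excursion_per_min = 0,
    scr_spike_per_min = 0, seed = seed)
}
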