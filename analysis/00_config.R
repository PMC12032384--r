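# Shared configuration for the analysis scripts: one synthetic cohort of
# 12 participants under the study design (2 blocks x 24 CS+ / 24 CS- per
# phase, 50% reinforcement), with a moderate injected group effect.
# Everything downstream is deterministic given these seeds.

library(pavcal)

DESIGN <- design_spec()
COHORT_SEED <- 20260927L
N_PARTICIPANTS <- 12L

make_cohort_spec <- function(seed = COHORT_SEED) {
  cohort_spec(n_participants = N_PARTICIPANTS, delta = 0.6,
              between_sd = 1, trial_sd = 2, seed = seed)
}

CHANNELS <- c("hpr", "scr", "psr_rf5", "peak1", "peak2", "rar")

results_dir <- function() {
  dir.create("results", showWarnings = FALSE)
  "results"
}
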