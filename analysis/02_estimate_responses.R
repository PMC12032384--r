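#!/usr/bin/env Rscript

# Step 2: run every channel's preprocessing and model inversion over the
# simulated cohort, for both phases.
#
#  - HPR: beats -> range-filtered IBIs -> 100-Hz band-passed heart period
#    (0.015-0.5 Hz) -> condition-wise convolution GLM with the gamma
#    kernel (nonreinforced CS+ and CS- only; reinforced CS+ and US as
#    nuisance).
#  - SCR: range/slope artifact rules -> 0.0159-5-Hz band-pass -> 10 Hz ->
#    session-wide trial-wise constrained GLM (CS and US/omission
#    responses) -> CS- normalization.
#  - PSR: validity/gaze filtering, foreshortening correction, per-block
#    z-scoring -> trial-wise kernel projection (RF5) and both
#    peak-scoring baselines -> +/-6 / 50%-missing exclusions.
#  - RAR: cycle detection -> 10-Hz amplitude series (0.01-2 Hz) ->
#    condition-wise GLM (learning phase only).

source("analysis/00_config.R")
out <- results_dir()

for (phase in c("learning", "recall")) {
  channels <- if (phase == "recall") setdiff(CHANNELS, "rar") else CHANNELS
  cohort <- simulate_cohort(DESIGN, make_cohort_spec(), phase = phase)
  analysis <- analyze_cohort(cohort, DESIGN, channels = channels)
  for (m in names(analysis$condition_estimates))
    write.table(analysis$condition_estimates[[m]],
                file.path(out, sprintf("estimates_%s_%s.tsv", m, phase)),
                sep = "\t", row.names = FALSE, quote = FALSE)
  for (m in names(analysis$trial_estimates))
    write.table(analysis$trial_estimates[[m]],
                file.path(out, sprintf("trials_%s_%s.tsv", m, phase)),
                sep = "\t", row.names = FALSE, quote = FALSE)
  cat(sprintf("%s phase: condition estimates for %s\n", phase,
              paste(names(analysis$condition_estimates), collapse = ", ")))
}
cat("Per-measure estimate tables written under", out, "\n")
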