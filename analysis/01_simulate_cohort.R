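#!/usr/bin/env Rscript

# Step 1: simulate the synthetic cohort (learning phase) and record what
# was injected. The generator draws a per-participant standardized CS+/CS-
# difference (mean 0.6, SD 1) and trial-level noise (SD 2), then renders
# four channels: beat times via integral pulse frequency modulation, skin
# conductance with CS- and US-locked phasic responses, pupil diameter with
# blinks and gaze, and a respiration carrier with a modulated envelope.
#
# Waveforms are large and reproducible from the seed, so only the design
# tables and injected ground truth go to results/; full recordings can be
# re-rendered on demand (see scratch/ note below).

source("analysis/00_config.R")

cohort <- simulate_cohort(DESIGN, make_cohort_spec(), phase = "learning")
out <- results_dir()

truth_all <- do.call(rbind, lapply(cohort, function(rec) {
  cbind(participant = rec$participant, rec$truth,
        d_i = rec$d)
}))
num <- vapply(truth_all, is.numeric, TRUE)
truth_all[num] <- lapply(truth_all[num], function(x) round(x, 4))
write.table(truth_all, file.path(out, "cohort_truth_learning.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
write_events(cohort[[1]]$events,
             file.path(out, "example_events_learning.tsv"),
             cs_duration = DESIGN$cs_duration)

d_i <- vapply(cohort, `[[`, 0, "d")
cat(sprintf("Simulated %d participants, %d trials each.\n",
            length(cohort), nrow(cohort[[1]]$events)))
cat(sprintf("Injected standardized effects d_i: mean %.2f, SD %.2f\n",
            mean(d_i), sd(d_i)))
cat(sprintf("Implied true paired effect after trial averaging: %.2f\n",
            true_paired_effect(0.6, 1, 2, 24, 48)))
cat("Ground truth written to", file.path(out, "cohort_truth_learning.tsv"),
    "\n")

# Optionally persist full waveforms for inspection (large; kept out of the
# tracked results):
if (dir.exists("scratch")) {
  dir.create("scratch/cohort_p1", showWarnings = FALSE, recursive = TRUE)
  rec <- cohort[[1]]
  writeLines(format(rec$beats, digits = 10), "scratch/cohort_p1/beats.tsv")
  write_channel(rec$scr, "scratch/cohort_p1/scr.tsv")
  write_channel(rec$resp, "scratch/cohort_p1/resp.tsv")
  cat("Example participant waveforms in scratch/cohort_p1/\n")
}
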