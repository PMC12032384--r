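#!/usr/bin/env Rscript

# Step 3: the retrodictive-validity layer. For each measure and phase:
# 3-SD participant exclusion (non-pupil measures), paired t test of the
# CS+/CS- condition means, small-sample-corrected Hedges g, and the
# retained flag at the a priori threshold g > 0.5. Trial-level measures
# additionally get the early-trial subset scan; the HPR learning/recall
# p-values get Holm-Bonferroni correction across the two confirmatory
# tests.

source("analysis/00_config.R")
out <- results_dir()

reports <- list()
for (phase in c("learning", "recall")) {
  files <- list.files(out, sprintf("^estimates_.*_%s\\.tsv$", phase),
                      full.names = TRUE)
  est <- lapply(files, read.delim)
  names(est) <- sub(sprintf("^estimates_(.*)_%s\\.tsv$", phase), "\\1",
                    basename(files))
  rep <- calibration_report(est)
  rep$phase <- phase
  reports[[phase]] <- rep
  write.table(rep, file.path(out, sprintf("calibration_%s.tsv", phase)),
              sep = "\t", row.names = FALSE, quote = FALSE)
  cat(sprintf("\n== %s phase ==\n", phase))
  print(rep[, c("measure", "n", "csp_mean", "csm_mean", "t", "df", "p",
                "g", "retained")], digits = 3, row.names = FALSE)
}

# Early-trial scan for the trial-wise measures (recall phase is where the
# early-trial effect matters: responses extinguish without reinforcement)
for (m in c("scr", "psr_rf5")) {
  f <- file.path(out, sprintf("trials_%s_recall.tsv", m))
  if (!file.exists(f)) next
  tr <- read.delim(f)
  scheme <- if (m == "scr") "nonreinforced_pairing" else "standard"
  scan <- trial_subset_scan(tr, scheme = scheme)
  write.table(scan, file.path(out, sprintf("scan_%s_recall.tsv", m)),
              sep = "\t", row.names = FALSE, quote = FALSE)
  cat(sprintf("\n%s recall scan: max g = %.2f at n = %d trials\n", m,
              max(scan$g), scan$n_trials[which.max(scan$g)]))
}

# Halves analysis on the trial-wise SCR estimates (does the effect decay
# from the first to the second half of the learning phase?)
f <- file.path(out, "trials_scr_learning.tsv")
if (file.exists(f)) {
  hv <- halves_analysis(read.delim(f))
  cat(sprintf("\nSCR learning halves: g = %.2f (first), %.2f (second)\n",
              hv$first$g, hv$second$g))
}

# Holm-Bonferroni across the two confirmatory HPR tests
hpr_p <- vapply(reports, function(r) r$p[r$measure == "hpr"], 0)
hb <- holm_bonferroni(hpr_p)
cat("\nHPR p-values (learning, recall):", signif(hpr_p, 3),
    "-> Holm-adjusted:", signif(hb$adjusted, 3),
    "; rejected:", hb$reject, "\n")
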