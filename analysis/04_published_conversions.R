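#!/usr/bin/env Rscript

# Step 4: apply the package's paired-design Hedges g conversion to the
# reference paired-test statistics of the two reward-conditioning
# experiments (bundled as inst/extdata/reference_contrasts.tsv) and
# compare with the published effect sizes.

source("analysis/00_config.R")
out <- results_dir()

ref <- read.delim(system.file("extdata", "reference_contrasts.tsv",
                              package = "pavcal"))
ref$g_computed <- round(hedges_g(ref$t, ref$n), 2)
ref$match <- ref$g_computed == ref$g_printed
write.table(ref, file.path(out, "effect_size_conversions.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
print(ref, row.names = FALSE)
cat(sprintf("\n%d of %d conversions reproduce the printed value.\n",
            sum(ref$match), nrow(ref)))
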