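#!/usr/bin/env Rscript
# Select the exposure's genetic instruments from the simulated biomarker
# GWAS: p < 1e-5, greedy clumping (10,000 kb window, r2 < 0.001 when LD is
# supplied; distance-only here since the simulated instruments are
# independent), then drop weak instruments (F < 10).

library(mrmediate)

exposure <- read_panel("results/study/exposure.tsv",
                       trait_name = "exposure", check_pvalues = FALSE)
inst <- select_instruments(exposure, p_thresh = 1e-5)
inst <- filter_weak(inst, f_min = 10)

cat(sprintf("%d instruments retained; F statistics %.0f to %.0f\n",
            nrow(inst$data), min(inst$f_stats), max(inst$f_stats)))

dir.create("results", showWarnings = FALSE)
write.table(cbind(inst$data, f_stat = unname(inst$f_stats)),
            "results/instruments.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(inst$selection_log, "results/selection_log.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote results/instruments.tsv and results/selection_log.tsv\n")
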