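#!/usr/bin/env Rscript
# Stage 3: dose-response growth inhibition.
#
# Trapezoidal AUC per replicate curve, inhibition index (1 - AUC / mean
# control AUC per strain), Welch t-tests of each dose against the 0 uM
# control, Benjamini-Hochberg adjustment across all comparisons.

suppressMessages(library(rhizoscreen))

growth <- read_growth("results/bundle/growth.tsv")
ga <- growth_analysis(growth)
dir.create("results/growth", showWarnings = FALSE, recursive = TRUE)
utils::write.table(ga$results, "results/growth/growth_results.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(ga$tests, "results/growth/growth_tests.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

summ <- aggregate(inhibition_index ~ strain_id + dose_uM, ga$results, mean)
summ <- summ[order(summ$strain_id, summ$dose_uM), ]
cat("mean inhibition index by strain and dose:\n")
print(summ, row.names = FALSE, digits = 3)
sig <- ga$tests[ga$tests$significant, ]
cat(sprintf("\n%d of %d dose-vs-control comparisons significant at FDR 0.05\n",
            nrow(sig), nrow(ga$tests)))
cat("inhibited (strain x dose):",
    paste(sprintf("%s@%g", sig$strain_id, sig$dose_uM), collapse = ", "), "\n")
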