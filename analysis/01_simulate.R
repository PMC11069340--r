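#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Emulates the experimental design of the screen: a reference degrader strain
# plus 5 degrader and 5 non-degrader isolates (200 genes each), an
# 8-gene catabolic cluster present only in degraders, a two-condition
# RNA-seq experiment (3 + 3 replicates) in which the cluster is induced
# 2^3-fold, dose-response growth curves (0/10/30/100 uM, n = 6) and an LC-MS
# peak list carrying the three pathway intermediates.

suppressMessages(library(rhizoscreen))

cfg <- sim_config(seed = 1)
bundle <- "results/bundle"
write_bundle(cfg, bundle)

sim <- simulate_panel(cfg)
cat("wrote synthetic bundle to", bundle, "\n")
print(sim$panel)
cat("planted cluster:", paste(sim$truth$cluster_locus_ids, collapse = ", "),
    "(ranks", min(sim$truth$cluster_ranks), "-",
    max(sim$truth$cluster_ranks), ")\n")
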