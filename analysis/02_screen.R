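#!/usr/bin/env Rscript
# Stage 2: the three-criteria cluster screen.
#
# Normalises counts to CPM, computes per-gene log2 fold change
# (daidzein-analogue vs control), scores conservation of every induced gene
# across the panel, intersects the criteria (induced; conserved in
# degraders; lost or diverged in non-degraders), detects chromosomal
# hotspots and tests trait enrichment of cluster presence.

suppressMessages(library(rhizoscreen))

bundle <- "results/bundle"
if (!dir.exists(bundle))
  stop("run analysis/01_simulate.R first", call. = FALSE)

report <- run_screen(bundle, "results/screen")

cat(sprintf("%d genes screened; %d upregulated (log2FC >= 1); %d candidates\n",
            report$n_genes, report$n_upregulated, report$n_candidates))
if (length(report$hotspots)) {
  hs <- report$hotspots[[1]]
  cat(sprintf("top hotspot: %s ranks %d-%d, %d candidate genes: %s\n",
              hs$replicon_id, hs$start_rank, hs$end_rank, hs$n_candidates,
              paste(hs$locus_ids, collapse = ", ")))
} else cat("no hotspot detected\n")

truth <- jsonlite::read_json(file.path(bundle, "truth.json"),
                             simplifyVector = TRUE)
found <- if (length(report$hotspots)) report$hotspots[[1]]$locus_ids else character(0)
cat(sprintf("vs planted truth: precision %.2f, recall %.2f\n",
            if (length(found)) mean(found %in% truth$cluster_locus_ids) else 0,
            mean(truth$cluster_locus_ids %in% found)))
if (!is.null(report$enrichment))
  cat(sprintf("cluster presence x legume isolation: odds ratio %s, p = %.3g (Fisher)\n",
              format(report$enrichment$odds_ratio),
              report$enrichment$p_two_sided))
cat("stage outputs in results/screen/\n")
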