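test_that("noiseless limit: degraders match the reference, non-degraders lose the cluster", {
  cfg <- small_sim_config()  # divergence 0, loss prob 1
  sim <- simulate_panel(cfg)
  panel <- sim$panel
  ref <- panel$genes[panel$genes$strain_id == "REF", ]
  for (sid in c("DEG01", "DEG02", "DEG03")) {
    g <- panel$genes[panel$genes$strain_id == sid, ]
    expect_identical(g$protein_seq, ref$protein_seq)
  }
  for (sid in c("NON01", "NON02", "NON03")) {
    g <- panel$genes[panel$genes$strain_id == sid, ]
    expect_equal(nrow(g), cfg$genes_per_strain - cfg$cluster_size)
    cluster_seqs <- ref$protein_seq[ref$locus_id %in% sim$truth$cluster_locus_ids]
    expect_false(any(cluster_seqs %in% g$protein_seq))
  }
})

test_that("all generators are byte-deterministic under a fixed seed", {
  cfg <- small_sim_config(seed = 42)
  s1 <- simulate_panel(cfg); s2 <- simulate_panel(cfg)
  expect_identical(s1, s2)
  expect_identical(simulate_counts(s1, cfg)$counts,
                   simulate_counts(s2, cfg)$counts)
  expect_identical(simulate_growth(s1, cfg = cfg), simulate_growth(s2, cfg = cfg))
  expect_identical(simulate_peaks(cfg = cfg), simulate_peaks(cfg = cfg))
})

test_that("realized protein identity matches the binomial expectation", {
  # substitution probability p -> expected identity 100(1-p); the realized
  # number of substituted sites is Binomial(L, p)
  cfg <- sim_config(seed = 3, n_degraders = 2, n_nondegraders = 2,
                    genes_per_strain = 12, protein_length = 1000,
                    cluster_size = 3, cluster_start_rank = 5,
                    background_divergence = 0.1,
                    cluster_divergence_degraders = 0.1)
  sim <- simulate_panel(cfg)
  ref <- sim$panel$genes[sim$panel$genes$strain_id == "REF", ]
  g <- sim$panel$genes[sim$panel$genes$strain_id == "DEG01", ]
  ident <- mapply(function(a, b) {
    mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
  }, ref$protein_seq, g$protein_seq)
  # mean over 12 genes x 1000 residues; 3 SD band of the per-site binomial
  se3 <- 3 * sqrt(0.1 * 0.9 / (12 * 1000))
  expect_lt(abs(mean(ident) - 0.9), se3)
})

test_that("planted induction is recovered at the configured magnitude", {
  # Poisson limit, mean 1000: estimated cluster log2FC within +-0.3 of 3.
  # Library factors are estimated in-test by median-of-ratios over the
  # background genes, which is robust to the induced cluster (plain CPM is
  # composition-biased when a large fraction of counts is induced).
  cfg <- small_sim_config(seed = 5, nb_dispersion = 0)
  sim <- simulate_panel(cfg)
  cm <- simulate_counts(sim, cfg)
  counts <- cm$counts
  is_cluster <- rownames(counts) %in% sim$truth$cluster_locus_ids
  geo <- exp(rowMeans(log(counts[!is_cluster, ] + 0.5)))
  sizefac <- apply(counts[!is_cluster, ], 2, function(s) median((s + 0.5) / geo))
  norm <- sweep(counts, 2, sizefac, "/")
  treated <- cm$design$sample_id[cm$design$condition == "treated"]
  control <- cm$design$sample_id[cm$design$condition == "control"]
  lfc <- log2(rowMeans(norm[, treated]) + 0.5) -
    log2(rowMeans(norm[, control]) + 0.5)
  expect_true(all(abs(lfc[is_cluster] - 3) < 0.3))
  expect_true(all(abs(lfc[!is_cluster]) < 0.5))
})

test_that("zero induction leaves no systematic treated/control ratio", {
  # with no induced genes CPM is unbiased, so the plain pipeline estimate
  # applies directly
  cfg <- small_sim_config(seed = 6, induction_log2fc = 0, nb_dispersion = 0)
  sim <- simulate_panel(cfg)
  cm <- simulate_counts(sim, cfg)
  fc <- log2_fold_change(cpm_normalize(cm), cm$design)
  expect_lt(max(abs(fc$log2fc)), 0.5)
  expect_lt(abs(mean(fc$log2fc)), 0.1)
})

test_that("growth curves respond to dose only in non-degraders", {
  cfg <- small_sim_config(seed = 1)
  sim <- simulate_panel(cfg)
  growth <- simulate_growth(sim, doses = c(0, 100), cfg = cfg)
  mean_auc <- function(sid, dose) {
    g <- growth[growth$strain_id == sid & growth$dose_uM == dose, ]
    mean(vapply(split(g, g$replicate), function(r) {
      r <- r[order(r$time_h), ]
      auc_trapezoid(r$time_h, r$od600)
    }, numeric(1)))
  }
  expect_lt(mean_auc("NON01", 100), mean_auc("NON01", 0) * 0.8)
  expect_gt(mean_auc("DEG01", 100), mean_auc("DEG01", 0) * 0.95)
  expect_error(simulate_growth(sim, doses = c(-1, 0), cfg = cfg), "negative")
  expect_error(simulate_growth(sim, doses = c(10, 30), cfg = cfg), "control")
})

test_that("peak lists plant each formula at its deprotonated mass", {
  cfg0 <- small_sim_config(ms_ppm_sigma = 0)
  peaks <- simulate_peaks(c("C15H10O5"), cfg0)
  planted <- peaks$mz[which.min(abs(peaks$mz - 269.045))]
  expect_equal(round(planted, 6), round(mz_deprotonated("C15H10O5"), 6))

  cfg2 <- small_sim_config(ms_ppm_sigma = 2)
  peaks2 <- simulate_peaks(c("C15H10O5"), cfg2)
  theo <- mz_deprotonated("C15H10O5")
  expect_true(any(abs(ppm_error(peaks2$mz, theo)) <= 3 * cfg2$ms_ppm_sigma))
})

test_that("invalid simulation configurations are rejected", {
  expect_error(sim_config(cluster_size = 50, genes_per_strain = 40,
                          cluster_start_rank = 1), "does not fit")
  expect_error(sim_config(background_divergence = 1.2), "background_divergence")
  expect_error(sim_config(cluster_loss_prob = -0.1), "cluster_loss_prob")
})
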