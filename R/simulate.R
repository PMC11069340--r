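#' Simulation configuration for the synthetic strain panel
#'
#' Defines the study conditions the generators emulate: a panel of isolates
#' whose proteomes diverge from a reference at class-dependent rates with a
#' catabolic gene cluster planted only in degraders; negative-binomial RNA-seq
#' counts with the cluster induced under treatment; logistic growth curves
#' with dose-dependent inhibition of non-degraders; and an LC-MS peak list
#' containing the pathway intermediates at ppm-scale mass accuracy.
#'
#' Mutations are i.i.d. per-residue substitutions to a uniformly chosen
#' different residue (no indels), so the expected percent identity of a
#' mutated copy is exactly `100 * (1 - p)` — the closed form the conservation
#' tests exploit. Gene loss is whole-gene. Counts are negative-binomial with
#' mean `mean_count` (times `2^induction_log2fc` for cluster genes under
#' treatment) and dispersion `nb_dispersion`; per-sample library-size factors
#' are drawn log-normally (sigma `libsize_sigma`) so CPM normalisation is
#' actually exercised.
#'
#' @param seed integer seed; all generators are fully deterministic given it
#' @param n_degraders,n_nondegraders panel sizes, excluding the reference
#'   strain (itself a degrader)
#' @param genes_per_strain genes in the reference genome
#' @param protein_length protein length in residues
#' @param cluster_size number of planted cluster genes
#' @param cluster_start_rank coordinate rank of the first cluster gene
#' @param background_divergence per-residue substitution probability for
#'   background genes in all strains
#' @param cluster_divergence_degraders per-residue substitution probability
#'   for cluster orthologs carried by degraders
#' @param cluster_loss_prob probability that a non-degrader loses each
#'   cluster gene outright; retained copies are mutated at
#'   `background_divergence + 0.25` (capped at 0.9)
#' @param induction_log2fc planted log2 fold change on cluster genes
#' @param mean_count negative-binomial mean for background genes
#' @param nb_dispersion negative-binomial dispersion (0 = Poisson limit)
#' @param n_replicates RNA-seq replicates per condition
#' @param libsize_sigma sdlog of the log-normal library-size factors
#' @param growth_K,growth_r,growth_t0 logistic growth parameters: carrying
#'   capacity (OD600), rate (per hour) and lag midpoint (hours)
#' @param inhibition_slope fractional growth-rate reduction per uM dose for
#'   non-degraders (degraders are unaffected)
#' @param growth_noise_sd Gaussian OD600 read noise
#' @param growth_t_max,growth_dt plate-read horizon and interval, hours
#' @param growth_replicates replicates per strain x dose
#' @param ms_ppm_sigma mass error (ppm, 1 sd) applied to planted peaks
#' @param n_decoy_peaks uniform decoy peaks added over m/z 50-350
#' @return a validated `sim_config` list
#' @export
sim_config <- function(seed = 1L,
                       n_degraders = 5L,
                       n_nondegraders = 5L,
                       genes_per_strain = 200L,
                       protein_length = 120L,
                       cluster_size = 8L,
                       cluster_start_rank = 101L,
                       background_divergence = 0.05,
                       cluster_divergence_degraders = 0.10,
                       cluster_loss_prob = 1.0,
                       induction_log2fc = 3.0,
                       mean_count = 1000,
                       nb_dispersion = 0.1,
                       n_replicates = 3L,
                       libsize_sigma = 0.2,
                       growth_K = 1.0,
                       growth_r = 0.35,
                       growth_t0 = 12,
                       inhibition_slope = 0.006,
                       growth_noise_sd = 0.02,
                       growth_t_max = 48,
                       growth_dt = 0.5,
                       growth_replicates = 6L,
                       ms_ppm_sigma = 2,
                       n_decoy_peaks = 20L) {
  cfg <- as.list(environment())
  assert_scalar_number(cfg$seed, "seed")
  for (nm in c("n_degraders", "n_nondegraders", "genes_per_strain",
               "protein_length", "cluster_size", "n_replicates",
               "growth_replicates"))
    assert_scalar_number(cfg[[nm]], nm, lower = 1)
  if (cfg$n_replicates < 2L)
    stop_input("n_replicates must be >= 2")
  for (nm in c("background_divergence", "cluster_divergence_degraders"))
    assert_scalar_number(cfg[[nm]], nm, lower = 0, upper = 0.999)
  assert_scalar_number(cfg$cluster_loss_prob, "cluster_loss_prob", 0, 1)
  assert_scalar_number(cfg$nb_dispersion, "nb_dispersion", lower = 0)
  assert_scalar_number(cfg$mean_count, "mean_count", lower = 1e-9)
  assert_scalar_number(cfg$ms_ppm_sigma, "ms_ppm_sigma", lower = 0)
  if (cfg$cluster_start_rank < 1 ||
      cfg$cluster_start_rank + cfg$cluster_size - 1 > cfg$genes_per_strain)
    stop_input("planted cluster (ranks %d-%d) does not fit in %d genes",
               cfg$cluster_start_rank,
               cfg$cluster_start_rank + cfg$cluster_size - 1,
               cfg$genes_per_strain)
  class(cfg) <- "sim_config"
  cfg
}

AA20 <- setdiff(PROTEIN_ALPHABET, "X")

random_protein <- function(len) {
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

# i.i.d. substitution to a uniformly chosen *different* residue
mutate_protein <- function(seq, p) {
  if (p <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- stats::runif(length(chars)) < p
  if (any(hit)) {
    repl <- vapply(chars[hit],
                   function(a) sample(setdiff(AA20, a), 1L),
                   character(1))
    chars[hit] <- repl
  }
  paste(chars, collapse = "")
}

#' Simulate a strain panel with a planted catabolic cluster
#'
#' The reference strain carries the planted cluster; every degrader carries
#' mutated orthologs of all cluster genes; each non-degrader loses each
#' cluster gene with `cluster_loss_prob` and mutates retained copies heavily.
#' Background genes are mutated at the background rate in every strain. Gene
#' coordinates place all genes on one replicon in rank order.
#'
#' @param cfg a [sim_config()]
#' @return list with elements `panel` (a `strain_panel`) and `truth`
#'   (planted cluster locus IDs and ranks)
#' @export
simulate_panel <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n_genes <- cfg$genes_per_strain
  cluster_ranks <- seq(cfg$cluster_start_rank,
                       length.out = cfg$cluster_size)
  ref_id <- "REF"
  deg_ids <- sprintf("DEG%02d", seq_len(cfg$n_degraders))
  non_ids <- sprintf("NON%02d", seq_len(cfg$n_nondegraders))

  ref_prot <- vapply(rep(cfg$protein_length, n_genes), random_protein,
                     character(1))
  ref_locus <- sprintf("%05d", 10L * seq_len(n_genes))
  gene_len_nt <- 3L * cfg$protein_length + 3L
  starts <- 1L + (seq_len(n_genes) - 1L) * (gene_len_nt + 200L)

  ref_genes <- data.frame(
    strain_id = ref_id, locus_id = ref_locus, replicon_id = "chr1",
    start = starts, end = starts + gene_len_nt - 1L,
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    product = ifelse(seq_len(n_genes) %in% cluster_ranks,
                     "planted catabolic cluster protein",
                     "hypothetical protein"),
    protein_seq = unname(ref_prot),
    stringsAsFactors = FALSE
  )

  make_strain <- function(sid, degrader) {
    keep <- rep(TRUE, n_genes)
    p <- rep(cfg$background_divergence, n_genes)
    if (degrader) {
      p[cluster_ranks] <- cfg$cluster_divergence_degraders
    } else {
      lost <- stats::runif(length(cluster_ranks)) < cfg$cluster_loss_prob
      keep[cluster_ranks[lost]] <- FALSE
      p[cluster_ranks] <- min(cfg$background_divergence + 0.25, 0.9)
    }
    idx <- which(keep)
    data.frame(
      strain_id = sid,
      locus_id = sprintf("%s_%04d", sid, seq_along(idx)),
      replicon_id = "chr1",
      start = starts[idx], end = starts[idx] + gene_len_nt - 1L,
      strand = ref_genes$strand[idx],
      product = ref_genes$product[idx],
      protein_seq = vapply(idx, function(i) mutate_protein(ref_prot[[i]], p[[i]]),
                           character(1)),
      stringsAsFactors = FALSE
    )
  }

  others <- lapply(c(deg_ids, non_ids), function(sid)
    make_strain(sid, degrader = sid %in% deg_ids))
  genes <- do.call(rbind, c(list(ref_genes), others))

  phenotypes <- data.frame(
    strain_id = c(ref_id, deg_ids, non_ids),
    degrader = c(TRUE, rep(TRUE, length(deg_ids)), rep(FALSE, length(non_ids))),
    isolation_source = c("legume", rep("legume", length(deg_ids)),
                         rep("soil", length(non_ids))),
    stringsAsFactors = FALSE
  )

  proteins <- stats::setNames(genes$protein_seq,
                              paste(genes$strain_id, genes$locus_id, sep = "|"))
  panel <- build_panel(genes[, GENE_TABLE_COLS], proteins, phenotypes, ref_id)
  truth <- list(cluster_locus_ids = ref_locus[cluster_ranks],
                cluster_ranks = cluster_ranks,
                replicon_id = "chr1")
  list(panel = panel, truth = truth)
}

#' Simulate a two-condition RNA-seq count matrix for the reference strain
#'
#' Background genes have negative-binomial mean `mean_count` in both
#' conditions; planted cluster genes have their treated-condition mean
#' multiplied by `2^induction_log2fc`. Per-sample library-size factors are
#' log-normal.
#'
#' @param sim output of [simulate_panel()]
#' @param cfg the same [sim_config()]
#' @return a `count_matrix`
#' @export
simulate_counts <- function(sim, cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  ref <- reference_genes(sim$panel)
  n_genes <- nrow(ref)
  nrep <- cfg$n_replicates
  sample_ids <- c(sprintf("treated_%d", seq_len(nrep)),
                  sprintf("control_%d", seq_len(nrep)))
  condition <- rep(c("treated", "control"), each = nrep)
  libfac <- stats::rlnorm(2L * nrep, meanlog = 0, sdlog = cfg$libsize_sigma)
  is_cluster <- ref$locus_id %in% sim$truth$cluster_locus_ids
  base_mu <- rep(cfg$mean_count, n_genes)
  counts <- matrix(0L, n_genes, 2L * nrep,
                   dimnames = list(ref$locus_id, sample_ids))
  for (s in seq_along(sample_ids)) {
    mu <- base_mu * libfac[[s]]
    if (condition[[s]] == "treated")
      mu[is_cluster] <- mu[is_cluster] * 2^cfg$induction_log2fc
    counts[, s] <- if (cfg$nb_dispersion <= 0) {
      stats::rpois(n_genes, mu)
    } else {
      stats::rnbinom(n_genes, mu = mu, size = 1 / cfg$nb_dispersion)
    }
  }
  design <- data.frame(sample_id = sample_ids, condition = condition,
                       replicate = rep(seq_len(nrep), times = 2L),
                       stringsAsFactors = FALSE)
  count_matrix(counts, design)
}

#' Simulate dose-response growth curves
#'
#' Logistic growth `OD(t) = K / (1 + exp(-r (t - t0)))` with Gaussian read
#' noise; for non-degraders both the rate and the carrying capacity are
#' scaled by `1 - inhibition_slope * dose` (floored at zero), the usual
#' sub-inhibitory antimicrobial effect of slower growth and lower final
#' yield. Degraders grow identically at every dose.
#'
#' @param sim output of [simulate_panel()]
#' @param doses doses in uM; must include 0 (the control)
#' @param cfg the same [sim_config()]
#' @return long data.frame: `strain_id, dose_uM, replicate, time_h, od600`
#' @export
simulate_growth <- function(sim, doses = c(0, 10, 30, 100),
                            cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  if (any(doses < 0)) stop_input("negative dose")
  if (!0 %in% doses) stop_input("doses must include the 0 uM control")
  set.seed(cfg$seed + 2L)
  times <- seq(0, cfg$growth_t_max, by = cfg$growth_dt)
  ph <- sim$panel$phenotypes
  rows <- list()
  for (i in seq_len(nrow(ph))) {
    for (dose in doses) {
      inhib <- if (ph$degrader[[i]]) 1 else
        max(0, 1 - cfg$inhibition_slope * dose)
      r_eff <- cfg$growth_r * inhib
      k_eff <- cfg$growth_K * inhib
      for (rep_i in seq_len(cfg$growth_replicates)) {
        od <- k_eff / (1 + exp(-r_eff * (times - cfg$growth_t0)))
        od <- pmax(0, od + stats::rnorm(length(times), sd = cfg$growth_noise_sd))
        rows[[length(rows) + 1L]] <- data.frame(
          strain_id = ph$strain_id[[i]], dose_uM = dose, replicate = rep_i,
          time_h = times, od600 = od, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Simulate an LC-MS peak list containing pathway intermediates
#'
#' One peak per candidate formula at its theoretical deprotonated m/z,
#' perturbed by Normal(0, `ms_ppm_sigma` ppm), plus uniform decoy peaks over
#' m/z 50-350.
#'
#' @param formulas character vector of molecular formulas (must contain H)
#' @param cfg a [sim_config()]
#' @return data.frame `rt_min, mz, intensity`, ordered by retention time
#' @export
simulate_peaks <- function(formulas = c("C15H10O5", "C10H10O3", "C10H10O4"),
                           cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 3L)
  theo <- vapply(formulas, function(f) mz_deprotonated(parse_formula(f)),
                 numeric(1))
  n <- length(theo)
  planted <- data.frame(
    rt_min = stats::runif(n, 5, 18),
    mz = theo * (1 + stats::rnorm(n, sd = cfg$ms_ppm_sigma) * 1e-6),
    intensity = stats::rlnorm(n, meanlog = log(1e6), sdlog = 0.3)
  )
  decoys <- data.frame(
    rt_min = stats::runif(cfg$n_decoy_peaks, 0, 20),
    mz = stats::runif(cfg$n_decoy_peaks, 50, 350),
    intensity = stats::rlnorm(cfg$n_decoy_peaks, meanlog = log(1e4), sdlog = 0.5)
  )
  out <- rbind(planted, decoys)
  out[order(out$rt_min), , drop = FALSE]
}

#' Write a complete synthetic input bundle to disk
#'
#' Emits exactly the plain-text formats the readers consume: `genes.tsv`,
#' `proteins.fasta` (IDs `strain|locus`), `phenotypes.tsv`, `counts.tsv`,
#' `design.tsv`, `growth.tsv`, `peaks.tsv` and `truth.json`.
#'
#' @param cfg a [sim_config()]
#' @param dir output directory (created if absent)
#' @param doses growth-assay doses in uM
#' @param formulas planted MS formulas
#' @return `dir`, invisibly
#' @export
write_bundle <- function(cfg = sim_config(), dir,
                         doses = c(0, 10, 30, 100),
                         formulas = c("C15H10O5", "C10H10O3", "C10H10O4")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_panel(cfg)
  cm <- simulate_counts(sim, cfg)
  growth <- simulate_growth(sim, doses, cfg)
  peaks <- simulate_peaks(formulas, cfg)

  genes <- sim$panel$genes
  write_tsv_plain(genes[, GENE_TABLE_COLS], file.path(dir, "genes.tsv"))
  write_fasta(stats::setNames(genes$protein_seq,
                              paste(genes$strain_id, genes$locus_id, sep = "|")),
              file.path(dir, "proteins.fasta"))
  write_tsv_plain(sim$panel$phenotypes, file.path(dir, "phenotypes.tsv"))
  counts_df <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                          check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_plain(counts_df, file.path(dir, "counts.tsv"))
  write_tsv_plain(cm$design, file.path(dir, "design.tsv"))
  write_tsv_plain(growth, file.path(dir, "growth.tsv"))
  write_tsv_plain(peaks, file.path(dir, "peaks.tsv"))
  jsonlite::write_json(
    c(sim$truth,
      list(reference_strain_id = sim$panel$reference_strain_id,
           formulas = formulas)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
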