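#' Configuration for a full screen run
#'
#' Collects every tunable of the pipeline in one validated list. Unknown
#' keys are rejected so typos fail loudly. Field groups: screening criteria
#' (see [screen_criteria()]), hotspot detection, alignment, growth and mass
#' annotation.
#'
#' @param criteria a [screen_criteria()]
#' @param hotspot_min_run,hotspot_max_gap see [find_hotspots()]
#' @param substitution_matrix,gap_open,gap_extend,min_coverage alignment
#'   settings, see [conservation_matrix()]
#' @param restrict_to_upregulated compute conservation only for genes that
#'   pass the expression criterion (the candidate set is unchanged; the
#'   full matrix is only needed for genome-wide heatmaps)
#' @param growth_index_variant see [inhibition_index()]
#' @param mass_tol_ppm,mass_electron_correction see [annotate_peaks()]
#' @param trait_sources isolation sources counted as trait-positive for the
#'   enrichment test
#' @param presence_min_fraction fraction of top-hotspot genes a strain must
#'   conserve for the cluster to be called present in it
#' @return a `run_config` list
#' @export
run_config <- function(criteria = screen_criteria(),
                       hotspot_min_run = 4L,
                       hotspot_max_gap = 2L,
                       substitution_matrix = "BLOSUM62",
                       gap_open = 10,
                       gap_extend = 1,
                       min_coverage = 50,
                       restrict_to_upregulated = TRUE,
                       growth_index_variant = "one_minus_ratio",
                       mass_tol_ppm = 10,
                       mass_electron_correction = FALSE,
                       trait_sources = "legume",
                       presence_min_fraction = 0.5) {
  cfg <- as.list(environment())
  stopifnot(inherits(cfg$criteria, "screen_criteria"))
  assert_scalar_number(cfg$hotspot_min_run, "hotspot_min_run", lower = 1)
  assert_scalar_number(cfg$hotspot_max_gap, "hotspot_max_gap", lower = 0)
  assert_scalar_number(cfg$mass_tol_ppm, "mass_tol_ppm", lower = 1e-12)
  assert_scalar_number(cfg$presence_min_fraction, "presence_min_fraction", 0, 1)
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; `criteria` is a
#' nested map of [screen_criteria()] arguments. Unknown keys are rejected.
#'
#' @param path YAML file
#' @return a `run_config`
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop_input("the 'yaml' package is required to read YAML configs")
  raw <- yaml::read_yaml(path)
  crit_args <- raw$criteria %||% list()
  unknown <- setdiff(names(crit_args), names(formals(screen_criteria)))
  if (length(unknown))
    stop_input("unknown criteria key: %s", unknown[[1]])
  raw$criteria <- NULL
  unknown <- setdiff(names(raw), setdiff(names(formals(run_config)), "criteria"))
  if (length(unknown))
    stop_input("unknown config key: %s", unknown[[1]])
  do.call(run_config, c(list(criteria = do.call(screen_criteria, crit_args)), raw))
}

read_bundle_panel <- function(dir) {
  genes <- read_gene_table(file.path(dir, "genes.tsv"))
  proteins <- read_fasta(file.path(dir, "proteins.fasta"))
  phenotypes <- read_phenotypes(file.path(dir, "phenotypes.tsv"))
  truth_path <- file.path(dir, "truth.json")
  ref <- if (file.exists(truth_path)) {
    jsonlite::read_json(truth_path)$reference_strain_id
  } else NULL
  if (is.null(ref)) {
    # default: the strain whose genes are counted in counts.tsv
    counts_genes <- read_tsv_plain(file.path(dir, "counts.tsv"))$gene_id
    hit <- genes$strain_id[match(as.character(counts_genes[1]), genes$locus_id)]
    if (is.na(hit)) stop_input("cannot infer the reference strain; provide truth.json")
    ref <- hit
  }
  build_panel(genes, proteins, phenotypes, ref)
}

#' Run the three-criteria cluster screen end-to-end
#'
#' Reads an input bundle (the file set written by [write_bundle()]:
#' `genes.tsv`, `proteins.fasta`, `phenotypes.tsv`, `counts.tsv`,
#' `design.tsv`), normalises counts, computes fold changes, builds the
#' phenotype-stratified conservation matrix, classifies candidates, detects
#' hotspots and tests trait enrichment of top-hotspot presence. All stage
#' tables are written under `out_dir` together with a machine-readable
#' `report.json` (no timestamps, so reruns are byte-identical).
#'
#' @param bundle_dir directory with the input files
#' @param out_dir output directory (created)
#' @param config a [run_config()]
#' @return the report, invisibly (also written as `report.json`)
#' @export
run_screen <- function(bundle_dir, out_dir, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  panel <- read_bundle_panel(bundle_dir)
  cm <- read_counts(file.path(bundle_dir, "counts.tsv"),
                    file.path(bundle_dir, "design.tsv"))

  cpm <- cpm_normalize(cm)
  fc <- log2_fold_change(cpm, cm$design,
                         log2fc_threshold = config$criteria$log2fc_threshold)
  write_tsv_plain(fc, file.path(out_dir, "foldchange.tsv"))

  score_genes <- if (config$restrict_to_upregulated) {
    call_upregulated(fc, config$criteria$log2fc_threshold)
  } else NULL
  cons <- conservation_matrix(panel, reference_gene_ids = score_genes,
                              min_coverage = config$min_coverage,
                              substitution_matrix = config$substitution_matrix,
                              gap_open = config$gap_open,
                              gap_extend = config$gap_extend)
  write_tsv_plain(cons, file.path(out_dir, "conservation.tsv"))

  candidates <- classify_candidates(
    fc, cons, panel$phenotypes, config$criteria,
    reference_strain_id = panel$reference_strain_id)
  ref <- reference_genes(panel)
  gene_flags <- data.frame(
    replicon_id = ref$replicon_id, rank = ref$rank, locus_id = ref$locus_id,
    candidate = candidates$candidate[match(ref$locus_id, candidates$gene_id)],
    stringsAsFactors = FALSE)
  write_tsv_plain(candidates, file.path(out_dir, "candidates.tsv"))

  hotspots <- find_hotspots(gene_flags,
                            min_run = config$hotspot_min_run,
                            max_gap = config$hotspot_max_gap)
  jsonlite::write_json(hotspots, file.path(out_dir, "hotspots.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  enrichment <- NULL
  if (length(hotspots)) {
    presence <- cluster_presence(panel, cons, hotspots[[1]], config)
    trait <- stats::setNames(
      panel$phenotypes$isolation_source %in% config$trait_sources,
      panel$phenotypes$strain_id)
    enrichment <- trait_enrichment(presence, trait[names(presence)])
    jsonlite::write_json(
      list(table = enrichment$contingency,
           odds_ratio = enrichment$odds_ratio,
           p_two_sided = enrichment$p_two_sided),
      file.path(out_dir, "enrichment.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  report <- list(
    package_version = as.character(utils::packageVersion("rhizoscreen")),
    config = config_echo(config),
    n_genes = nrow(fc),
    n_upregulated = sum(fc$upregulated),
    n_candidates = sum(candidates$candidate),
    hotspots = hotspots,
    enrichment = if (is.null(enrichment)) NULL else list(
      table = enrichment$contingency,
      odds_ratio = enrichment$odds_ratio,
      p_two_sided = enrichment$p_two_sided))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

# per-strain presence call for the hotspot cluster: fraction of hotspot
# genes conserved in the strain at the screen's conserved thresholds
cluster_presence <- function(panel, cons, hotspot, config) {
  crit <- config$criteria
  strains <- panel$phenotypes$strain_id
  vapply(strains, function(sid) {
    rows <- cons[cons$strain_id == sid &
                   cons$gene_id %in% hotspot$locus_ids, , drop = FALSE]
    conserved <- !is.na(rows$identity_pct) &
      rows$identity_pct >= crit$conserved_identity_min &
      rows$coverage_pct >= crit$conserved_coverage_min
    sum(conserved) / length(hotspot$locus_ids) >= config$presence_min_fraction
  }, logical(1))
}

#' Run the full analysis: screen, growth assay and mass annotation
#'
#' [run_screen()] plus the dose-response growth analysis (`growth.tsv`) and
#' exact-mass peak annotation (`peaks.tsv` against the candidate formulas in
#' `truth.json`, or `formulas`). Results are folded into `report.json`.
#'
#' @param bundle_dir directory with the input files
#' @param out_dir output directory
#' @param config a [run_config()]
#' @param formulas candidate formulas for peak annotation; default: the
#'   `formulas` field of the bundle's `truth.json`
#' @return the report, invisibly
#' @export
run_all <- function(bundle_dir, out_dir, config = run_config(),
                    formulas = NULL) {
  report <- run_screen(bundle_dir, out_dir, config)

  growth_path <- file.path(bundle_dir, "growth.tsv")
  if (!file.exists(growth_path))
    stop_input("growth input not found: %s", growth_path)
  growth <- read_growth(growth_path)
  ga <- growth_analysis(growth, variant = config$growth_index_variant)
  write_tsv_plain(ga$results, file.path(out_dir, "growth_results.tsv"))
  write_tsv_plain(ga$tests, file.path(out_dir, "growth_tests.tsv"))

  peaks_path <- file.path(bundle_dir, "peaks.tsv")
  if (!file.exists(peaks_path))
    stop_input("peaks input not found: %s", peaks_path)
  peaks <- read_peaks(peaks_path)
  if (is.null(formulas)) {
    truth_path <- file.path(bundle_dir, "truth.json")
    if (file.exists(truth_path))
      formulas <- unlist(jsonlite::read_json(truth_path)$formulas)
  }
  if (is.null(formulas))
    stop_input("no candidate formulas supplied for peak annotation")
  ann <- annotate_peaks(peaks, formulas, tol_ppm = config$mass_tol_ppm,
                        electron_correction = config$mass_electron_correction)
  write_tsv_plain(ann, file.path(out_dir, "annotations.tsv"))

  report$growth <- list(
    n_strains = length(unique(ga$results$strain_id)),
    tests = ga$tests)
  report$annotations <- ann
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

config_echo <- function(config) {
  out <- unclass(config)
  out$criteria <- unclass(out$criteria)
  out
}
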