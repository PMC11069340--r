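#' Screening criteria for the three-way candidate filter
#'
#' The screen keeps a gene when it is (1) upregulated under the substrate,
#' (2) conserved in at least `conserved_fraction_degraders` of the degrader
#' strains (identity and coverage at or above the conserved thresholds), and
#' (3) less conserved in at least `nonconserved_fraction_nondegraders` of the
#' non-degraders (best hit absent, or identity below
#' `nonconserved_identity_max`). The thresholds are package choices exposed
#' as configuration; the two identity bounds must not overlap.
#'
#' @param log2fc_threshold minimum log2 fold change for criterion (1)
#' @param conserved_identity_min,conserved_coverage_min percent thresholds
#'   defining "conserved" in degraders
#' @param conserved_fraction_degraders required fraction of degrader strains
#' @param nonconserved_identity_max identity below which (or absence) a gene
#'   counts as "less conserved" in a non-degrader. The default (45) lies in
#'   the empirical gap between true orthologs and the best spurious hit a
#'   proteome offers: under the global-alignment identity definition the
#'   best of a few hundred unrelated proteins typically reaches 30-40
#'   percent identity, so a ceiling below 40 would misclassify genuinely
#'   absent genes as conserved
#' @param nonconserved_fraction_nondegraders required fraction of
#'   non-degrader strains
#' @return a `screen_criteria` list
#' @export
screen_criteria <- function(log2fc_threshold = 1.0,
                            conserved_identity_min = 50,
                            conserved_coverage_min = 50,
                            conserved_fraction_degraders = 1.0,
                            nonconserved_identity_max = 45,
                            nonconserved_fraction_nondegraders = 1.0) {
  cr <- as.list(environment())
  assert_scalar_number(cr$log2fc_threshold, "log2fc_threshold")
  assert_scalar_number(cr$conserved_identity_min, "conserved_identity_min", 0, 100)
  assert_scalar_number(cr$conserved_coverage_min, "conserved_coverage_min", 0, 100)
  assert_scalar_number(cr$nonconserved_identity_max, "nonconserved_identity_max", 0, 100)
  assert_scalar_number(cr$conserved_fraction_degraders,
                       "conserved_fraction_degraders", 1e-9, 1)
  assert_scalar_number(cr$nonconserved_fraction_nondegraders,
                       "nonconserved_fraction_nondegraders", 0, 1)
  if (cr$nonconserved_identity_max >= cr$conserved_identity_min)
    stop_input("nonconserved_identity_max must be below conserved_identity_min")
  class(cr) <- "screen_criteria"
  cr
}

#' Classify genes as cluster candidates by the three-way screen
#'
#' Intersects the expression criterion with the phenotype-stratified
#' conservation pattern. The reference strain itself is excluded from the
#' degrader fraction (its self-identity is 100 by construction). A gene with
#' no conservation rows is never a candidate.
#'
#' @param fc fold-change table from [log2_fold_change()]
#' @param cons conservation matrix from [conservation_matrix()]
#' @param phenotypes phenotype data.frame (`strain_id`, `degrader`)
#' @param criteria a [screen_criteria()]
#' @param reference_strain_id strain excluded from the degrader fraction
#' @return data.frame: `gene_id, upregulated, frac_conserved_degraders,
#'   frac_nonconserved_nondegraders, candidate`
#' @export
classify_candidates <- function(fc, cons, phenotypes,
                                criteria = screen_criteria(),
                                reference_strain_id = NULL) {
  stopifnot(inherits(criteria, "screen_criteria"))
  deg <- setdiff(phenotypes$strain_id[phenotypes$degrader],
                 reference_strain_id)
  non <- phenotypes$strain_id[!phenotypes$degrader]
  if (length(deg) == 0L || length(non) == 0L)
    stop_input("need at least one degrader and one non-degrader strain")

  up <- fc$log2fc >= criteria$log2fc_threshold
  frac_cons <- frac_noncons <- numeric(nrow(fc))
  has_rows <- logical(nrow(fc))
  for (i in seq_len(nrow(fc))) {
    rows <- cons[cons$gene_id == fc$gene_id[[i]], , drop = FALSE]
    has_rows[[i]] <- nrow(rows) > 0L
    drows <- rows[rows$strain_id %in% deg, , drop = FALSE]
    nrows <- rows[rows$strain_id %in% non, , drop = FALSE]
    conserved <- !is.na(drows$identity_pct) &
      drows$identity_pct >= criteria$conserved_identity_min &
      drows$coverage_pct >= criteria$conserved_coverage_min
    noncons <- is.na(nrows$identity_pct) |
      nrows$identity_pct < criteria$nonconserved_identity_max
    # strains with no row at all count as absent (non-conserved)
    frac_cons[[i]] <- (sum(conserved)) / length(deg)
    frac_noncons[[i]] <- (sum(noncons) + (length(non) - nrow(nrows))) /
      length(non)
  }
  candidate <- up & has_rows &
    frac_cons >= criteria$conserved_fraction_degraders &
    frac_noncons >= criteria$nonconserved_fraction_nondegraders
  data.frame(gene_id = fc$gene_id,
             upregulated = up,
             frac_conserved_degraders = frac_cons,
             frac_nonconserved_nondegraders = frac_noncons,
             candidate = candidate,
             stringsAsFactors = FALSE)
}

#' Detect chromosomal hotspots of candidate genes
#'
#' A hotspot is a maximal run of candidate genes, in coordinate-rank order on
#' one replicon, in which consecutive candidates are separated by at most
#' `max_gap` non-candidate genes and which contains at least `min_run`
#' candidates. Boundaries are trimmed to candidate genes. Hotspots are
#' returned sorted by candidate count (descending), then replicon, then
#' start rank.
#'
#' @param gene_flags data.frame with columns `replicon_id, rank, locus_id,
#'   candidate`, ranks being 1-based coordinate order within each replicon
#' @param min_run minimum number of candidate genes in a hotspot (>= 1)
#' @param max_gap maximum run of consecutive non-candidates allowed inside
#' @return list of hotspots; each is a list with `replicon_id, start_rank,
#'   end_rank, locus_ids` (candidate loci), `n_candidates, span, score`
#' @export
find_hotspots <- function(gene_flags, min_run = 4L, max_gap = 2L) {
  if (min_run < 1L) stop_input("min_run must be >= 1")
  if (max_gap < 0L) stop_input("max_gap must be >= 0")
  need <- c("replicon_id", "rank", "locus_id", "candidate")
  missing <- setdiff(need, names(gene_flags))
  if (length(missing))
    stop_input("gene_flags lacks column(s): %s", paste(missing, collapse = ", "))
  hotspots <- list()
  for (rep_id in unique(gene_flags$replicon_id)) {
    g <- gene_flags[gene_flags$replicon_id == rep_id, , drop = FALSE]
    g <- g[order(g$rank), , drop = FALSE]
    cand_pos <- which(g$candidate)
    if (length(cand_pos) == 0L) next
    # split candidate positions wherever the gap exceeds max_gap
    grp <- cumsum(c(1L, diff(cand_pos) > max_gap + 1L))
    for (k in split(cand_pos, grp)) {
      if (length(k) < min_run) next
      hotspots[[length(hotspots) + 1L]] <- list(
        replicon_id = rep_id,
        start_rank = g$rank[k[[1]]],
        end_rank = g$rank[k[[length(k)]]],
        locus_ids = g$locus_id[k],
        n_candidates = length(k),
        span = g$rank[k[[length(k)]]] - g$rank[k[[1]]] + 1L,
        score = length(k))
    }
  }
  if (length(hotspots) > 1L) {
    ord <- order(-vapply(hotspots, `[[`, numeric(1), "score"),
                 vapply(hotspots, `[[`, character(1), "replicon_id"),
                 vapply(hotspots, `[[`, numeric(1), "start_rank"))
    hotspots <- hotspots[ord]
  }
  hotspots
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric test with fixed margins; the two-sided p-value is
#' the sum of the probabilities of all tables whose point probability does
#' not exceed that of the observed table (with a 1e-7 relative tolerance on
#' the comparison, the convention of mainstream implementations). The odds
#' ratio is the unconditioned cross-product `ad/bc` (`Inf` when `bc = 0`
#' and `ad > 0`).
#'
#' @param table 2x2 matrix (or length-4 vector, row-major `a,b,c,d`) of
#'   non-negative integer counts
#' @return list: `contingency`, `odds_ratio`, `p_two_sided`
#' @export
#' @examples
#' fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2, byrow = TRUE))$p_two_sided
fisher_exact_2x2 <- function(table) {
  tab <- if (is.matrix(table)) table else matrix(as.numeric(table), 2, 2, byrow = TRUE)
  if (!all(dim(tab) == c(2L, 2L))) stop_input("need a 2x2 table")
  if (any(is.na(tab)) || any(tab < 0) || any(tab != round(tab)))
    stop_input("table entries must be non-negative integers")
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  N <- a + b + c + d
  if (N <= 0) stop_input("table must have a positive grand total")
  m <- a + c          # column-1 margin (white balls)
  n <- b + d          # column-2 margin
  k <- a + b          # row-1 margin (draws)
  lo <- max(0, k - n); hi <- min(k, m)
  support <- lo:hi
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  odds <- if (b * c == 0) {
    if (a * d > 0) Inf else NaN
  } else a * d / (b * c)
  list(contingency = matrix(c(a, b, c, d), 2, 2, byrow = TRUE),
       odds_ratio = odds, p_two_sided = p)
}

#' Trait enrichment of cluster presence across strains
#'
#' Builds the 2x2 presence-by-trait contingency table over a common strain
#' universe and applies [fisher_exact_2x2()] — the test behind "is the
#' cluster found specifically in strains from trait-positive environments".
#'
#' @param presence named logical vector: cluster present per strain
#' @param trait named logical vector: trait per strain (same names)
#' @return list as [fisher_exact_2x2()], table rows = present/absent,
#'   columns = trait/non-trait
#' @export
trait_enrichment <- function(presence, trait) {
  strains <- names(presence)
  if (is.null(strains) || length(strains) == 0L)
    stop_input("presence must be a named, non-empty logical vector")
  if (!setequal(strains, names(trait)))
    stop_input("presence and trait must cover the same strains")
  trait <- trait[strains]
  tab <- matrix(c(sum(presence & trait), sum(presence & !trait),
                  sum(!presence & trait), sum(!presence & !trait)),
                2, 2, byrow = TRUE,
                dimnames = list(c("present", "absent"),
                                c("trait", "non_trait")))
  fisher_exact_2x2(tab)
}
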