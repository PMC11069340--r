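# Conservation scoring: global affine-gap alignment of each reference
# protein against every protein of every panel strain, summarised as
# percent identity and reference coverage. Alignment is delegated to
# Biostrings::pairwiseAlignment; score conventions (BLOSUM62, gap open 10,
# gap extend 1, end gaps penalised) are fixed here and verified against an
# independent dynamic-programming oracle in the test suite.

get_substitution_matrix <- function(name = "BLOSUM62") {
  env <- new.env()
  utils::data(list = name, package = "Biostrings", envir = env)
  get(name, envir = env)
}

# identity = identical pairs / both-non-gap columns; X never counts as
# identical (conservative). coverage = reference residues in both-non-gap
# columns / reference length.
ident_cov_from_strings <- function(aligned_ref, aligned_hit, ref_length) {
  a <- strsplit(aligned_ref, "")[[1]]
  b <- strsplit(aligned_hit, "")[[1]]
  both <- a != "-" & b != "-"
  n_pairs <- sum(both)
  ident <- sum(both & a == b & a != "X")
  c(identity_pct = if (n_pairs > 0) 100 * ident / n_pairs else 0,
    coverage_pct = 100 * n_pairs / ref_length)
}

#' Global pairwise protein alignment with affine gaps
#'
#' Needleman-Wunsch/Gotoh global alignment (end gaps penalised) under a
#' substitution matrix, with gap cost `gap_open + k * gap_extend` for a gap
#' of length k. Returns the aligned strings plus percent identity over
#' aligned (both-non-gap) columns and coverage of sequence `a` (the
#' reference). A global aligner with a consistent scoring scheme is used as
#' the conservation score throughout the screen.
#'
#' @param a reference protein sequence
#' @param b target protein sequence
#' @param substitution_matrix matrix name (default `"BLOSUM62"`) or an
#'   actual substitution matrix
#' @param gap_open,gap_extend affine gap penalties (positive numbers)
#' @return list: `aligned_a`, `aligned_b`, `score`, `identity_pct`,
#'   `coverage_pct`
#' @export
#' @examples
#' global_align("MKVL", "MKIL")$identity_pct  # 75
global_align <- function(a, b, substitution_matrix = "BLOSUM62",
                         gap_open = 10, gap_extend = 1) {
  assert_protein(a, "sequence a")
  assert_protein(b, "sequence b")
  mat <- if (is.character(substitution_matrix))
    get_substitution_matrix(substitution_matrix) else substitution_matrix
  aln <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b, type = "global",
    substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend)
  aligned_a <- as.character(Biostrings::alignedPattern(aln))
  aligned_b <- as.character(Biostrings::alignedSubject(aln))
  ic <- ident_cov_from_strings(aligned_a, aligned_b, nchar(a))
  list(aligned_a = unname(aligned_a), aligned_b = unname(aligned_b),
       score = Biostrings::score(aln),
       identity_pct = unname(ic[["identity_pct"]]),
       coverage_pct = unname(ic[["coverage_pct"]]))
}

#' Identity and coverage of an alignment
#'
#' @param aligned_a,aligned_b gapped aligned strings of equal length;
#'   `aligned_a` is the reference
#' @param ref_length ungapped length of the reference sequence
#' @return named numeric vector `identity_pct`, `coverage_pct`
#' @export
identity_and_coverage <- function(aligned_a, aligned_b, ref_length) {
  if (nchar(aligned_a) != nchar(aligned_b))
    stop_input("aligned strings differ in length")
  ident_cov_from_strings(aligned_a, aligned_b, ref_length)
}

# Align one reference protein against a whole strain proteome in one
# vectorised pairwiseAlignment call; returns per-target identity/coverage.
align_one_vs_all <- function(ref_seq, targets, mat, gap_open, gap_extend) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(targets),
    subject = ref_seq, type = "global",
    substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend)
  # fast path: both-non-gap columns = nmatch + nmismatch (reference is the
  # subject here)
  nm <- Biostrings::nmatch(aln)
  nmm <- Biostrings::nmismatch(aln)
  pairs <- nm + nmm
  ref_len <- nchar(ref_seq)
  has_x <- grepl("X", ref_seq, fixed = TRUE) | grepl("X", targets, fixed = TRUE)
  identity <- ifelse(pairs > 0, 100 * nm / pairs, 0)
  coverage <- 100 * pairs / ref_len
  if (any(has_x)) {
    # nmatch counts X==X as identical; recount those pairs from strings
    ap <- as.character(Biostrings::alignedSubject(aln))
    ah <- as.character(Biostrings::alignedPattern(aln))
    for (i in which(has_x)) {
      ic <- ident_cov_from_strings(ap[[i]], ah[[i]], ref_len)
      identity[[i]] <- ic[["identity_pct"]]
      coverage[[i]] <- ic[["coverage_pct"]]
    }
  }
  data.frame(target_locus = names(targets),
             identity_pct = identity, coverage_pct = coverage,
             stringsAsFactors = FALSE)
}

#' Best-hit conservation matrix of reference genes across a strain panel
#'
#' For every (reference gene, strain) pair, aligns the reference protein
#' against every protein of the strain and keeps the best hit: the target
#' maximising percent identity among hits with coverage at least
#' `min_coverage` (ties broken by lexicographically lowest target locus ID).
#' Cells with no qualifying hit are reported absent (`NA` identity). The
#' reference strain's own column is 100/100 by construction.
#'
#' @param panel a `strain_panel`
#' @param reference_gene_ids locus IDs of reference genes to score
#'   (default: all reference genes)
#' @param min_coverage minimum reference coverage (percent) for a hit to
#'   qualify; default 50
#' @param substitution_matrix,gap_open,gap_extend see [global_align()]
#' @return long data.frame: `gene_id, strain_id, identity_pct, coverage_pct,
#'   best_hit_locus` (`NA` identity/coverage/locus = absent)
#' @export
conservation_matrix <- function(panel, reference_gene_ids = NULL,
                                min_coverage = 50,
                                substitution_matrix = "BLOSUM62",
                                gap_open = 10, gap_extend = 1) {
  stopifnot(inherits(panel, "strain_panel"))
  ref <- reference_genes(panel)
  if (is.null(reference_gene_ids)) reference_gene_ids <- ref$locus_id
  missing <- setdiff(reference_gene_ids, ref$locus_id)
  if (length(missing))
    stop_input("gene %s is not a reference-strain gene", missing[[1]])
  ref_seqs <- stats::setNames(ref$protein_seq, ref$locus_id)[reference_gene_ids]
  mat <- if (is.character(substitution_matrix))
    get_substitution_matrix(substitution_matrix) else substitution_matrix
  strains <- unique(panel$genes$strain_id)
  out <- vector("list", length(strains))
  for (si in seq_along(strains)) {
    sid <- strains[[si]]
    if (sid == panel$reference_strain_id) {
      out[[si]] <- data.frame(
        gene_id = reference_gene_ids, strain_id = sid,
        identity_pct = 100, coverage_pct = 100,
        best_hit_locus = reference_gene_ids, stringsAsFactors = FALSE)
      next
    }
    targets <- strain_proteins(panel, sid)
    cells <- lapply(reference_gene_ids, function(gid) {
      hits <- align_one_vs_all(ref_seqs[[gid]], targets, mat,
                               gap_open, gap_extend)
      hits <- hits[hits$coverage_pct >= min_coverage, , drop = FALSE]
      if (nrow(hits) == 0L)
        return(data.frame(gene_id = gid, strain_id = sid,
                          identity_pct = NA_real_, coverage_pct = NA_real_,
                          best_hit_locus = NA_character_,
                          stringsAsFactors = FALSE))
      hits <- hits[order(-hits$identity_pct, hits$target_locus), , drop = FALSE]
      data.frame(gene_id = gid, strain_id = sid,
                 identity_pct = hits$identity_pct[[1]],
                 coverage_pct = hits$coverage_pct[[1]],
                 best_hit_locus = hits$target_locus[[1]],
                 stringsAsFactors = FALSE)
    })
    out[[si]] <- do.call(rbind, cells)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
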