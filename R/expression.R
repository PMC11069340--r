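#' Counts-per-million normalisation
#'
#' Scales each sample (column) so it sums to one million. This is the
#' library-size normalisation behind the fold-change screen; no
#' composition-aware scaling (TMM etc.) is applied because the screen is a
#' ranking, not an inference.
#'
#' @param cm a `count_matrix` (see [count_matrix()]) or a plain numeric
#'   gene x sample matrix
#' @return numeric matrix of CPM values; columns sum to 1e6
#' @export
cpm_normalize <- function(cm) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else cm
  totals <- colSums(counts)
  zero <- colnames(counts)[totals == 0]
  if (length(zero))
    stop_input("sample %s has zero total count", zero[[1]])
  sweep(counts, 2, totals, "/") * 1e6
}

#' Per-gene log2 fold change between treated and control
#'
#' For every gene: the arithmetic mean CPM per condition and
#' `log2((mean treated + pseudocount) / (mean control + pseudocount))`.
#' The pseudocount keeps the ratio finite and pulls low-abundance genes
#' toward zero fold change; a gene absent in both conditions gets exactly 0.
#'
#' @param cpm gene x sample CPM matrix (from [cpm_normalize()])
#' @param design design data.frame with `sample_id` and `condition`
#' @param pseudocount CPM pseudocount added to both means (> 0); default 1
#' @param log2fc_threshold threshold defining the `upregulated` flag
#' @return data.frame: `gene_id, mean_cpm_control, mean_cpm_treated, log2fc,
#'   upregulated`
#' @export
log2_fold_change <- function(cpm, design, pseudocount = 1,
                             log2fc_threshold = 1) {
  assert_scalar_number(pseudocount, "pseudocount", lower = 1e-12)
  for (cond in c("treated", "control"))
    if (!cond %in% design$condition)
      stop_input("design has no '%s' samples", cond)
  treated <- design$sample_id[design$condition == "treated"]
  control <- design$sample_id[design$condition == "control"]
  mt <- rowMeans(cpm[, treated, drop = FALSE])
  mc <- rowMeans(cpm[, control, drop = FALSE])
  # difference of logs, not log of ratio: exactly antisymmetric under a
  # treated/control swap
  lfc <- log2(mt + pseudocount) - log2(mc + pseudocount)
  data.frame(gene_id = rownames(cpm),
             mean_cpm_control = unname(mc),
             mean_cpm_treated = unname(mt),
             log2fc = unname(lfc),
             upregulated = unname(lfc >= log2fc_threshold),
             stringsAsFactors = FALSE)
}

#' Genes called upregulated at a fold-change threshold
#'
#' Screening criterion (1): induction under the candidate substrate.
#'
#' @param fc fold-change table from [log2_fold_change()]
#' @param log2fc_threshold minimum log2 fold change (inclusive)
#' @return character vector of gene IDs with `log2fc >= threshold`
#' @export
call_upregulated <- function(fc, log2fc_threshold = 1) {
  assert_scalar_number(log2fc_threshold, "log2fc_threshold")
  fc$gene_id[fc$log2fc >= log2fc_threshold]
}
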