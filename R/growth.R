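#' Area under a growth curve by the trapezoidal rule
#'
#' Composite trapezoid over the observed time grid; no extrapolation or
#' baseline subtraction. Units: OD600 x hours.
#'
#' @param times strictly increasing time points (hours), length >= 2
#' @param od OD600 readings, same length as `times`
#' @return area (OD.h)
#' @export
auc_trapezoid <- function(times, od) {
  if (length(times) != length(od))
    stop_input("times and od must have the same length")
  if (length(times) < 2L)
    stop_input("need at least two time points for an AUC")
  if (any(diff(times) <= 0))
    stop_input("times must be strictly increasing")
  pracma::trapz(times, od)
}

#' Growth-inhibition index of one replicate
#'
#' `1 - auc / mean(control AUCs)`: 0 means control-like growth, 1 means no
#' growth at all. The alternative raw-ratio convention (`auc / mean control`)
#' is available via `variant = "ratio"`.
#'
#' @param auc_treated AUC of the treated replicate
#' @param control_aucs AUCs of the same strain's 0-dose replicates
#' @param variant `"one_minus_ratio"` (default) or `"ratio"`
#' @return the inhibition index
#' @export
inhibition_index <- function(auc_treated, control_aucs,
                             variant = c("one_minus_ratio", "ratio")) {
  variant <- match.arg(variant)
  ctrl <- mean(control_aucs)
  if (!is.finite(ctrl) || ctrl <= 0)
    stop_input("mean control AUC must be positive")
  ratio <- auc_treated / ctrl
  if (variant == "ratio") ratio else 1 - ratio
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value. Degenerate inputs (both samples constant) return
#' `t = 0, p = 1` when the means agree, and a `p = 0` sentinel with a
#' warning when they differ.
#'
#' @param x,y numeric samples, each of length >= 2
#' @return list: `t`, `df`, `p`
#' @export
welch_t_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop_input("each sample needs >= 2 values")
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, df = length(x) + length(y) - 2, p = 1))
    warning("both samples are constant with different means; p = 0 sentinel")
    return(list(t = sign(mean(x) - mean(y)) * Inf,
                df = length(x) + length(y) - 2, p = 0))
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment via [stats::p.adjust()]; input order is preserved.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`
#' @return adjusted p-values, same order
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop_input("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Dose-response growth analysis: AUCs, inhibition indices and tests
#'
#' For every (strain, dose, replicate) the trapezoidal AUC is computed; each
#' replicate's inhibition index is its AUC normalised by the mean 0-dose AUC
#' of the same strain. Every non-control dose is compared with the control
#' by Welch's t-test on the AUCs, and all dose-vs-control p-values across
#' strains form one Benjamini-Hochberg family.
#'
#' @param growth long-format data.frame (`strain_id, dose_uM, replicate,
#'   time_h, od600`), e.g. from [read_growth()] or [simulate_growth()]
#' @param control_dose the control dose (default 0 uM)
#' @param variant inhibition-index convention, see [inhibition_index()]
#' @param alpha significance level for the reported `significant` flag
#' @return list of two data.frames: `results` (strain, dose, replicate, auc,
#'   inhibition_index) and `tests` (strain, dose, t, df, p, p_adj,
#'   significant)
#' @export
growth_analysis <- function(growth, control_dose = 0,
                            variant = c("one_minus_ratio", "ratio"),
                            alpha = 0.05) {
  variant <- match.arg(variant)
  if (!control_dose %in% growth$dose_uM)
    stop_input("growth data contain no control dose (%g uM)", control_dose)
  grp <- interaction(growth$strain_id, growth$dose_uM, growth$replicate,
                     drop = TRUE)
  pieces <- split(growth, grp)
  results <- do.call(rbind, lapply(pieces, function(g) {
    g <- g[order(g$time_h), , drop = FALSE]
    data.frame(strain_id = g$strain_id[[1]], dose_uM = g$dose_uM[[1]],
               replicate = g$replicate[[1]],
               auc = auc_trapezoid(g$time_h, g$od600),
               stringsAsFactors = FALSE)
  }))
  rownames(results) <- NULL
  results <- results[order(results$strain_id, results$dose_uM,
                           results$replicate), , drop = FALSE]

  results$inhibition_index <- NA_real_
  tests <- list()
  for (sid in unique(results$strain_id)) {
    rows <- results$strain_id == sid
    ctrl_aucs <- results$auc[rows & results$dose_uM == control_dose]
    if (length(ctrl_aucs) < 2L)
      stop_input("strain %s has < 2 control replicates", sid)
    results$inhibition_index[rows] <- vapply(
      results$auc[rows], inhibition_index, numeric(1),
      control_aucs = ctrl_aucs, variant = variant)
    for (dose in setdiff(sort(unique(results$dose_uM[rows])), control_dose)) {
      w <- welch_t_test(results$auc[rows & results$dose_uM == dose], ctrl_aucs)
      tests[[length(tests) + 1L]] <- data.frame(
        strain_id = sid, dose_uM = dose,
        t = w$t, df = w$df, p = w$p, stringsAsFactors = FALSE)
    }
  }
  tests <- do.call(rbind, tests)
  tests$p_adj <- bh_adjust(tests$p)
  tests$significant <- tests$p_adj < alpha
  rownames(tests) <- NULL
  list(results = results, tests = tests)
}
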