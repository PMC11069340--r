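# Exact-mass annotation of catabolic intermediates: monoisotopic masses,
# deprotonated ([M-H]-) m/z, ppm matching and deuterium label shifts.

# monoisotopic atomic masses (Da); D = deuterium, distinct from H
ATOMIC_MASS <- c(C = 12, H = 1.00782503, D = 2.01410178, N = 14.00307401,
                 O = 15.99491462, S = 31.97207117, P = 30.97376200)

MASS_H_ATOM <- ATOMIC_MASS[["H"]]
MASS_ELECTRON <- 0.00054858
MASS_H_TO_D <- ATOMIC_MASS[["D"]] - ATOMIC_MASS[["H"]]  # 1.00627675

#' Parse a molecular formula string
#'
#' Accepts Hill-style element symbols, each followed by an optional count
#' (absent = 1); `D` is accepted as deuterium, distinct from `H`. Supported
#' elements: C, H, D, N, O, S, P.
#'
#' @param text formula string, e.g. `"C15H10O5"` or `"C10H6D4O3"`
#' @return named integer vector of element counts, in canonical Hill order
#'   (C, H, then alphabetical), class `mol_formula`
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || text == "")
    stop_input("formula must be a non-empty string")
  tokens <- regmatches(text, gregexpr("([A-Z][a-z]?)([0-9]*)", text))[[1]]
  if (paste(tokens, collapse = "") != text)
    stop_input("cannot parse formula '%s'", text)
  counts <- integer(0)
  for (tok in tokens) {
    el <- sub("[0-9]*$", "", tok)
    num <- sub("^[A-Za-z]+", "", tok)
    if (!el %in% names(ATOMIC_MASS))
      stop_input("unknown element '%s' in formula '%s'", el, text)
    n <- if (num == "") 1L else as.integer(num)
    if (n == 0L)
      stop_input("zero count for element '%s' in formula '%s'", el, text)
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + n
  }
  hill <- c(intersect(c("C", "H"), names(counts)),
            sort(setdiff(names(counts), c("C", "H"))))
  structure(counts[hill], class = "mol_formula")
}

#' Canonical Hill-order string of a formula
#'
#' @param formula a `mol_formula` (or named count vector)
#' @return character scalar, counts of 1 omitted
#' @export
format_formula <- function(formula) {
  paste0(names(formula),
         ifelse(unclass(formula) == 1L, "", unclass(formula)),
         collapse = "")
}

as_formula <- function(x) {
  if (inherits(x, "mol_formula")) x else parse_formula(x)
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum of element counts times most-abundant-isotope atomic masses
#' (C = 12 exactly on the unified scale).
#'
#' @param formula a `mol_formula` or formula string
#' @return mass in Da
#' @export
#' @examples
#' monoisotopic_mass("H2O")  # 18.0105646
monoisotopic_mass <- function(formula) {
  f <- as_formula(formula)
  sum(ATOMIC_MASS[names(f)] * unclass(f))
}

#' Theoretical deprotonated ([M-H]-) m/z
#'
#' Monoisotopic mass minus the mass of one hydrogen atom (1.00782503 Da).
#' By default no electron-mass correction is applied — the convention under
#' which the pathway intermediates take their conventional calculated
#' masses (e.g. C15H10O5 -> 269.0450). Setting
#' `electron_correction = TRUE` adds the electron mass of the anion's extra
#' electron (giving 269.0455 for the same formula).
#'
#' @param formula a `mol_formula` or formula string; must contain >= 1 H
#' @param electron_correction add the electron mass (default `FALSE`)
#' @param report round half-up to 4 decimals (display precision) instead of
#'   returning full precision
#' @return m/z in Thomson
#' @export
#' @examples
#' mz_deprotonated("C15H10O5", report = TRUE)  # 269.0450
mz_deprotonated <- function(formula, electron_correction = FALSE,
                            report = FALSE) {
  f <- as_formula(formula)
  if (!"H" %in% names(f) || f[["H"]] < 1L)
    stop_input("cannot deprotonate '%s': no hydrogen", format_formula(f))
  mz <- monoisotopic_mass(f) - MASS_H_ATOM +
    if (electron_correction) MASS_ELECTRON else 0
  if (report) round_half_up(mz, 4) else mz
}

#' Signed relative mass error in parts per million
#'
#' @param observed,theoretical m/z values; `theoretical` must be positive
#' @return `1e6 * (observed - theoretical) / theoretical`
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop_input("theoretical m/z must be positive")
  1e6 * (observed - theoretical) / theoretical
}

#' Match observed peaks to candidate formulas within a ppm tolerance
#'
#' Every (peak, formula) pair whose deprotonated theoretical m/z lies within
#' `tol_ppm` of the observed m/z is reported, sorted by absolute ppm error.
#' A peak may match several formulas; ambiguity is reported, not resolved.
#'
#' @param peaks data.frame with columns `rt_min, mz, intensity`
#' @param candidates character vector of formula strings (or list of
#'   `mol_formula`)
#' @param tol_ppm match tolerance in ppm (> 0)
#' @param electron_correction see [mz_deprotonated()]
#' @return data.frame: `rt_min, observed_mz, formula, theoretical_mz,
#'   ppm_error`
#' @export
annotate_peaks <- function(peaks, candidates, tol_ppm = 10,
                           electron_correction = FALSE) {
  assert_scalar_number(tol_ppm, "tol_ppm", lower = 1e-12)
  forms <- lapply(candidates, as_formula)
  labels <- vapply(forms, format_formula, character(1))
  theo <- vapply(forms, mz_deprotonated, numeric(1),
                 electron_correction = electron_correction)
  grid <- expand.grid(peak = seq_len(nrow(peaks)),
                      cand = seq_along(forms))
  err <- ppm_error(peaks$mz[grid$peak], theo[grid$cand])
  keep <- abs(err) <= tol_ppm
  out <- data.frame(
    rt_min = peaks$rt_min[grid$peak[keep]],
    observed_mz = peaks$mz[grid$peak[keep]],
    formula = labels[grid$cand[keep]],
    theoretical_mz = round_half_up(theo[grid$cand[keep]], 4),
    ppm_error = err[keep],
    stringsAsFactors = FALSE)
  out[order(abs(out$ppm_error)), , drop = FALSE]
}

#' Deuterium label substitution and its mass shift
#'
#' Replaces `n_deuterium` hydrogens by deuterium — the reasoning used to
#' show that labelled substrate positions are retained in a reaction
#' product: the product's m/z shifts by `n` nominal mass units
#' (n x 1.00627675 Da exactly).
#'
#' @param formula a `mol_formula` or formula string with >= `n_deuterium` H
#' @param n_deuterium number of H to replace (>= 0)
#' @return list: `formula` (labelled `mol_formula`), `mass_shift` (Da),
#'   `nominal_shift` (integer)
#' @export
label_shift <- function(formula, n_deuterium) {
  f <- as_formula(formula)
  assert_scalar_number(n_deuterium, "n_deuterium", lower = 0)
  n <- as.integer(n_deuterium)
  if (n > 0L) {
    if (!"H" %in% names(f) || f[["H"]] < n)
      stop_input("formula '%s' has fewer than %d hydrogens", format_formula(f), n)
    counts <- unclass(f)
    counts[["H"]] <- counts[["H"]] - n
    counts[["D"]] <- (if ("D" %in% names(counts)) counts[["D"]] else 0L) + n
    counts <- counts[counts > 0L]
    f <- parse_formula(paste0(names(counts), counts, collapse = ""))
  }
  list(formula = f, mass_shift = n * MASS_H_TO_D, nominal_shift = n)
}
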