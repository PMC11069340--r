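# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero at a fixed number of decimals
#'
#' Report-precision rounding used for m/z fields: 0.00005 rounds up, unlike
#' [base::round()]'s round-half-even. Only used for display/report values;
#' internal computation keeps full precision.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return numeric vector rounded half-up
#' @keywords internal
round_half_up <- function(x, digits = 4) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stop_input <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stop_input("'%s' must be a single number in [%s, %s]", name, lower, upper)
  invisible(x)
}

#' Write a data frame as a plain TSV
#'
#' @param df data frame
#' @param path output path
#' @return `path`, invisibly
#' @keywords internal
write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_plain <- function(path, ...) {
  if (!file.exists(path)) stop_input("input file not found: %s", path)
  utils::read.delim(path, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

PROTEIN_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")

assert_protein <- function(seq, name = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || nchar(seq) == 0L)
    stop_input("%s must be a non-empty protein string", name)
  bad <- setdiff(unique(strsplit(seq, "")[[1]]), PROTEIN_ALPHABET)
  if (length(bad))
    stop_input("%s contains illegal character(s): %s", name,
               paste(bad, collapse = ", "))
  invisible(seq)
}
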