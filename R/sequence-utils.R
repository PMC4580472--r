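# Internal sequence helpers. All pipeline code works in uppercase T-space
# (U is normalized to T on input and restored only in human-facing reports).

#' Normalize a nucleotide string to uppercase DNA (T-space)
#'
#' @param x character vector of nucleotide sequences (RNA or DNA, any case).
#' @return character vector over \{A,C,G,T,N\}.
#' @keywords internal
#' @noRd
norm_seq <- function(x) {
  chartr("U", "T", toupper(x))
}

#' @noRd
to_rna <- function(x) {
  chartr("T", "U", toupper(x))
}

#' Reverse complement in T-space
#' @noRd
revcomp <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

#' @noRd
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Random DNA string over a given alphabet (uses the current RNG stream)
#' @noRd
random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

#' Percentage of a total, rounded for report tables
#'
#' The report convention throughout: `100 * x / total`, rounded to
#' `digits` decimal places. Used for all read-accounting ratios.
#'
#' @param x numerator count(s).
#' @param total denominator count (must be > 0).
#' @param digits decimal places (default 2, matching the published tables).
#' @return numeric vector of percentages.
#' @export
#' @examples
#' pct(16527710, 38092056)  # 43.39
pct <- function(x, total, digits = 2) {
  stopifnot(is.numeric(x), is.numeric(total), total > 0)
  round(100 * x / total, digits)
}
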