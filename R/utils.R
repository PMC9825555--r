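#' Round half away from zero
#'
#' Fixed-precision rounding where a trailing 5 always rounds up (the
#' convention used when printing percentage tables), unlike [base::round()]
#' which rounds half to even.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return numeric vector rounded half-up.
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage at printed precision
#'
#' Computes `100 * numerator / denominator` rounded half-up to `decimals`
#' places, matching how percentage rows are printed in annotation-database
#' summary tables.
#'
#' @param numerator,denominator non-negative integers; `denominator` > 0.
#' @param decimals integer number of decimal places (default 2).
#' @return a numeric scalar in percent.
#' @examples
#' percentage(4183, 5111, 1) # 81.8
#' percentage(41447, 168906, 2) # 24.54
#' @export
percentage <- function(numerator, denominator, decimals = 2) {
  stopifnot(is.numeric(numerator), is.numeric(denominator),
            length(numerator) == length(denominator) || length(denominator) == 1)
  if (any(denominator == 0)) {
    stop("percentage(): denominator must be non-zero", call. = FALSE)
  }
  round_half_up(100 * numerator / denominator, decimals)
}

# the five signature-relevant gene classes
SIGNATURE_CLASSES <- c("CAZyme", "TC", "TF", "STP")
GENE_CLASSES <- c(SIGNATURE_CLASSES, "Other")

# the three CAZyme-calling tools whose agreement is counted
CAZYME_TOOLS <- c("hmm", "alignment", "kmer")

`%||%` <- function(a, b) if (is.null(a)) b else a

# normalized substrate comparison: case-fold + trim, no synonym merging
norm_substrate <- function(x) tolower(trimws(x))

is_ecami_subfamily <- function(x) grepl("_e[0-9]+$", x)

# family prefix of an eCAMI subfamily name, e.g. "GH130_e13" -> "GH130"
ecami_family_prefix <- function(x) sub("_e[0-9]+$", "", x)
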