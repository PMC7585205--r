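#' Percentage with half-up rounding
#'
#' Computes `100 * count / total` rounded half-up to a fixed number of
#' decimals. Report tables round half-up (so 77.105 prints as 77.11), unlike
#' [base::round()], which rounds half to even.
#'
#' @param count Numerator count (vectorised).
#' @param total Denominator count.
#' @param digits Decimal places to keep (default 2).
#' @return Numeric vector of percentages.
#' @examples
#' percentage(2814161, 3649775) # 77.11
#' @export
percentage <- function(count, total, digits = 2) {
  stopifnot(is.numeric(count), is.numeric(total), total > 0)
  round_half_up(100 * count / total, digits)
}

#' Round half away from zero
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded values; exact .5 ties go away from zero.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Run code with a locally-set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Collapse a character vector to "a, b, c" for error messages.
comma <- function(x, max = 10) {
  x <- as.character(x)
  if (length(x) > max) x <- c(x[seq_len(max)], "...")
  paste(x, collapse = ", ")
}

stop2 <- function(...) stop(..., call. = FALSE)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Reverse-complement for plain character sequences.
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
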