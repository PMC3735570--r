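# Shared helpers: sequence containers and the printed-percentage convention.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Percentage with half-up rounding
#'
#' The reporting convention used by every summary table in the package:
#' `100 * n / d`, rounded half-up to `digits` decimals (so 45.9155 prints as
#' 45.92, and 93.3333 at one decimal prints as 93.3).
#'
#' @param n Numerator count(s).
#' @param d Denominator count(s); must be non-zero.
#' @param digits Decimal places (default 2).
#' @return Numeric percentage(s).
#' @examples
#' pct(24, 355)      # 6.76
#' pct(70, 75, 1)    # 93.3
#' @export
pct <- function(n, d, digits = 2) {
  if (any(d == 0)) stop("percentage denominator is zero")
  x <- 100 * n / d
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Normalize a protein set to a named character vector
#'
#' Accepts a named character vector or a [Biostrings::AAStringSet] and
#' returns upper-case sequences keyed by gene id. Gap characters are
#' rejected: these are unaligned protein records.
#'
#' @param x Named character vector or `AAStringSet`.
#' @return Named character vector of sequences.
#' @export
as_protein_set <- function(x) {
  if (methods::is(x, "XStringSet")) x <- as.character(x)
  if (!is.character(x)) stop("proteins must be a named character vector or an AAStringSet")
  if (is.null(names(x)) || any(!nzchar(names(x)))) stop("every protein needs a gene id name")
  if (anyDuplicated(names(x))) stop("duplicate gene ids in protein set")
  x <- toupper(x)
  if (any(!nzchar(x))) stop("empty protein sequence")
  if (any(grepl("-", x, fixed = TRUE))) stop("protein sequences must not contain gap characters")
  x
}

.seq_chars <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1]]

# ORF completeness on a translated model: initial Met and no internal stop.
# A single trailing '*' (annotation style) is tolerated.
orf_complete <- function(sequence) {
  if (!nzchar(sequence)) return(FALSE)
  body <- sub("\\*$", "", sequence)
  startsWith(body, "M") && !grepl("*", body, fixed = TRUE)
}

# lexicographic comparison of two numeric vectors (used for tie-breaking)
.lex_less <- function(a, b) {
  n <- min(length(a), length(b))
  for (i in seq_len(n)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}
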