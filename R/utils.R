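#' @importFrom stats rbinom rpois rnorm rlnorm runif setNames pchisq cor
#'   predict loess lm quantile
#' @importFrom utils head tail write.table read.table modifyList combn
#' @import data.table
NULL

.datatable.aware <- TRUE

utils::globalVariables(c(
  ".", ".N", "ref_base", "contig", "pos", "base", "n", "alt_n", "alt",
  "n_seg", "tag", "tot", "N"
))

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement DNA strings
#'
#' Vectorised reverse complement over plain character strings
#' (uppercase A/C/G/T).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Flat Phred+33 quality string for a given substitution error rate.
## Rate 0 is encoded at the conventional Q40 cap.
phred_char <- function(error_rate) {
  q <- if (error_rate <= 0) 40L else min(40L, round(-10 * log10(error_rate)))
  intToUtf8(33L + q)
}

qual_string <- function(n, error_rate) {
  strrep(phred_char(error_rate), n)
}

## Derive reproducible per-stage seeds from one master seed, keeping the
## result inside 32-bit integer range.
derive_seed <- function(seed, stage) {
  as.integer((as.double(seed) * 48271 + stage * 1299709) %% 2147483647)
}

## Per-character views of equal-length strings as integer code matrices.
str_to_int <- function(x) utf8ToInt(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
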