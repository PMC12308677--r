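#' @importFrom stats runif setNames na.omit
#' @importFrom utils read.table write.table
#' @importFrom methods is
NULL

DNA_BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse-complement a DNA string
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Random DNA sequence
#'
#' Uniform A/C/G/T sequence of the given length. Caller controls the RNG
#' state (see [withr::with_seed()]).
#'
#' @param n sequence length in bases.
#' @return a single character string.
#' @export
random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

random_protein <- function(n, alphabet) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

assert_dna <- function(x, what = "sequence", allow_n = FALSE) {
  pat <- if (allow_n) "[^ACGTN]" else "[^ACGT]"
  bad <- grepl(pat, x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside A/C/G/T%s (first offender: %s)",
                 what, if (allow_n) "/N" else "", x[bad][1]), call. = FALSE)
  }
  invisible(x)
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# 0-based half-open substring
substr0 <- function(x, start, end) substr(x, start + 1L, end)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)
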