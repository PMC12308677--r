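#' Ser/Tyr/Pro composition of a protein
#'
#' Percentages are computed over the standard 20 amino-acid residues; X and
#' other non-standard letters are excluded from the denominator so that
#' partially determined sequences are not deflated.
#'
#' @param sequence single protein sequence (uppercase one-letter codes).
#' @return named numeric vector c(S=, Y=, P=) of percentages (0-100).
#' @export
aa_composition <- function(sequence) {
  stopifnot(nzchar(sequence))
  chars <- seq_chars(sequence)
  denom <- sum(chars %in% AA_ALPHABET)
  if (denom == 0) return(c(S = NA_real_, Y = NA_real_, P = NA_real_))
  100 * c(S = sum(chars == "S"), Y = sum(chars == "Y"),
          P = sum(chars == "P")) / denom
}

#' Find tandem SP(n)Y motifs in a protein
#'
#' A motif is a serine followed by k consecutive prolines (n_min <= k <=
#' n_max) followed by a tyrosine — the tandem repeat building block of
#' extensins. Matches are maximal in k, non-overlapping, and scanned left to
#' right. Coverage is the fraction of the full sequence length inside motif
#' spans.
#'
#' @param sequence protein sequence.
#' @param n_min minimum proline run (default 2, the classical extensin
#'   Ser-Pro(>=2) repeat).
#' @param n_max maximum proline run (default unbounded).
#' @return list(spans = data.frame(start, end) 0-based half-open,
#'   coverage = numeric).
#' @export
find_spny_motifs <- function(sequence, n_min = 2L, n_max = Inf) {
  stopifnot(n_min >= 1)
  upper <- if (is.finite(n_max)) as.character(as.integer(n_max)) else ""
  pat <- sprintf("SP{%d,%s}Y", as.integer(n_min), upper)
  m <- gregexpr(pat, sequence, perl = TRUE)[[1]]
  if (m[1] == -1) {
    spans <- data.frame(start = integer(0), end = integer(0))
  } else {
    spans <- data.frame(start = as.integer(m) - 1L,
                        end = as.integer(m) + attr(m, "match.length") - 1L)
  }
  list(spans = spans,
       coverage = sum(spans$end - spans$start) / nchar(sequence))
}

#' Rank a proteome by Ser/Tyr co-enrichment
#'
#' Scores each protein by the geometric mean of the within-proteome
#' percentile ranks of its Ser and Tyr percentages (Pro content is carried
#' as an annotation); ties are broken by id, so the ranking is
#' deterministic and invariant to input order.
#'
#' @param proteins data.frame (id, seq).
#' @param n_min,n_max SP(n)Y grammar bounds passed to
#'   [find_spny_motifs()].
#' @return data.frame (id, length, pct_S, pct_Y, pct_P, n_motifs,
#'   motif_coverage, score, rank) ordered by rank; the score definition is
#'   recorded in the `score` attribute.
#' @export
rank_coenrichment <- function(proteins, n_min = 2L, n_max = Inf) {
  stopifnot(nrow(proteins) >= 1)
  comp <- t(vapply(proteins$seq, aa_composition, c(S = 0, Y = 0, P = 0)))
  motifs <- lapply(proteins$seq, find_spny_motifs, n_min = n_min,
                   n_max = n_max)
  n <- nrow(proteins)
  pr <- function(x) rank(x, ties.method = "average") / n
  score <- sqrt(pr(comp[, "S"]) * pr(comp[, "Y"]))
  out <- data.frame(
    id = proteins$id,
    length = nchar(proteins$seq),
    pct_S = comp[, "S"], pct_Y = comp[, "Y"], pct_P = comp[, "P"],
    n_motifs = vapply(motifs, function(m) nrow(m$spans), 1L),
    motif_coverage = vapply(motifs, `[[`, 1.0, "coverage"),
    score = score, stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$score, out$id), ]
  out$rank <- seq_len(n)
  rownames(out) <- NULL
  attr(out, "score") <-
    "geometric mean of within-proteome percentile ranks of %S and %Y"
  attr(out, "n_min") <- n_min
  attr(out, "n_max") <- n_max
  out
}
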