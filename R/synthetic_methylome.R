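#' Plant a ground-truth methylome on a reference
#'
#' Every cytosine on both strands is assigned its context (via
#' [classify_context()]) and the planted methylation probability for that
#' context; the assignment is deterministic — each unambiguous cytosine gets
#' the context level itself, so the per-context mean of planted
#' probabilities equals the level exactly. Ambiguous-context cytosines get
#' probability 0.
#'
#' @param reference reference sequence (character).
#' @param level_by_context named numeric vector or list with names exactly
#'   c("CG", "CHG", "CHH"), values in [0,1].
#' @param seed kept for generator API symmetry; the assignment is
#'   deterministic and does not consume randomness.
#' @return data.frame (pos, strand, context, prob) — one row per reference
#'   cytosine per strand; empty when the reference has no cytosines.
#' @export
generate_methylome <- function(reference, level_by_context, seed = NULL) {
  lv <- unlist(level_by_context)
  if (!setequal(names(lv), c("CG", "CHG", "CHH"))) {
    stop("level_by_context must have names CG, CHG, CHH and no others")
  }
  stopifnot(all(lv >= 0 & lv <= 1))
  cyt <- cytosine_positions(reference)
  if (nrow(cyt) == 0) {
    return(data.frame(pos = integer(0), strand = character(0),
                      context = character(0), prob = numeric(0)))
  }
  cyt$context <- classify_context(reference, cyt$pos, cyt$strand)
  cyt$prob <- ifelse(cyt$context == "ambiguous", 0,
                     as.numeric(lv[cyt$context]))
  cyt <- cyt[order(cyt$pos, cyt$strand), ]
  rownames(cyt) <- NULL
  cyt
}

#' Simulate bisulfite-converted sequencing reads
#'
#' Reads are drawn uniformly from both strands of the reference. At each
#' covered cytosine of the read's origin strand, the methylation state is
#' drawn from the planted probability: methylated cytosines survive as C in
#' the read; unmethylated ones are converted to T except with probability
#' `conversion_failure_rate` (incomplete conversion). Independent
#' substitution errors are then applied at `error_rate` per base. Reads are
#' returned as sequenced (minus-strand reads are the reverse complement of
#' the genomic slice), with their true origin recorded, so downstream calls
#' can run in truth-placement mode without an aligner.
#'
#' @param reference reference sequence (A/C/G/T, optionally N — e.g. a
#'   degenerate consensus; N bases carry no methylation state).
#' @param methylome planted methylome from [generate_methylome()].
#' @param coverage mean fold-coverage (> 0).
#' @param read_length read length (<= reference length).
#' @param conversion_failure_rate probability an unmethylated C escapes
#'   conversion.
#' @param error_rate per-base substitution error probability.
#' @param seed integer RNG seed.
#' @return list(reads, truth, params): `reads` is a data.frame (id, seq,
#'   start, strand) with 0-based starts; `truth` records the simulated
#'   methylation state of every covered cytosine (read_id, pos, strand,
#'   methylated).
#' @export
generate_bisulfite_reads <- function(reference, methylome, coverage,
                                     read_length,
                                     conversion_failure_rate = 0,
                                     error_rate = 0, seed = 1L) {
  assert_dna(reference, allow_n = TRUE)
  L <- nchar(reference)
  stopifnot(coverage > 0, read_length >= 1, read_length <= L,
            conversion_failure_rate >= 0, conversion_failure_rate <= 1,
            error_rate >= 0, error_rate <= 1)
  n_reads <- max(1L, as.integer(round(coverage * L / read_length)))
  prob_key <- setNames(methylome$prob,
                       paste(methylome$pos, methylome$strand))
  withr::with_seed(seed, {
    starts <- sample.int(L - read_length + 1L, n_reads, replace = TRUE) - 1L
    strands <- sample(c("+", "-"), n_reads, replace = TRUE)
    seqs <- character(n_reads)
    truth <- vector("list", n_reads)
    for (i in seq_len(n_reads)) {
      s <- starts[i]
      slice <- substr0(reference, s, s + read_length)
      rch <- seq_chars(if (strands[i] == "-") revcomp(slice) else slice)
      # genomic positions (0-based) of this strand's cytosines in the read
      cyt_idx <- which(rch == "C")            # read-coordinate, 1-based
      if (length(cyt_idx) > 0) {
        gpos <- if (strands[i] == "+") s + cyt_idx - 1L
                else s + read_length - cyt_idx
        p <- prob_key[paste(gpos, strands[i])]
        p[is.na(p)] <- 0
        meth <- runif(length(p)) < p
        convert <- !meth & (runif(length(p)) >= conversion_failure_rate)
        rch[cyt_idx[convert]] <- "T"
        truth[[i]] <- data.frame(read_id = i, pos = gpos,
                                 strand = strands[i], methylated = meth,
                                 stringsAsFactors = FALSE)
      }
      if (error_rate > 0) {
        err <- which(runif(read_length) < error_rate)
        for (j in err) {
          rch[j] <- sample(setdiff(DNA_BASES, rch[j]), 1)
        }
      }
      seqs[i] <- paste(rch, collapse = "")
    }
    truth <- truth[!vapply(truth, is.null, TRUE)]
    list(
      reads = data.frame(id = sprintf("read%06d", seq_len(n_reads)),
                         seq = seqs, start = starts, strand = strands,
                         stringsAsFactors = FALSE),
      truth = if (length(truth) > 0) do.call(rbind, truth) else
        data.frame(read_id = integer(0), pos = integer(0),
                   strand = character(0), methylated = logical(0)),
      params = list(coverage = coverage, read_length = read_length,
                    conversion_failure_rate = conversion_failure_rate,
                    error_rate = error_rate, seed = seed))
  })
}

#' Write simulated reads as FASTQ
#'
#' @param reads data.frame (id, seq) from [generate_bisulfite_reads()].
#' @param path output FASTQ path (uncompressed).
#' @export
write_fastq <- function(reads, path) {
  ss <- Biostrings::DNAStringSet(setNames(reads$seq, reads$id))
  quals <- Biostrings::BStringSet(vapply(nchar(reads$seq),
                                         function(n) strrep("I", n), ""))
  Biostrings::writeXStringSet(ss, path, format = "fastq", qualities = quals)
}
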