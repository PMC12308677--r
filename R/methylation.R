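#' Classify the methylation context of cytosines
#'
#' Plant bisulfite analyses distinguish three cytosine contexts by the two
#' bases downstream of the cytosine on its own strand: CG (next base G),
#' CHG (next base not G, the one after G) and CHH (neither of the next two
#' bases G), with H = A, C or T. A context is `ambiguous` when a needed base
#' is N (e.g. on a degenerate consensus reference) or lies beyond the
#' sequence end.
#'
#' @param reference reference sequence (single character string; may contain
#'   N).
#' @param pos integer vector of 0-based positions; the base at each
#'   (position, strand) must be a cytosine on that strand (C on `+`, G on
#'   `-`).
#' @param strand character vector ("+"/"-"), recycled against `pos`.
#' @return character vector in {"CG","CHG","CHH","ambiguous"}.
#' @export
classify_context <- function(reference, pos, strand = "+") {
  chars <- seq_chars(reference)
  n <- length(chars)
  pos <- as.integer(pos)
  strand <- rep_len(strand, length(pos))
  if (length(pos) == 0) return(character(0))
  base_at <- function(p) {
    out <- rep(NA_character_, length(p))
    ok <- p >= 0 & p < n
    out[ok] <- chars[p[ok] + 1L]
    out
  }
  here <- base_at(pos)
  want <- ifelse(strand == "+", "C", "G")
  if (any(is.na(here)) || any(here != want)) {
    bad <- which(is.na(here) | here != want)[1]
    stop(sprintf("position %d (%s strand) is not a cytosine on that strand",
                 pos[bad], strand[bad]))
  }
  step <- ifelse(strand == "+", 1L, -1L)
  n1 <- base_at(pos + step)
  n2 <- base_at(pos + 2L * step)
  minus <- strand == "-"
  n1[minus] <- unname(COMPLEMENT[n1[minus]])
  n2[minus] <- unname(COMPLEMENT[n2[minus]])
  valid <- function(b) !is.na(b) & b %in% DNA_BASES
  out <- rep("ambiguous", length(pos))
  cg <- valid(n1) & n1 == "G"
  out[cg] <- "CG"
  rest <- valid(n1) & n1 != "G"
  chg <- rest & valid(n2) & n2 == "G"
  chh <- rest & valid(n2) & n2 != "G"
  out[chg] <- "CHG"
  out[chh] <- "CHH"
  out
}

# all cytosine positions (0-based) on both strands of a reference
cytosine_positions <- function(reference) {
  chars <- seq_chars(reference)
  data.frame(
    pos = c(which(chars == "C") - 1L, which(chars == "G") - 1L),
    strand = rep(c("+", "-"), c(sum(chars == "C"), sum(chars == "G"))),
    stringsAsFactors = FALSE)
}

#' Call a per-cytosine methylome from placed bisulfite reads
#'
#' Truth-placement mode: each read carries its origin position and strand.
#' At every reference cytosine covered by a read of the same strand, a read
#' base C counts as a methylated call and T as an unmethylated call (reads
#' are stored as sequenced, i.e. in their own strand's orientation); any
#' other base is ignored as a sequencing error. Contexts come from
#' [classify_context()].
#'
#' @param reads data.frame (id, seq, start, strand) as produced by
#'   [generate_bisulfite_reads()], or with placements from [place_reads()].
#' @param reference reference sequence (character).
#' @return a methylome track data.frame: pos (0-based), strand, context,
#'   meth, total — one row per covered (position, strand).
#' @export
call_methylome <- function(reads, reference) {
  L <- nchar(reference)
  chars <- seq_chars(reference)
  meth_p <- integer(L); tot_p <- integer(L)
  meth_m <- integer(L); tot_m <- integer(L)
  refC <- which(chars == "C")   # 1-based
  refG <- which(chars == "G")
  if (nrow(reads) > 0) {
    for (i in seq_len(nrow(reads))) {
      s <- reads$start[i]            # 0-based
      rl <- nchar(reads$seq[i])
      rchars <- seq_chars(reads$seq[i])
      if (reads$strand[i] == "+") {
        hits <- refC[refC > s & refC <= s + rl]       # 1-based ref positions
        if (length(hits) == 0) next
        b <- rchars[hits - s]
        meth_p[hits] <- meth_p[hits] + (b == "C")
        tot_p[hits] <- tot_p[hits] + (b %in% c("C", "T"))
      } else {
        hits <- refG[refG > s & refG <= s + rl]
        if (length(hits) == 0) next
        b <- rchars[s + rl - hits + 1L]               # read is revcomp of slice
        meth_m[hits] <- meth_m[hits] + (b == "C")
        tot_m[hits] <- tot_m[hits] + (b %in% c("C", "T"))
      }
    }
  }
  rows <- list()
  covered_p <- which(tot_p > 0)
  covered_m <- which(tot_m > 0)
  if (length(covered_p) > 0) {
    rows[[1]] <- data.frame(pos = covered_p - 1L, strand = "+",
                            meth = meth_p[covered_p], total = tot_p[covered_p],
                            stringsAsFactors = FALSE)
  }
  if (length(covered_m) > 0) {
    rows[[2]] <- data.frame(pos = covered_m - 1L, strand = "-",
                            meth = meth_m[covered_m], total = tot_m[covered_m],
                            stringsAsFactors = FALSE)
  }
  track <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(pos = integer(0), strand = character(0),
               meth = integer(0), total = integer(0))
  track$context <- if (nrow(track) > 0)
    classify_context(reference, track$pos, track$strand) else character(0)
  track[, c("pos", "strand", "context", "meth", "total")]
}

#' Read a per-cytosine CX-style call table
#'
#' Expected columns: chrom, pos (0-based), strand, context, meth_count,
#' total_count (tab-separated, with header).
#'
#' @param path TSV path.
#' @return methylome track data.frame (pos, strand, context, meth, total)
#'   with a `chrom` column retained.
#' @export
read_cx_table <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  needed <- c("chrom", "pos", "strand", "context", "meth_count", "total_count")
  stopifnot(all(needed %in% names(d)))
  if (any(d$meth_count > d$total_count)) {
    stop("meth_count exceeds total_count in CX table")
  }
  data.frame(chrom = d$chrom, pos = d$pos, strand = d$strand,
             context = d$context, meth = d$meth_count, total = d$total_count,
             stringsAsFactors = FALSE)
}

#' Write a methylome track as a CX-style TSV
#'
#' @param track methylome track (from [call_methylome()]).
#' @param path output TSV path.
#' @param chrom sequence name to record.
#' @export
write_cx_table <- function(track, path, chrom = "region") {
  out <- data.frame(chrom = chrom, pos = track$pos, strand = track$strand,
                    context = track$context, meth_count = track$meth,
                    total_count = track$total)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Naive bisulfite-aware read placement
#'
#' Exact-match placement for simulated reads against a (possibly degenerate)
#' reference: a reference N matches any read base; on the plus strand a
#' reference C additionally matches a read T (bisulfite conversion); on the
#' minus strand a reference G matches a reverse-complemented-read A. Reads
#' with zero or multiple candidate placements are dropped. Intended for
#' small end-to-end runs, not as an aligner.
#'
#' @param read_seqs character vector of read sequences (as sequenced).
#' @param reference reference sequence (may contain N).
#' @return data.frame (id, seq, start, strand) of uniquely placed reads.
#' @export
place_reads <- function(read_seqs, reference) {
  L <- nchar(reference)
  chars <- seq_chars(reference)
  match_at <- function(rch, offset, strand) {
    # offset: 0-based; rch: read chars in plus-strand orientation
    ref <- chars[(offset + 1L):(offset + length(rch))]
    if (strand == "+") {
      all(ref == "N" | ref == rch | (ref == "C" & rch == "T"))
    } else {
      all(ref == "N" | ref == rch | (ref == "G" & rch == "A"))
    }
  }
  out <- list()
  for (i in seq_along(read_seqs)) {
    rl <- nchar(read_seqs[i])
    if (rl > L) next
    fw <- seq_chars(read_seqs[i])
    rv <- seq_chars(revcomp(read_seqs[i]))
    cands <- list()
    for (off in 0:(L - rl)) {
      if (match_at(fw, off, "+")) cands[[length(cands) + 1L]] <- c(off, 1L)
      if (match_at(rv, off, "-")) cands[[length(cands) + 1L]] <- c(off, 2L)
    }
    if (length(cands) == 1) {
      out[[length(out) + 1L]] <- data.frame(
        id = sprintf("read%06d", i), seq = read_seqs[i],
        start = cands[[1]][1], strand = c("+", "-")[cands[[1]][2]],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(id = character(0), seq = character(0),
                      start = integer(0), strand = character(0)))
  }
  do.call(rbind, out)
}

#' Bin methylation ratios along a feature
#'
#' Tiles the feature with fixed-width bins anchored at its 5' end on the
#' given strand (the last bin may be partial) and reports a call-weighted
#' methylation ratio per (bin, context), pooling both strands within a bin.
#'
#' @param track methylome track (pos, strand, context, meth, total).
#' @param feature numeric length-2 vector c(start, end), 0-based half-open.
#' @param b bin width in bases (default 20).
#' @param strand feature strand; for "-" bins are anchored at the feature's
#'   right edge.
#' @return data.frame (bin, bin_start, bin_end, context, n_sites, n_calls,
#'   ratio); ratio is NA when a (bin, context) has zero calls. Only
#'   (bin, context) combinations with at least one site are listed.
#' @export
bin_methylation <- function(track, feature, b = 20L, strand = "+") {
  stopifnot(b >= 1, length(feature) == 2, feature[2] > feature[1])
  fs <- feature[1]; fe <- feature[2]
  keep <- track$pos >= fs & track$pos < fe
  t2 <- track[keep, , drop = FALSE]
  if (nrow(t2) == 0) {
    out <- data.frame(bin = integer(0), bin_start = integer(0),
                      bin_end = integer(0), context = character(0),
                      n_sites = integer(0), n_calls = integer(0),
                      ratio = numeric(0), stringsAsFactors = FALSE)
    attr(out, "bin_width") <- b
    attr(out, "n_bins") <- ceiling((fe - fs) / b)
    return(out)
  }
  if (strand == "+") {
    bin <- (t2$pos - fs) %/% b
  } else {
    bin <- (fe - 1L - t2$pos) %/% b
  }
  n_bins <- ceiling((fe - fs) / b)
  key <- paste(bin, t2$context, sep = "\r")
  agg_m <- tapply(t2$meth, key, sum)
  agg_t <- tapply(t2$total, key, sum)
  agg_n <- tapply(t2$meth, key, length)
  parts <- strsplit(names(agg_m), "\r", fixed = TRUE)
  bins <- as.integer(vapply(parts, `[`, "", 1))
  ctx <- vapply(parts, `[`, "", 2)
  if (strand == "+") {
    bs <- fs + bins * b
    be <- pmin(bs + b, fe)
  } else {
    be <- fe - bins * b
    bs <- pmax(be - b, fs)
  }
  out <- data.frame(bin = bins, bin_start = bs, bin_end = be, context = ctx,
                    n_sites = as.integer(agg_n), n_calls = as.integer(agg_t),
                    ratio = ifelse(agg_t > 0, agg_m / agg_t, NA_real_),
                    stringsAsFactors = FALSE)
  out <- out[order(out$bin, out$context), ]
  rownames(out) <- NULL
  attr(out, "bin_width") <- b
  attr(out, "n_bins") <- n_bins
  out
}

# methylation-sensitive restriction enzymes used as context probes:
# recognition pattern and the 0-based offset of the diagnostic
# (methyl-sensitive) cytosine within the site, on the plus strand
MSRE_TABLE <- data.frame(
  enzyme = c("Bsp119I", "MspI", "HpyF3I"),
  pattern = c("TTCGAA", "CCGG", "CTNAG"),
  diag_offset = c(2L, 0L, 0L),
  stringsAsFactors = FALSE)

#' Find methylation-sensitive restriction enzyme (MSRE) sites
#'
#' Scans the plus strand for the recognition sites of Bsp119I (TTCGAA, CG
#' probe), MspI (CCGG, CHG probe at the outer C) and HpyF3I (CTNAG, CHH
#' probe; N = any base). All three patterns are palindromic, so plus-strand
#' scanning finds every site. The diagnostic cytosine's context is computed
#' from the actual sequence — e.g. a HpyF3I site CTGAG has a CHG diagnostic
#' cytosine, not CHH.
#'
#' @param sequence DNA sequence (A/C/G/T).
#' @param enzymes subset of c("Bsp119I", "MspI", "HpyF3I").
#' @return data.frame (enzyme, start, end, diag_pos, diag_strand,
#'   diag_context), coordinates 0-based half-open.
#' @export
find_msre_sites <- function(sequence,
                            enzymes = c("Bsp119I", "MspI", "HpyF3I")) {
  assert_dna(sequence)
  enzymes <- match.arg(enzymes, MSRE_TABLE$enzyme, several.ok = TRUE)
  subj <- Biostrings::DNAString(sequence)
  out <- list()
  for (e in enzymes) {
    row <- MSRE_TABLE[MSRE_TABLE$enzyme == e, ]
    m <- Biostrings::matchPattern(row$pattern, subj, fixed = FALSE)
    if (length(m) == 0) next
    st <- Biostrings::start(m) - 1L
    out[[e]] <- data.frame(
      enzyme = e, start = st, end = st + nchar(row$pattern),
      diag_pos = st + row$diag_offset, diag_strand = "+",
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(enzyme = character(0), start = integer(0),
                      end = integer(0), diag_pos = integer(0),
                      diag_strand = character(0), diag_context = character(0)))
  }
  sites <- do.call(rbind, out)
  sites <- sites[order(sites$start, sites$enzyme), ]
  rownames(sites) <- NULL
  sites$diag_context <- classify_context(sequence, sites$diag_pos,
                                         sites$diag_strand)
  sites
}

#' In-silico chop-PCR digestion model
#'
#' A chop-PCR template amplifies only if it is uncut at every diagnostic
#' MSRE site within the amplicon. Methylation protects a site from cutting:
#' site i with methylation fraction m_i is cut with probability
#' (1 - m_i) * delta, independently across sites. The mock (no-enzyme)
#' control is 1 by definition, so the returned fraction is already
#' mock-normalized. The analytic amplifiable fraction is
#' prod_i (1 - (1 - m_i) * delta); an optional Monte-Carlo mode simulates
#' `n_molecules` templates and must converge to the analytic value.
#'
#' @param m numeric vector of per-site methylation fractions in [0,1]
#'   (length 0 means no diagnostic site in the amplicon).
#' @param delta digestion completeness in [0,1]; 1 = complete digestion.
#' @param n_molecules if non-NULL, also run a Monte-Carlo simulation over
#'   this many template molecules.
#' @param seed optional seed for the Monte-Carlo mode.
#' @return list(analytic, monte_carlo) — monte_carlo is NA unless requested.
#' @export
simulate_chop_pcr <- function(m, delta = 1.0, n_molecules = NULL,
                              seed = NULL) {
  stopifnot(all(m >= 0 & m <= 1), delta >= 0, delta <= 1)
  analytic <- prod(1 - (1 - m) * delta)   # prod(numeric(0)) == 1: mock case
  mc <- NA_real_
  if (!is.null(n_molecules)) {
    run <- function() {
      if (length(m) == 0) return(1)
      cut_any <- rep(FALSE, n_molecules)
      for (mi in m) {
        cut_any <- cut_any | (runif(n_molecules) < (1 - mi) * delta)
      }
      mean(!cut_any)
    }
    mc <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  }
  list(analytic = analytic, monte_carlo = mc)
}

#' Compare binned methylation between two conditions
#'
#' Descriptive per-(bin, context) ratio differences plus a pooled
#' per-context difference computed from summed calls; no hypothesis tests.
#'
#' @param binned_a,binned_b outputs of [bin_methylation()] over the same
#'   feature and bin width (condition B minus condition A).
#' @return list(per_bin, per_context) of data.frames with `delta` columns.
#' @export
compare_conditions <- function(binned_a, binned_b) {
  key <- c("bin", "bin_start", "bin_end", "context")
  m <- merge(binned_a, binned_b, by = key, suffixes = c("_a", "_b"),
             all = TRUE)
  m <- m[order(m$bin, m$context), ]
  rownames(m) <- NULL
  m$delta <- m$ratio_b - m$ratio_a
  pool <- function(d, suf) {
    meth <- tapply(d[[paste0("ratio", suf)]] * d[[paste0("n_calls", suf)]],
                   d$context, sum, na.rm = TRUE)
    tot <- tapply(d[[paste0("n_calls", suf)]], d$context, sum, na.rm = TRUE)
    meth / tot
  }
  ra <- pool(m, "_a"); rb <- pool(m, "_b")
  ctx <- sort(unique(m$context))
  per_context <- data.frame(context = ctx,
                            ratio_a = as.numeric(ra[ctx]),
                            ratio_b = as.numeric(rb[ctx]),
                            stringsAsFactors = FALSE)
  per_context$delta <- per_context$ratio_b - per_context$ratio_a
  list(per_bin = m, per_context = per_context)
}
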