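test_that("context classification matches hand-worked examples", {
  #      0123456789
  ref <- "ACGTCCAGCA"
  expect_equal(classify_context(ref, 1L, "+"), "CG")    # C G ...
  expect_equal(classify_context(ref, 4L, "+"), "CHH")   # C C A
  expect_equal(classify_context(ref, 5L, "+"), "CHG")   # C A G
  expect_equal(classify_context(ref, 8L, "+"), "ambiguous")  # C A <end>
  expect_equal(classify_context(ref, 2L, "-"), "CG")    # G on minus, CG pair
  expect_equal(classify_context(ref, 7L, "-"), "CHG")   # minus strand reads CTG
  expect_error(classify_context(ref, 0L, "+"), "cytosine")
  expect_error(classify_context(ref, 1L, "-"), "cytosine")
  # N makes the context ambiguous
  expect_equal(classify_context("ACNT", 1L, "+"), "ambiguous")
})

test_that("context classification agrees with the revcomp oracle exhaustively", {
  # every reference of length 5 over {A,C,G,T} plus a batch with N
  alph <- c("A", "C", "G", "T")
  grid <- expand.grid(alph, alph, alph, stringsAsFactors = FALSE)
  refs <- apply(grid, 1, paste, collapse = "")
  refs <- paste0("C", refs, "G")                 # force sites at both ends
  refs <- c(refs, "CNGAG", "CCNGG", "ACNCG", "GNCGN")
  for (ref in refs) {
    sites <- cytosine_positions(ref)
    got <- classify_context(ref, sites$pos, sites$strand)
    want <- vapply(seq_len(nrow(sites)), function(i)
      oracle_context(ref, sites$pos[i], sites$strand[i]), "")
    expect_equal(got, want, info = ref)
  }
})

test_that("minus-strand contexts equal plus-strand contexts on the revcomp", {
  ref <- withr::with_seed(12, random_dna(200))
  rc <- revcomp(ref)
  sites <- cytosine_positions(ref)
  minus <- sites[sites$strand == "-", ]
  got <- classify_context(ref, minus$pos, "-")
  mirrored <- nchar(ref) - 1L - minus$pos
  want <- classify_context(rc, mirrored, "+")
  expect_equal(got, want)
})

test_that("methylome calling counts C/T read bases at reference cytosines", {
  ref <- "AACGTT"
  reads <- data.frame(
    id = c("r1", "r2", "r3", "r4"),
    seq = c("AACGTT",   # + read, methylated C at pos 2
            "AATGTT",   # + read, converted (unmethylated)
            "AACGTT",   # - read stored as revcomp of the slice = AACGTT
            "AATGTT"),  # - read with the site converted (T at read index 3)
    start = 0L, strand = c("+", "+", "-", "-"),
    stringsAsFactors = FALSE)
  tr <- call_methylome(reads, ref)
  plus <- tr[tr$strand == "+", ]
  minus <- tr[tr$strand == "-", ]
  expect_equal(plus$pos, 2L)
  expect_equal(plus$meth, 1L)
  expect_equal(plus$total, 2L)
  expect_equal(minus$pos, 3L)                   # the G of CG, minus strand
  expect_equal(minus$meth, 1L)
  expect_equal(minus$total, 2L)
  expect_equal(unique(tr$context), "CG")
  # empty input gives an empty, well-formed track
  empty <- call_methylome(reads[0, ], ref)
  expect_equal(nrow(empty), 0L)
  expect_equal(names(empty), c("pos", "strand", "context", "meth", "total"))
})

test_that("CX tables round-trip and reject impossible counts", {
  ref <- withr::with_seed(31, random_dna(300))
  mt <- generate_methylome(ref, c(CG = 0.9, CHG = 0.5, CHH = 0.1))
  rs <- generate_bisulfite_reads(ref, mt, coverage = 8, read_length = 50,
                                 seed = 32)
  tr <- call_methylome(rs$reads, ref)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cx_table(tr, path, chrom = "region")
  back <- read_cx_table(path)
  expect_equal(back[, c("pos", "strand", "context", "meth", "total")], tr)
  bad <- tr; bad$meth[1] <- bad$total[1] + 1L
  write_cx_table(bad, path)
  expect_error(read_cx_table(path), "exceeds")
})

test_that("read placement recovers true positions on a unique reference", {
  ref <- withr::with_seed(41, random_dna(500))
  mt <- generate_methylome(ref, c(CG = 0.8, CHG = 0.4, CHH = 0.05))
  rs <- generate_bisulfite_reads(ref, mt, coverage = 3, read_length = 60,
                                 seed = 42)
  placed <- place_reads(rs$reads$seq, ref)
  truth <- rs$reads[match(placed$seq, rs$reads$seq), ]
  expect_gt(nrow(placed), 0)
  expect_equal(placed$start, truth$start)
  expect_equal(placed$strand, truth$strand)
})

test_that("bin arithmetic is exact on a constructed track", {
  track <- data.frame(
    pos = c(1L, 5L, 22L, 25L, 44L),
    strand = "+",
    context = c("CG", "CG", "CG", "CHH", "CG"),
    meth = c(3L, 0L, 2L, 1L, 5L),
    total = c(10L, 10L, 4L, 2L, 5L))
  out <- bin_methylation(track, feature = c(0L, 50L), b = 20L)
  # bins tile [0,20), [20,40), [40,50)
  expect_equal(attr(out, "n_bins"), 3L)
  cg0 <- out[out$bin == 0 & out$context == "CG", ]
  expect_equal(cg0$ratio, 3 / 20)               # call-weighted: (3+0)/(10+10)
  expect_equal(cg0$n_sites, 2L)
  cg1 <- out[out$bin == 1 & out$context == "CG", ]
  expect_equal(cg1$ratio, 0.5)
  chh1 <- out[out$bin == 1 & out$context == "CHH", ]
  expect_equal(chh1$ratio, 0.5)
  last <- out[out$bin == 2, ]
  expect_equal(last$bin_end, 50L)               # partial final bin
  expect_equal(last$ratio, 1)
  # minus-strand anchoring mirrors the bins
  rev_out <- bin_methylation(track, feature = c(0L, 50L), b = 20L,
                             strand = "-")
  expect_equal(rev_out$ratio[rev_out$bin == 0 & rev_out$context == "CG"], 1)
  # empty in-feature track yields an empty frame with the right shape
  empty <- bin_methylation(track, feature = c(100L, 140L), b = 20L)
  expect_equal(nrow(empty), 0L)
  expect_equal(attr(empty, "n_bins"), 2L)
})

test_that("pooled per-context ratios equal call-weighted bin means", {
  ref <- withr::with_seed(51, random_dna(800))
  mt <- generate_methylome(ref, c(CG = 0.6, CHG = 0.3, CHH = 0.1))
  rs <- generate_bisulfite_reads(ref, mt, coverage = 20, read_length = 60,
                                 seed = 52)
  tr <- call_methylome(rs$reads, ref)
  binned <- bin_methylation(tr, c(0L, nchar(ref)), b = 20L)
  for (ctx in c("CG", "CHG", "CHH")) {
    d <- binned[binned$context == ctx & !is.na(binned$ratio), ]
    pooled_bins <- sum(d$ratio * d$n_calls) / sum(d$n_calls)
    sel <- tr$context == ctx
    pooled_track <- sum(tr$meth[sel]) / sum(tr$total[sel])
    expect_equal(pooled_bins, pooled_track)
  }
})

test_that("MSRE site finding matches examples and the scanning oracle", {
  # one site of each enzyme, with contexts dictated by the sequence itself
  s <- "AATTCGAATACCGGTACTCAGTA"
  sites <- find_msre_sites(s)
  expect_equal(sites$enzyme, c("Bsp119I", "MspI", "HpyF3I"))
  expect_equal(sites$start, c(2L, 10L, 16L))
  expect_equal(sites$diag_pos, c(4L, 10L, 16L))
  expect_equal(sites$diag_context, c("CG", "CHG", "CHH"))
  # HpyF3I with N = G gives a CHG diagnostic cytosine
  s2 <- "AACTGAGAA"
  site2 <- find_msre_sites(s2, "HpyF3I")
  expect_equal(site2$diag_context, "CHG")
  # no sites
  expect_equal(nrow(find_msre_sites("ACACACACAC")), 0L)
  # random-sequence equivalence with the brute-force oracle
  for (seed in 1:20) {
    sq <- withr::with_seed(seed, random_dna(300))
    got <- find_msre_sites(sq)
    want <- oracle_msre(sq)
    expect_equal(got[, c("enzyme", "start", "diag_pos")], want,
                 ignore_attr = TRUE)
  }
})

test_that("chop-PCR analytic fractions hit exact boundary cases", {
  expect_equal(simulate_chop_pcr(numeric(0))$analytic, 1)   # mock / no site
  expect_equal(simulate_chop_pcr(c(1, 1, 1))$analytic, 1)   # fully protected
  expect_equal(simulate_chop_pcr(c(0.5, 1), delta = 0)$analytic, 1)
  expect_equal(simulate_chop_pcr(0)$analytic, 0)            # cut for sure
  expect_equal(simulate_chop_pcr(c(0.8, 0.5))$analytic, 0.8 * 0.5)
  expect_equal(simulate_chop_pcr(0.4, delta = 0.5)$analytic, 1 - 0.6 * 0.5)
  expect_error(simulate_chop_pcr(1.2))
})

test_that("chop-PCR Monte-Carlo converges to the analytic fraction", {
  m <- c(0.8, 0.3, 0.6)
  res <- simulate_chop_pcr(m, delta = 0.9, n_molecules = 200000L, seed = 7)
  p <- res$analytic
  se <- sqrt(p * (1 - p) / 200000)
  expect_lt(abs(res$monte_carlo - p), 3 * se + 1e-9)
  # deterministic under a seed
  res2 <- simulate_chop_pcr(m, delta = 0.9, n_molecules = 200000L, seed = 7)
  expect_identical(res$monte_carlo, res2$monte_carlo)
})

test_that("condition comparison is zero on identical tracks and signed otherwise", {
  ref <- withr::with_seed(61, random_dna(600))
  hi <- generate_methylome(ref, c(CG = 0.8, CHG = 0.4, CHH = 0.05))
  lo <- generate_methylome(ref, c(CG = 0.3, CHG = 0.1, CHH = 0.05))
  tr_hi <- call_methylome(
    generate_bisulfite_reads(ref, hi, 30, 60, seed = 62)$reads, ref)
  tr_lo <- call_methylome(
    generate_bisulfite_reads(ref, lo, 30, 60, seed = 63)$reads, ref)
  b_hi <- bin_methylation(tr_hi, c(0L, nchar(ref)))
  b_lo <- bin_methylation(tr_lo, c(0L, nchar(ref)))
  same <- compare_conditions(b_hi, b_hi)
  expect_true(all(same$per_bin$delta == 0, na.rm = TRUE))
  expect_true(all(same$per_context$delta == 0))
  cmp <- compare_conditions(b_hi, b_lo)
  pc <- cmp$per_context
  expect_lt(pc$delta[pc$context == "CG"], -0.3)     # strong CG loss
  expect_lt(pc$delta[pc$context == "CHG"], -0.1)
  expect_lt(abs(pc$delta[pc$context == "CHH"]), 0.05)  # CHH stable
  # antisymmetry of the pooled deltas
  rev <- compare_conditions(b_lo, b_hi)
  expect_equal(rev$per_context$delta, -pc$delta)
})
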