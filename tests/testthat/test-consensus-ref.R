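# minimal hand-built alignment in the documented structure
manual_alignment <- function(rows, role = "spacer", is_intron = FALSE) {
  mat <- do.call(rbind, strsplit(rows, ""))
  nc <- ncol(mat)
  list(matrix = mat,
       columns = data.frame(segment = role, role = role,
                            ref_pos = 0:(nc - 1),
                            is_intron = rep(is_intron, nc),
                            intron_label = NA_character_,
                            stringsAsFactors = FALSE),
       unit_pos = matrix(rep(0:(nc - 1), each = nrow(mat)),
                         nrow = nrow(mat)),
       unit_index = seq_len(nrow(mat)),
       unit_start = rep(0L, nrow(mat)))
}

test_that("the consensus column rule marks polymorphic columns as N", {
  cons <- build_consensus(manual_alignment(c("ACGT", "ACGT")))
  expect_equal(cons$sequence, "ACGT")
  expect_equal(cons$mask, integer(0))
  cons2 <- build_consensus(manual_alignment(c("ACGT", "AGGT")))
  expect_equal(cons2$sequence, "ANGT")
  expect_equal(cons2$mask, 1L)
})

test_that("blocked intervals are forced to the MAJOR sequence and never N", {
  al <- manual_alignment(c("TTTT", "TTTT"), role = "Y1")
  cons <- build_consensus(al, list(Y1 = "ACGT"))
  expect_equal(cons$sequence, "ACGT")
  expect_equal(cons$mask, integer(0))
  # even polymorphic blocked columns take the MAJOR base, not N
  al2 <- manual_alignment(c("TTTT", "TATT"), role = "Y1")
  cons2 <- build_consensus(al2, list(Y1 = "ACGT"))
  expect_equal(cons2$sequence, "ACGT")
  expect_equal(length(cons2$mask), 0L)
  expect_error(build_consensus(al2, list(Y1 = "ACG")), "length")
})

test_that("minority columns are dropped under the 50% presence rule", {
  al <- manual_alignment(c("AC-T", "AC-T", "ACGT", "AC--"))
  cons <- build_consensus(al)
  # column 2 present in 1/4 units -> dropped; column 3 present in 3/4
  expect_equal(cons$sequence, "ACT")
  expect_equal(cons$dropped_columns, 1L)
})

test_that("anchor alignment flags exactly the planted polymorphic columns", {
  spec <- cluster_spec(6, test_pool(), data.frame(
    S = rep("S1", 6), Y1 = rep(c("YMAJ", "YMIN"), 3),
    Y2 = rep("YMAJ", 6), stringsAsFactors = FALSE), seed = 17)
  cl <- generate_cluster(spec)
  units <- decompose_generated(cl)
  al <- align_units(cl$sequence, units, cl$genes)
  cons <- build_consensus(al)
  # the two Y1 variants differ at exactly one mature position (offset 18);
  # every other column is monomorphic by construction
  pool <- test_pool()
  diff_pos <- which(strsplit(pool$mature[2], "")[[1]] !=
                      strsplit(pool$mature[3], "")[[1]]) - 1L
  expect_length(diff_pos, 1L)
  expect_length(cons$mask, 1L)
  y1 <- cl$genes[cl$genes$role == "Y1", ][1, ]
  unit1_off <- y1$start - units$start[1]
  # the masked consensus position corresponds to the planted substitution
  cm1 <- cons$column_map[cons$column_map$unit == 1, ]
  masked_unit_pos <- cm1$unit_pos[cm1$cons_pos == cons$mask]
  intron_len <- nchar(pool$intron[2])
  expected_unit_pos <- unit1_off +
    ifelse(diff_pos < pool$intron_offset[2], diff_pos, diff_pos + intron_len)
  expect_equal(masked_unit_pos, expected_unit_pos)
  # blocking the Y1 cassette with the MAJOR sequence removes the N entirely
  cons_blocked <- build_consensus(al, list(Y1 = pool$mature[2]))
  expect_length(cons_blocked$mask, 0L)
  bl <- cons_blocked$blocked
  got <- paste(vapply(seq_len(nrow(bl)), function(i)
    substr(cons_blocked$sequence, bl$start[i] + 1, bl$end[i]), ""),
    collapse = "")
  expect_identical(got, pool$mature[2])
})

test_that("a single spacer substitution yields exactly one polymorphic column", {
  spec <- cluster_spec(2, test_pool(), data.frame(
    S = c("S1", "S1"), Y1 = c("YMAJ", "YMAJ"), Y2 = c("YMAJ", "YMAJ"),
    stringsAsFactors = FALSE), seed = 23)
  cl <- generate_cluster(spec)
  units <- decompose_generated(cl)
  # plant one substitution in the second unit's S-Y1 spacer
  s2 <- cl$genes[cl$genes$id == "u002_S", ]
  pos <- s2$end + 3L
  old <- substr(cl$sequence, pos + 1, pos + 1)
  new <- if (old == "A") "G" else "A"
  mutated <- paste0(substr(cl$sequence, 1, pos), new,
                    substr(cl$sequence, pos + 2, nchar(cl$sequence)))
  al <- align_units(mutated, units, cl$genes)
  cons <- build_consensus(al)
  expect_length(cons$mask, 1L)
})

test_that("introns are never blocked even though they sit inside cassettes", {
  pool <- test_pool()
  pool$intron[pool$label == "YMIN" & pool$role == "Y1"] <- "ATGCAGATCA"
  spec <- cluster_spec(4, pool, data.frame(
    S = rep("S1", 4), Y1 = c("YMAJ", "YMIN", "YMAJ", "YMIN"),
    Y2 = rep("YMAJ", 4), stringsAsFactors = FALSE), seed = 31)
  cl <- generate_cluster(spec)
  units <- decompose_generated(cl)
  al <- align_units(cl$sequence, units, cl$genes)
  cons <- build_consensus(al, list(Y1 = pool$mature[2], Y2 = pool$mature[4]))
  # intron polymorphism (one substitution between the two intron variants)
  # survives as N despite full cassette blocking; i1 interval contains it
  expect_length(cons$mask, 1L)
  i1 <- cons$introns[cons$introns$label == "i1", ]
  expect_true(any(cons$mask >= i1$start & cons$mask < i1$end))
  # and no N inside any blocked interval
  bl <- cons$blocked
  inside <- any(vapply(cons$mask, function(p)
    any(p >= bl$start & p < bl$end), TRUE))
  expect_false(inside)
})

test_that("reference editing shrinks the genome and lifts coordinates reversibly", {
  d <- synthetic_tdna_deposit(seed = 3)
  ann <- load_annotations(d$annotations, d$genome)
  ann <- assign_locality(ann)
  fam <- classify_families(ann)
  cl <- ann[ann$chrom == "Chr1", ]
  units <- assign_cassettes(
    decompose_repeats(cl[, c("id", "start", "end", "isotype")]),
    fam$gene_labels, genes = ann)
  al <- align_units(d$genome$Chr1, units, ann)
  major <- fam$classes$representative_sequence[
    fam$classes$isotype == "Tyr" & fam$classes$locality == "C" &
      fam$classes$rank_label == "MAJOR"]
  cons <- build_consensus(al, list(Y1 = major, Y2 = major))
  ed <- emit_reference(d$genome, d$cluster_interval, cons, annotations = ann)
  iv <- d$cluster_interval
  expect_equal(nchar(ed$genome$Chr1),
               nchar(d$genome$Chr1) - (iv$end - iv$start) +
                 nchar(cons$sequence))
  # liftover identity upstream, shift downstream, NA inside
  expect_equal(ed$lift(c(0L, iv$start - 1L)), c(0L, iv$start - 1L))
  expect_equal(ed$lift(iv$end + 10L), iv$end + 10L + ed$shift)
  expect_true(is.na(ed$lift(iv$start + 1L)))
  # edited chromosome: upstream and downstream bases are preserved
  expect_equal(substr(ed$genome$Chr1, 1, iv$start),
               substr(d$genome$Chr1, 1, iv$start))
  expect_equal(substr(ed$genome$Chr1, iv$start + nchar(cons$sequence) + 1,
                      nchar(ed$genome$Chr1)),
               substr(d$genome$Chr1, iv$end + 1, nchar(d$genome$Chr1)))
  # annotations in the replaced interval are flagged collapsed
  st <- ed$annotations$status
  expect_true(all(st[ed$annotations$chrom == "Chr1" &
                       d$annotations$start >= iv$start] == "collapsed"))
  expect_true(all(st[ed$annotations$chrom != "Chr1"] == "unchanged"))
})

test_that("single-unit consensus of equal length preserves the genome outside N", {
  spec <- cluster_spec(1, test_pool(), data.frame(
    S = "S1", Y1 = "YMAJ", Y2 = "YMAJ"), seed = 41)
  cl <- generate_cluster(spec)
  units <- decompose_generated(cl)
  al <- align_units(cl$sequence, units, cl$genes)
  cons <- build_consensus(al)
  genome <- list(region = cl$sequence)
  iv <- list(chrom = "region", start = units$start[1], end = units$end[1])
  ed <- emit_reference(genome, iv, cons)
  expect_equal(ed$shift, 0L)
  expect_equal(ed$genome$region, cl$sequence)   # 1 unit: nothing polymorphic
})
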