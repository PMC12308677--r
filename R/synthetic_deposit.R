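# Fixed cassette sequences used by the synthetic deposit. These are
# invented stand-ins (not the real gene sequences): what matters for the
# pipeline is the planted equivalence-class structure, which mirrors the
# census reported for the endogenous nuclear tRNA-Tyr/Ser copies.
TYR_MATURE_BASE <- paste0(
  "CCGACCTTAGCTCAGTTGGTAGAGCGGTGGACTGTAGATCC",
  "TTAGGTCGCTGGTTCGATTCCGGCTCGAAGGACCAGGTGGCGCAATGGT")
SER_MATURE_CLUSTERED <- paste0(
  "GGAGAGATGGCCGAGTGGTTAAGGCGACAGACTAGAAATCT",
  "GTTGGGCTTTGCCCGCGCAGGTTCGAATCCTGCTCTCTCC")
SER_MATURE_DISPERSED <- paste0(
  "GGAGAGATGGCCGAGTGGTTAAGGCGACAGACTTGAAATCT",
  "GTTGGGCTTTGCCCGCGCAGGTTCGAATCCTGCTCTCTCC")
C_INTRON_BASE <- "ATGCAGATCCTTGAA"   # carries the conserved GCAGAT motif
D_INTRON_BASE <- "TTACCGGTTCAATCA"   # no GCAGAT
TYR_INTRON_OFFSET <- 37L             # mature bases before the intron

subst0_base <- function(seq, pos0, base = NULL) {
  cur <- substr(seq, pos0 + 1, pos0 + 1)
  if (is.null(base)) base <- if (cur == "A") "G" else "A"
  paste0(substr(seq, 1, pos0), base, substr(seq, pos0 + 2, nchar(seq)))
}

# the 9 clustered minor mature variants (single substitutions of the
# clustered MAJOR at distinct positions) and the dispersed variants
deposit_sequences <- function() {
  c_major <- TYR_MATURE_BASE
  c_minor <- lapply(1:9, function(k) subst0_base(c_major, 10 + k))
  d_major <- subst0_base(c_major, 5)
  d_minor <- list(subst0_base(d_major, 50), subst0_base(d_major, 55))
  c_intron <- c(list(C_INTRON_BASE),
                lapply(1:5, function(k) subst0_base(C_INTRON_BASE, 8 + k)),
                list(substr(C_INTRON_BASE, 1, 7)))    # truncated, motif lost
  d_intron <- lapply(1:12, function(j) {
    b1 <- DNA_BASES[(j - 1) %% 4 + 1]
    b2 <- DNA_BASES[((j - 1) %/% 4) %% 4 + 1]
    paste0(substr(D_INTRON_BASE, 1, 8), b1, b2,
           substr(D_INTRON_BASE, 11, nchar(D_INTRON_BASE)))
  })
  # two of the dispersed singleton intron variants share the clustered motif
  for (j in c(9L, 13L) - 4L) {     # will sit 5th and 9th among singletons
    d_intron[[j + 3L]] <- paste0(substr(d_intron[[j + 3L]], 1, 2), "GCAGAT",
                                 substr(d_intron[[j + 3L]], 9, 15))
  }
  seqs <- list(c_major = c_major, c_minor = c_minor, d_major = d_major,
               d_minor = d_minor, c_intron = c_intron, d_intron = d_intron)
  # planted motif structure must hold by construction
  stopifnot(
    all(vapply(seqs$c_intron[1:6], function(s) grepl("GCAGAT", s), TRUE)),
    !grepl("GCAGAT", seqs$c_intron[[7]]),
    sum(vapply(seqs$d_intron, function(s) grepl("GCAGAT", s), TRUE)) == 2,
    !anyDuplicated(unlist(seqs$c_intron)),
    !anyDuplicated(unlist(seqs$d_intron)),
    !anyDuplicated(c(c_major, unlist(c_minor), d_major, unlist(d_minor))))
  seqs
}

# implant a gene body into a chromosome at `start` on `strand`; bodies are
# given 5'->3' and reverse complemented for minus-strand placement
implant_gene <- function(chrom_seq, start, strand, mature, intron,
                         intron_offset) {
  body <- if (nzchar(intron))
    paste0(substr(mature, 1, intron_offset), intron,
           substr(mature, intron_offset + 1, nchar(mature)))
  else mature
  placed <- if (strand == "-") revcomp(body) else body
  end <- start + nchar(body)
  stopifnot(end <= nchar(chrom_seq))
  chrom_seq <- paste0(substr(chrom_seq, 1, start), placed,
                      substr(chrom_seq, end + 1, nchar(chrom_seq)))
  if (nzchar(intron)) {
    if (strand == "+") {
      istart <- start + intron_offset
    } else {
      istart <- end - intron_offset - nchar(intron)
    }
    iend <- istart + nchar(intron)
  } else {
    istart <- NA_integer_; iend <- NA_integer_
  }
  list(chrom_seq = chrom_seq, start = start, end = end,
       intron_start = istart, intron_end = iend)
}

#' Synthetic genome-scale tDNA annotation deposit
#'
#' Builds a small synthetic genome plus a tDNA-Ser/tDNA-Tyr annotation
#' table whose planted class structure mirrors the census of the endogenous
#' Arabidopsis Col-0 nuclear genome: 70 tRNA-Tyr copies of which 16 are
#' dispersed (one 14-copy MAJOR family and two single-copy minors, one of
#' them a tRNA-like pseudogene) and 54 sit in a 27-unit tandem S-Y1-Y2
#' cluster (one 32-copy MAJOR and nine minors totalling 22 copies, with 13
#' copies in tRNA-like minor classes); 12 dispersed and 7 clustered exact
#' intron variants, the conserved GCAGAT motif present in every clustered
#' intron variant except one truncated singleton; MAJOR cassettes
#' concentrated at the Y2 position (22/27) relative to Y1 (10/27). All
#' sequences are invented; only the class structure is modelled on the
#' census.
#'
#' @param seed integer RNG seed (random chromosome backgrounds and
#'   spacers).
#' @return list(genome, annotations, cluster_interval, truth) — `genome` a
#'   named list of chromosome sequences, `annotations` the tDNA table
#'   dialect, `cluster_interval` the Chr1 cluster span, and `truth` the
#'   planted per-gene labels and expected census counts.
#' @export
synthetic_tdna_deposit <- function(seed = 1L) {
  sq <- deposit_sequences()
  withr::with_seed(seed, {
    spacer <- 60L
    ann <- list()
    truth_gene <- list()
    add_gene <- function(chrom_name, chrom_seq, id, start, strand, isotype,
                         anticodon, mature, intron, offset, pseudo,
                         mature_class, intron_class) {
      im <- implant_gene(chrom_seq, start, strand, mature, intron, offset)
      ann[[length(ann) + 1L]] <<- data.frame(
        id = id, chrom = chrom_name, start = im$start, end = im$end,
        strand = strand, isotype = isotype, anticodon = anticodon,
        intron_start = im$intron_start, intron_end = im$intron_end,
        pseudogene_flag = pseudo, stringsAsFactors = FALSE)
      truth_gene[[length(truth_gene) + 1L]] <<- data.frame(
        id = id, mature_class = mature_class, intron_class = intron_class,
        stringsAsFactors = FALSE)
      im$chrom_seq
    }

    # --- Chr1: the 27-unit tandem S-Y1-Y2 cluster ------------------------
    # MAJOR-pair core at units 10-19 (Y1 majors: exactly those 10 units);
    # Y2 minors only at the outermost units (1-3, 26-27), so Y2 carries 22
    # majors; minor class labels m1..m9 with copy counts 5,4,3,2,2,2,2,1,1
    y1_minor <- c(u(1, 9), u(20, 27))
    y2_minor <- c(1:3, 26:27)
    minor_at <- list()
    assign_minor <- function(unit, pos, label) {
      minor_at[[paste(unit, pos)]] <<- label
    }
    y1_lab <- c("m1", "m1", "m2", "m1", "m5", "m2", "m6", "m3", "m7",
                "m1", "m5", "m6", "m4", "m7", "m1", "m2", "m8")
    for (k in seq_along(y1_minor)) assign_minor(y1_minor[k], "Y1", y1_lab[k])
    y2_lab <- c("m2", "m3", "m4", "m3", "m9")
    for (k in seq_along(y2_minor)) assign_minor(y2_minor[k], "Y2", y2_lab[k])
    pseudo_classes <- c("m1", "m5", "m6", "m7", "m8", "m9")
    # clustered intron variants cv1..cv7 with copy counts 30,8,6,4,3,2,1
    cv_per_slot <- rep(paste0("cv", 1:7), c(30, 8, 6, 4, 3, 2, 1))

    cluster_start <- 1000L
    chr1 <- random_dna(40000L)
    # shared spacer templates: the array is a tandem duplication, so the
    # sequence between cassettes repeats across units
    spacers <- setNames(lapply(1:3, function(i) random_dna(spacer)),
                        c("afterS", "afterY1", "afterY2"))
    cursor <- cluster_start
    slot <- 0L
    for (unit in 1:27) {
      chr1 <- add_gene("Chr1", chr1, sprintf("cS%02d", unit), cursor, "+",
                       "Ser", "AGA", SER_MATURE_CLUSTERED, "", 0L, FALSE,
                       "cS", NA_character_)
      cursor <- cursor + nchar(SER_MATURE_CLUSTERED)
      chr1 <- paste0(substr(chr1, 1, cursor), spacers$afterS,
                     substr(chr1, cursor + spacer + 1, nchar(chr1)))
      cursor <- cursor + spacer
      for (pos in c("Y1", "Y2")) {
        slot <- slot + 1L
        lab <- minor_at[[paste(unit, pos)]]
        mclass <- if (is.null(lab)) "c_major" else lab
        mature <- if (is.null(lab)) sq$c_major else
          sq$c_minor[[as.integer(sub("m", "", lab))]]
        iclass <- cv_per_slot[slot]
        intron <- sq$c_intron[[as.integer(sub("cv", "", iclass))]]
        chr1 <- add_gene("Chr1", chr1,
                         sprintf("c%s%02d", pos, unit), cursor, "+",
                         "Tyr", "GTA", mature, intron, TYR_INTRON_OFFSET,
                         mclass %in% pseudo_classes, mclass, iclass)
        cursor <- cursor + nchar(mature) + nchar(intron)
        sp <- if (pos == "Y1") spacers$afterY1 else spacers$afterY2
        chr1 <- paste0(substr(chr1, 1, cursor), sp,
                       substr(chr1, cursor + spacer + 1, nchar(chr1)))
        cursor <- cursor + spacer
      }
    }
    cluster_interval <- list(chrom = "Chr1", start = cluster_start,
                             end = cursor - spacer)

    # --- Chr2: 16 dispersed tRNA-Tyr copies, >2 kb apart -----------------
    # minors (single copies) at slots 8 (pseudogene) and 12; 12 intron
    # variants with copy counts 3,2,2 then nine singletons, the 5th and 9th
    # singleton carrying GCAGAT
    d_iclass <- rep(paste0("dv", 1:12), c(3, 2, 2, rep(1, 9)))
    chr2 <- random_dna(60000L)
    for (k in 1:16) {
      start <- 2000L + (k - 1L) * 3500L
      strand <- if (k %% 2 == 0) "-" else "+"
      mclass <- if (k == 8) "d_minor1" else if (k == 12) "d_minor2" else
        "d_major"
      mature <- switch(mclass, d_major = sq$d_major,
                       d_minor1 = sq$d_minor[[1]], d_minor2 = sq$d_minor[[2]])
      intron <- sq$d_intron[[as.integer(sub("dv", "", d_iclass[k]))]]
      chr2 <- add_gene("Chr2", chr2, sprintf("dY%02d", k), start, strand,
                       "Tyr", "GTA", mature, intron, TYR_INTRON_OFFSET,
                       mclass == "d_minor1", mclass, d_iclass[k])
    }

    # --- Chr3: 6 dispersed intronless tRNA-Ser copies --------------------
    chr3 <- random_dna(30000L)
    for (k in 1:6) {
      start <- 2000L + (k - 1L) * 4000L
      chr3 <- add_gene("Chr3", chr3, sprintf("dS%02d", k), start,
                       if (k %% 2 == 0) "-" else "+", "Ser", "AGA",
                       SER_MATURE_DISPERSED, "", 0L, FALSE, "dS",
                       NA_character_)
    }

    annotations <- do.call(rbind, ann)
    truth <- list(
      gene_classes = do.call(rbind, truth_gene),
      counts = list(tyr_total = 70L, d_major = 14L, c_major = 32L,
                    d_intron_variants = 12L, c_intron_variants = 7L,
                    trna_like_c = 13L, n_units = 27L,
                    y1_major = 10L, y2_major = 22L))
    list(genome = list(Chr1 = chr1, Chr2 = chr2, Chr3 = chr3),
         annotations = annotations, cluster_interval = cluster_interval,
         truth = truth)
  })
}

u <- function(a, b) seq.int(a, b)

#' Synthetic tandem SYY region at the endogenous repeat scale
#'
#' A generated cluster emulating the chromosome-1 SYY interval: `n_units`
#' complete S-Y1-Y2 units (34 by default, the endogenous repeat copy
#' number) with the MAJOR Tyr cassette at the Y2 position in ~80% of units
#' and at Y1 in ~40%.
#'
#' @param n_units number of repeat units.
#' @param seed integer RNG seed.
#' @return a [generate_cluster()] result.
#' @export
synthetic_syy_region <- function(n_units = 34L, seed = 1L) {
  sq <- deposit_sequences()
  pool <- data.frame(
    role = c("S", "Y1", "Y1", "Y2", "Y2"),
    label = c("S", "MAJOR", "MINOR", "MAJOR", "MINOR"),
    mature = c(SER_MATURE_CLUSTERED, sq$c_major, sq$c_minor[[1]],
               sq$c_major, sq$c_minor[[1]]),
    intron = c("", rep(sq$c_intron[[1]], 4)),
    intron_offset = c(0L, rep(TYR_INTRON_OFFSET, 4)),
    stringsAsFactors = FALSE)
  n_y2_major <- round(0.8 * n_units)
  n_y1_major <- round(0.4 * n_units)
  assign <- data.frame(
    S = rep("S", n_units),
    Y1 = rep(c("MAJOR", "MINOR"), c(n_y1_major, n_units - n_y1_major)),
    Y2 = rep(c("MINOR", "MAJOR"), c(n_units - n_y2_major, n_y2_major)),
    stringsAsFactors = FALSE)
  generate_cluster(cluster_spec(n_units, pool, assign, seed = seed))
}
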