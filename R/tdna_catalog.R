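#' Load tDNA annotations and extract gene sequences
#'
#' Reads a tDNA annotation table (the documented TSV dialect: id, chrom,
#' start, end, strand, isotype, anticodon, intron_start, intron_end,
#' pseudogene_flag; coordinates 0-based half-open, intron coordinates
#' genomic and nested in the gene body) and extracts each copy's mature and
#' intron sequence from the genome, strand-aware: minus-strand genes are
#' reverse complemented, and the mature sequence is the gene body with the
#' intron removed.
#'
#' @param annotations data.frame in the dialect above, or a path to a TSV
#'   with those columns.
#' @param genome named character vector of chromosome sequences, a
#'   `DNAStringSet`, or a FASTA path.
#' @return the annotation data.frame with `mature_sequence` and
#'   `intron_sequence` columns added (intron "" when absent).
#' @export
load_annotations <- function(annotations, genome) {
  ann <- if (is.character(annotations) && length(annotations) == 1)
    read_tdna_table(annotations) else annotations
  needed <- c("id", "chrom", "start", "end", "strand", "isotype",
              "anticodon", "intron_start", "intron_end", "pseudogene_flag")
  missing_cols <- setdiff(needed, names(ann))
  if (length(missing_cols) > 0) {
    stop("annotation table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  genome <- as_genome(genome)
  mature <- character(nrow(ann))
  intron <- character(nrow(ann))
  for (i in seq_len(nrow(ann))) {
    g <- ann[i, ]
    chrom_seq <- genome[[as.character(g$chrom)]]
    if (is.null(chrom_seq)) {
      stop(sprintf("record %s: chromosome %s not in genome", g$id, g$chrom))
    }
    if (g$end <= g$start || g$start < 0 || g$end > nchar(chrom_seq)) {
      stop(sprintf("record %s: coordinates [%d, %d) out of bounds",
                   g$id, g$start, g$end))
    }
    has_i <- !is.na(g$intron_start) && !is.na(g$intron_end)
    if (has_i && (g$intron_start < g$start || g$intron_end > g$end ||
                  g$intron_end <= g$intron_start)) {
      stop(sprintf("record %s: intron [%d, %d) not nested in gene body",
                   g$id, g$intron_start, g$intron_end))
    }
    body <- substr0(chrom_seq, g$start, g$end)
    if (has_i) {
      i_gen <- substr0(chrom_seq, g$intron_start, g$intron_end)
      m_gen <- paste0(substr0(chrom_seq, g$start, g$intron_start),
                      substr0(chrom_seq, g$intron_end, g$end))
    } else {
      i_gen <- ""
      m_gen <- body
    }
    if (g$strand == "-") {
      mature[i] <- revcomp(m_gen)
      intron[i] <- if (nzchar(i_gen)) revcomp(i_gen) else ""
    } else {
      mature[i] <- m_gen
      intron[i] <- i_gen
    }
  }
  ann$mature_sequence <- toupper(mature)
  ann$intron_sequence <- toupper(intron)
  ann
}

as_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    ss <- Biostrings::readDNAStringSet(genome)
    genome <- setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  } else if (methods::is(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  as.list(genome)
}

#' Read / write the tDNA annotation TSV dialect
#'
#' @param path TSV path.
#' @return data.frame with the dialect's columns.
#' @export
read_tdna_table <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                  na.strings = c("NA", ""))
  d$pseudogene_flag <- as.logical(d$pseudogene_flag)
  d
}

#' @rdname read_tdna_table
#' @param x annotation data.frame.
#' @export
write_tdna_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Assign dispersed/clustered locality to tDNA copies
#'
#' A copy is clustered (`C`) when it overlaps a supplied cluster interval,
#' or — with the distance rule — when another tDNA lies within `distance`
#' bases on the same chromosome; dispersed (`D`) otherwise.
#'
#' @param genes annotation data.frame (needs chrom, start, end).
#' @param cluster_intervals optional data.frame (chrom, start, end), 0-based
#'   half-open; when supplied the interval rule is used.
#' @param distance positive gap threshold in bases for the fallback rule
#'   (default 2000).
#' @return `genes` with a `locality` column ("D"/"C").
#' @export
assign_locality <- function(genes, cluster_intervals = NULL,
                            distance = 2000L) {
  n <- nrow(genes)
  loc <- rep("D", n)
  if (!is.null(cluster_intervals)) {
    for (i in seq_len(n)) {
      hit <- cluster_intervals$chrom == genes$chrom[i] &
        cluster_intervals$start < genes$end[i] &
        cluster_intervals$end > genes$start[i]
      if (any(hit)) loc[i] <- "C"
    }
  } else {
    stopifnot(distance > 0)
    for (i in seq_len(n)) {
      same <- genes$chrom == genes$chrom[i] & seq_len(n) != i
      if (!any(same)) next
      gap <- pmax(genes$start[same] - genes$end[i],
                  genes$start[i] - genes$end[same])
      if (any(gap <= distance)) loc[i] <- "C"
    }
  }
  genes$locality <- loc
  genes
}

# order key used for deterministic tie-breaks: chromosome then start
genomic_order <- function(genes) order(genes$chrom, genes$start, genes$id)

#' Classify tDNA copies into MAJOR/MINOR sequence families
#'
#' Within each (isotype, locality) group, families are exact
#' mature-sequence equivalence classes. The largest class is MAJOR; the
#' remaining classes are MINOR1, MINOR2, ... by descending copy count, ties
#' broken by the smallest genomic coordinate of each class's first member.
#'
#' @param genes annotation data.frame with `isotype`, `locality` and
#'   `mature_sequence` columns.
#' @return list(classes, gene_labels): `classes` is a data.frame (isotype,
#'   locality, rank_label, representative_sequence, copy_count, member_ids
#'   — comma separated); `gene_labels` maps every gene id to its rank_label.
#' @export
classify_families <- function(genes) {
  empty <- list(
    classes = data.frame(isotype = character(0), locality = character(0),
                         rank_label = character(0),
                         representative_sequence = character(0),
                         copy_count = integer(0), member_ids = character(0)),
    gene_labels = data.frame(id = character(0), rank_label = character(0)))
  if (nrow(genes) == 0) return(empty)
  stopifnot(all(c("isotype", "locality", "mature_sequence") %in% names(genes)))
  classes <- list(); labels <- list()
  for (grp in split(genes, list(genes$isotype, genes$locality), drop = TRUE)) {
    ranked <- rank_equivalence_classes(grp, grp$mature_sequence)
    ranked$ranks$rank_label <- ifelse(ranked$ranks$rank == 1, "MAJOR",
                                      paste0("MINOR", ranked$ranks$rank - 1))
    classes[[length(classes) + 1L]] <- data.frame(
      isotype = grp$isotype[1], locality = grp$locality[1],
      rank_label = ranked$ranks$rank_label,
      representative_sequence = ranked$ranks$sequence,
      copy_count = ranked$ranks$copy_count,
      member_ids = ranked$ranks$member_ids,
      stringsAsFactors = FALSE)
    labels[[length(labels) + 1L]] <- data.frame(
      id = grp$id,
      rank_label = ranked$ranks$rank_label[ranked$class_of],
      stringsAsFactors = FALSE)
  }
  classes <- do.call(rbind, classes)
  gene_labels <- do.call(rbind, labels)
  stopifnot(sum(classes$copy_count) == nrow(genes),
            !anyDuplicated(gene_labels$id))
  list(classes = classes, gene_labels = gene_labels)
}

# shared machinery: exact-sequence equivalence classes of the rows of
# `grp`, ranked by descending copy count then genomic order of the first
# member; returns per-class table plus each row's class index
rank_equivalence_classes <- function(grp, seqs) {
  ord <- genomic_order(grp)
  first_pos <- match(unique(seqs[ord]), seqs[ord])    # genomic order of class
  useq <- unique(seqs[ord])
  counts <- as.integer(table(factor(seqs, levels = useq)))
  rk <- order(-counts, first_pos)
  ranks <- data.frame(sequence = useq[rk], copy_count = counts[rk],
                      stringsAsFactors = FALSE)
  ranks$rank <- seq_len(nrow(ranks))
  ranks$member_ids <- vapply(ranks$sequence, function(s)
    paste(grp$id[ord][seqs[ord] == s], collapse = ","), "")
  list(ranks = ranks, class_of = match(seqs, ranks$sequence))
}

#' Group tDNA introns into exact-sequence variants
#'
#' Per locality, intron-bearing copies are partitioned into exact
#' intron-sequence equivalence classes labelled VAR1, VAR2, ... by
#' descending copy count then genomic order. Truncated introns are distinct
#' variants. Intronless copies are ignored.
#'
#' @param genes annotation data.frame with `locality` and `intron_sequence`.
#' @return list(variants, gene_labels): `variants` is a data.frame
#'   (locality, var_label, intron_sequence, copy_count, member_ids);
#'   `gene_labels` maps intron-bearing gene ids to var_label.
#' @export
cluster_intron_variants <- function(genes) {
  keep <- nzchar(genes$intron_sequence)
  genes <- genes[keep, , drop = FALSE]
  empty <- list(
    variants = data.frame(locality = character(0), var_label = character(0),
                          intron_sequence = character(0),
                          copy_count = integer(0), member_ids = character(0)),
    gene_labels = data.frame(id = character(0), var_label = character(0)))
  if (nrow(genes) == 0) return(empty)
  variants <- list(); labels <- list()
  for (grp in split(genes, genes$locality, drop = TRUE)) {
    ranked <- rank_equivalence_classes(grp, grp$intron_sequence)
    ranked$ranks$var_label <- paste0("VAR", ranked$ranks$rank)
    variants[[length(variants) + 1L]] <- data.frame(
      locality = grp$locality[1], var_label = ranked$ranks$var_label,
      intron_sequence = ranked$ranks$sequence,
      copy_count = ranked$ranks$copy_count,
      member_ids = ranked$ranks$member_ids,
      stringsAsFactors = FALSE)
    labels[[length(labels) + 1L]] <- data.frame(
      id = grp$id, var_label = ranked$ranks$var_label[ranked$class_of],
      stringsAsFactors = FALSE)
  }
  variants <- do.call(rbind, variants)
  gene_labels <- do.call(rbind, labels)
  stopifnot(sum(variants$copy_count) == nrow(genes))
  list(variants = variants, gene_labels = gene_labels)
}

#' Scan sequences for exact occurrences of a motif
#'
#' Reports all exact occurrences of the motif on the given sequences only
#' (no reverse complement), including overlapping ones, as 0-based offsets.
#'
#' @param sequences character vector (possibly named) of DNA sequences.
#' @param motif non-empty exact motif over A/C/G/T.
#' @return named list of integer vectors of 0-based hit offsets.
#' @export
scan_motif <- function(sequences, motif) {
  stopifnot(nzchar(motif))
  assert_dna(motif, "motif")
  out <- lapply(sequences, function(s) {
    if (!nzchar(s) || nchar(s) < nchar(motif)) return(integer(0))
    m <- Biostrings::matchPattern(motif, Biostrings::DNAString(s))
    Biostrings::start(m) - 1L
  })
  if (!is.null(names(sequences))) names(out) <- names(sequences)
  out
}
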