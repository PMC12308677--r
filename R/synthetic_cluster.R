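#' Specify a synthetic tandem S-Y1-Y2 cluster
#'
#' A `cluster_spec` describes a tandem array of repeat units, each carrying a
#' tRNA-Ser cassette (role `S`) followed by two tRNA-Tyr cassettes (roles
#' `Y1`, `Y2`), embedded in random flanking sequence. Cassette sequences are
#' drawn from a pool of named variants; each unit assigns one variant per
#' role, so MAJOR/MINOR mixtures and intron variants can be planted at will.
#'
#' @param n_units number of repeat units (>= 1).
#' @param cassette_pool data.frame with columns `role` (one of "S", "Y1",
#'   "Y2"), `label` (variant name), `mature` (intron-removed gene sequence),
#'   `intron` (intron sequence, "" for none), `intron_offset` (0-based number
#'   of mature bases preceding the intron insertion point), and optionally
#'   `pseudogene` (logical, default FALSE).
#' @param unit_assignment data.frame with `n_units` rows and columns `S`,
#'   `Y1`, `Y2` giving the variant label used at each position of each unit.
#' @param spacer_length bases of spacer sequence between consecutive
#'   cassettes (and between units); one spacer template per cassette gap is
#'   drawn once and repeated in every unit, as in a tandem duplication.
#' @param flank_length bases of random sequence on each side of the array.
#' @param seed integer RNG seed; the generated region is a pure function of
#'   the spec (including this seed).
#' @return an object of class `cluster_spec`.
#' @seealso [generate_cluster()]
#' @export
cluster_spec <- function(n_units, cassette_pool, unit_assignment,
                         spacer_length = 60L, flank_length = 300L,
                         seed = 1L) {
  stopifnot(is_scalar_number(n_units), n_units >= 1)
  needed <- c("role", "label", "mature", "intron", "intron_offset")
  if (!all(needed %in% names(cassette_pool))) {
    stop("cassette_pool must have columns: ", paste(needed, collapse = ", "))
  }
  if (is.null(cassette_pool$pseudogene)) cassette_pool$pseudogene <- FALSE
  stopifnot(all(cassette_pool$role %in% c("S", "Y1", "Y2")))
  assert_dna(cassette_pool$mature, "cassette mature sequence")
  with_intron <- nzchar(cassette_pool$intron)
  if (any(with_intron)) {
    assert_dna(cassette_pool$intron[with_intron], "cassette intron sequence")
  }
  stopifnot(nrow(unit_assignment) == n_units,
            all(c("S", "Y1", "Y2") %in% names(unit_assignment)))
  for (role in c("S", "Y1", "Y2")) {
    pool_labels <- cassette_pool$label[cassette_pool$role == role]
    unknown <- setdiff(unit_assignment[[role]], pool_labels)
    if (length(unknown) > 0) {
      stop(sprintf("unknown variant label '%s' for role %s", unknown[1], role))
    }
  }
  structure(
    list(n_units = as.integer(n_units),
         cassette_pool = cassette_pool,
         unit_assignment = unit_assignment,
         spacer_length = as.integer(spacer_length),
         flank_length = as.integer(flank_length),
         seed = as.integer(seed)),
    class = "cluster_spec")
}

pool_entry <- function(pool, role, label) {
  i <- which(pool$role == role & pool$label == label)
  pool[i[1], , drop = FALSE]
}

# gene-body sequence of a cassette: mature with intron inserted at the
# 0-based offset (bases of mature preceding the intron)
cassette_body <- function(entry) {
  if (!nzchar(entry$intron)) return(entry$mature)
  off <- entry$intron_offset
  paste0(substr(entry$mature, 1, off), entry$intron,
         substr(entry$mature, off + 1, nchar(entry$mature)))
}

#' Generate a synthetic tandem cluster region
#'
#' Builds the region sequence, cassette annotations and a planted truth
#' table for a [cluster_spec()]. All cassettes lie on the plus strand of the
#' region; coordinates are 0-based half-open.
#'
#' @param spec a [cluster_spec()].
#' @return list with elements
#'   \describe{
#'     \item{sequence}{region sequence (character).}
#'     \item{genes}{annotation data.frame in the tDNA table dialect
#'       (id, chrom, start, end, strand, isotype, anticodon, intron_start,
#'       intron_end, pseudogene_flag) plus `role`, `unit`, `variant_label`.}
#'     \item{truth}{data.frame (unit, role, variant_label).}
#'     \item{unit_intervals}{data.frame (unit, start, end) spanning each
#'       unit's first to last cassette.}
#'   }
#' @export
generate_cluster <- function(spec) {
  stopifnot(inherits(spec, "cluster_spec"))
  withr::with_seed(spec$seed, {
    pool <- spec$cassette_pool
    pieces <- character(0)
    genes <- list()
    truth <- list()
    unit_iv <- list()
    cursor <- spec$flank_length
    pieces <- c(pieces, random_dna(spec$flank_length))
    isotype_of <- c(S = "Ser", Y1 = "Tyr", Y2 = "Tyr")
    anticodon_of <- c(S = "AGA", Y1 = "GTA", Y2 = "GTA")
    # one spacer template per cassette gap, shared by every unit: the array
    # is a tandem duplication, so inter-cassette sequence is repeated and
    # polymorphism enters only through the assigned cassette variants
    spacers <- setNames(
      vapply(c("S", "Y1", "Y2"), function(x) random_dna(spec$spacer_length),
             ""),
      c("S", "Y1", "Y2"))
    for (u in seq_len(spec$n_units)) {
      unit_start <- NA_integer_
      for (role in c("S", "Y1", "Y2")) {
        label <- spec$unit_assignment[[role]][u]
        entry <- pool_entry(pool, role, label)
        body <- cassette_body(entry)
        g_start <- cursor
        g_end <- cursor + nchar(body)
        if (is.na(unit_start)) unit_start <- g_start
        has_intron <- nzchar(entry$intron)
        genes[[length(genes) + 1L]] <- data.frame(
          id = sprintf("u%03d_%s", u, role),
          chrom = "region",
          start = g_start, end = g_end, strand = "+",
          isotype = isotype_of[[role]], anticodon = anticodon_of[[role]],
          intron_start = if (has_intron) g_start + entry$intron_offset else NA_integer_,
          intron_end = if (has_intron) g_start + entry$intron_offset + nchar(entry$intron) else NA_integer_,
          pseudogene_flag = isTRUE(entry$pseudogene),
          role = role, unit = u, variant_label = label,
          stringsAsFactors = FALSE)
        truth[[length(truth) + 1L]] <- data.frame(
          unit = u, role = role, variant_label = label,
          stringsAsFactors = FALSE)
        pieces <- c(pieces, body, spacers[[role]])
        cursor <- g_end + spec$spacer_length
      }
      unit_iv[[u]] <- data.frame(unit = u, start = unit_start,
                                 end = cursor - spec$spacer_length)
    }
    pieces <- c(pieces, random_dna(spec$flank_length))
    list(sequence = paste(pieces, collapse = ""),
         genes = do.call(rbind, genes),
         truth = do.call(rbind, truth),
         unit_intervals = do.call(rbind, unit_iv))
  })
}

#' Write a generated cluster to FASTA and GFF3
#'
#' GFF3 coordinates are 1-based inclusive; introns are emitted as child
#' features of their cassette.
#'
#' @param cluster result of [generate_cluster()].
#' @param fasta,gff output file paths (either may be NULL to skip).
#' @param seqname sequence name used in both files.
#' @return invisibly, the paths written.
#' @export
write_cluster <- function(cluster, fasta = NULL, gff = NULL,
                          seqname = "region") {
  if (!is.null(fasta)) {
    ss <- Biostrings::DNAStringSet(setNames(cluster$sequence, seqname))
    Biostrings::writeXStringSet(ss, fasta)
  }
  if (!is.null(gff)) {
    g <- cluster$genes
    gr <- GenomicRanges::GRanges(
      seqnames = seqname,
      ranges = IRanges::IRanges(start = g$start + 1L, end = g$end),
      strand = g$strand)
    gr$type <- "gene"
    gr$ID <- g$id
    gr$isotype <- g$isotype
    gr$anticodon <- g$anticodon
    gr$variant_label <- g$variant_label
    gr$pseudogene <- tolower(as.character(g$pseudogene_flag))
    has_i <- !is.na(g$intron_start)
    if (any(has_i)) {
      gi <- g[has_i, ]
      gri <- GenomicRanges::GRanges(
        seqnames = seqname,
        ranges = IRanges::IRanges(start = gi$intron_start + 1L,
                                  end = gi$intron_end),
        strand = gi$strand)
      gri$type <- "intron"
      gri$ID <- paste0(gi$id, "_intron")
      gri$Parent <- gi$id
      gr$Parent <- NA_character_
      gri$isotype <- NA_character_
      gri$anticodon <- NA_character_
      gri$variant_label <- NA_character_
      gri$pseudogene <- NA_character_
      gr <- c(gr, gri)
    }
    rtracklayer::export(gr, gff, format = "gff3")
  }
  invisible(c(fasta = fasta, gff = gff))
}
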