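UNIT_SEGMENTS <- c("sp0", "S", "sp1", "Y1", "sp2", "Y2", "sp3")

# segment intervals (0-based half-open, genomic) of one complete unit
unit_segments <- function(unit, genes) {
  g <- function(id) genes[genes$id == id, , drop = FALSE]
  s <- g(unit$s_id); y1 <- g(unit$y1_id); y2 <- g(unit$y2_id)
  data.frame(
    segment = UNIT_SEGMENTS,
    start = c(unit$start, s$start, s$end, y1$start, y1$end, y2$start, y2$end),
    end = c(s$start, s$end, y1$start, y1$end, y2$start, y2$end, unit$end),
    stringsAsFactors = FALSE)
}

align_one_segment <- function(ref_seg, unit_seg) {
  # returns list(residues = per-ref-position unit residue ("-" = deletion),
  #              unit_pos = 0-based unit-segment position per ref position
  #                         (NA at deletions),
  #              insertions = number of unit bases absent from the ref
  #                           coordinate space)
  nr <- nchar(ref_seg)
  if (nr == 0) {
    return(list(residues = character(0), unit_pos = integer(0),
                insertions = nchar(unit_seg)))
  }
  if (identical(ref_seg, unit_seg)) {
    return(list(residues = seq_chars(ref_seg),
                unit_pos = 0:(nr - 1L), insertions = 0L))
  }
  if (nchar(unit_seg) == 0) {
    return(list(residues = rep("-", nr), unit_pos = rep(NA_integer_, nr),
                insertions = 0L))
  }
  pa <- Biostrings::pairwiseAlignment(
    unit_seg, ref_seg, type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1),
    gapOpening = 0, gapExtension = 2)
  au <- seq_chars(as.character(Biostrings::alignedPattern(pa)))
  ar <- seq_chars(as.character(Biostrings::alignedSubject(pa)))
  residues <- character(nr); unit_pos <- rep(NA_integer_, nr)
  rp <- 0L; up <- 0L; ins <- 0L
  for (j in seq_along(ar)) {
    if (ar[j] != "-") {
      rp <- rp + 1L
      residues[rp] <- au[j]
      if (au[j] != "-") {
        unit_pos[rp] <- up
        up <- up + 1L
      }
    } else {
      ins <- ins + 1L
      if (au[j] != "-") up <- up + 1L
    }
  }
  list(residues = residues, unit_pos = unit_pos, insertions = ins)
}

#' Anchor-based alignment of tandem repeat units
#'
#' Aligns the complete units of a decomposed cluster column-by-column.
#' Cassette intervals (S, Y1, Y2) anchor the alignment by role; each
#' cassette and inter-cassette spacer is aligned against the corresponding
#' segment of the first unit with a simple global pairwise scheme (match
#' +1, mismatch -1, gap -2). The column space is the first unit's
#' coordinates: bases of other units inserted relative to it are counted
#' and excluded (they are minority columns under the consensus <50%%
#' presence rule); a warning is raised if an insertion would be shared by
#' half or more of the units.
#'
#' @param region cluster region sequence (character), cassettes on its plus
#'   strand.
#' @param units unit table from [decompose_repeats()] (complete units are
#'   used; incomplete ones are excluded with a warning).
#' @param genes cassette annotation data.frame (id, start, end,
#'   intron_start, intron_end).
#' @return list with `matrix` (units x columns character matrix, "-" =
#'   deletion), `columns` (data.frame: segment, role, ref_pos, is_intron,
#'   intron_label), and `unit_pos` (integer matrix of 0-based within-unit
#'   positions per column, NA at deletions).
#' @export
align_units <- function(region, units, genes) {
  if (any(!units$complete)) {
    warning(sprintf("%d incomplete unit(s) excluded from alignment",
                    sum(!units$complete)))
    units <- units[units$complete, , drop = FALSE]
  }
  stopifnot(nrow(units) >= 1)
  n <- nrow(units)
  seg_tabs <- lapply(seq_len(n), function(i) unit_segments(units[i, ], genes))
  ref_segs <- seg_tabs[[1]]
  cols <- list(); mat_cols <- list(); pos_cols <- list()
  total_ins <- integer(n)
  for (sj in seq_len(nrow(ref_segs))) {
    seg_name <- ref_segs$segment[sj]
    ref_seq <- substr0(region, ref_segs$start[sj], ref_segs$end[sj])
    nr <- nchar(ref_seq)
    if (nr == 0) next
    resid <- matrix("-", nrow = n, ncol = nr)
    upos <- matrix(NA_integer_, nrow = n, ncol = nr)
    for (i in seq_len(n)) {
      st <- seg_tabs[[i]]
      useq <- substr0(region, st$start[sj], st$end[sj])
      al <- align_one_segment(ref_seq, useq)
      resid[i, ] <- al$residues
      # convert within-segment positions to within-unit positions
      upos[i, ] <- al$unit_pos + (st$start[sj] - units$start[i])
      total_ins[i] <- total_ins[i] + al$insertions
    }
    role <- if (seg_name %in% c("S", "Y1", "Y2")) seg_name else "spacer"
    is_intron <- rep(FALSE, nr)
    intron_label <- rep(NA_character_, nr)
    if (role %in% c("Y1", "Y2")) {
      id <- units[[paste0(tolower(role), "_id")]][1]
      g <- genes[genes$id == id, ]
      if (!is.na(g$intron_start)) {
        rel <- (g$intron_start - g$start):(g$intron_end - g$start - 1L)
        is_intron[rel + 1L] <- TRUE
        intron_label[rel + 1L] <- if (role == "Y1") "i1" else "i2"
      }
    }
    cols[[length(cols) + 1L]] <- data.frame(
      segment = seg_name, role = role, ref_pos = 0:(nr - 1L),
      is_intron = is_intron, intron_label = intron_label,
      stringsAsFactors = FALSE)
    mat_cols[[length(mat_cols) + 1L]] <- resid
    pos_cols[[length(pos_cols) + 1L]] <- upos
  }
  if (sum(total_ins) > 0 && mean(total_ins > 0) >= 0.5) {
    warning("insertions relative to the first unit are present in half or ",
            "more of the units; they are not representable in the column ",
            "space and were dropped")
  }
  list(matrix = do.call(cbind, mat_cols),
       columns = do.call(rbind, cols),
       unit_pos = do.call(cbind, pos_cols),
       unit_index = units$index,
       unit_start = units$start)
}

#' Build a degenerate consensus repeat reference
#'
#' Column rule outside blocked intervals: columns whose residues are
#' present in fewer than half of the units are dropped; kept columns take
#' the agreed base when all present residues match and the degenerate base
#' N when two or more distinct residues occur. Inside blocked intervals
#' (the mature, intron-free part of each role for which a MAJOR sequence is
#' supplied) the consensus is forced to that MAJOR sequence and never
#' contains N — intron columns are always left to the consensus rule, even
#' though they lie inside the cassette's genomic span.
#'
#' @param alignment output of [align_units()].
#' @param major_by_role named list/character vector of mature MAJOR
#'   sequences keyed by role (typically Y1 and Y2; S may be supplied too).
#' @return an object of class `consensus_reference`: list(sequence, mask
#'   (0-based N positions), blocked (data.frame role, start, end, source),
#'   introns (data.frame label, start, end), column_map (data.frame unit,
#'   unit_pos, cons_pos), n_units, dropped_columns).
#' @export
build_consensus <- function(alignment, major_by_role = list()) {
  mat <- alignment$matrix
  cols <- alignment$columns
  stopifnot(ncol(mat) == nrow(cols), ncol(mat) >= 1)
  n <- nrow(mat)
  blocked_col <- cols$role %in% names(major_by_role) & !cols$is_intron
  presence <- colMeans(mat != "-")
  keep <- blocked_col | presence >= 0.5
  cons <- character(ncol(mat))
  is_n <- logical(ncol(mat))
  for (j in which(keep & !blocked_col)) {
    res <- unique(mat[mat[, j] != "-", j])
    if (length(res) == 1) {
      cons[j] <- res
    } else {
      cons[j] <- "N"
      is_n[j] <- TRUE
    }
  }
  blocked_runs <- list()
  for (role in names(major_by_role)) {
    jj <- which(cols$role == role & !cols$is_intron)
    major <- as.character(major_by_role[[role]])
    if (length(jj) != nchar(major)) {
      stop(sprintf(
        "role %s: MAJOR sequence length (%d) does not match its %d mature columns",
        role, nchar(major), length(jj)))
    }
    cons[jj] <- seq_chars(major)
    is_n[jj] <- FALSE
  }
  # consensus coordinates of kept columns
  cons_pos <- cumsum(keep) - 1L
  kept <- which(keep)
  out_seq <- paste(cons[kept], collapse = "")
  mask <- cons_pos[kept][is_n[kept]]
  runs_of <- function(sel) {
    # contiguous runs (in consensus coordinates) of the selected kept columns
    p <- cons_pos[sel & keep]
    if (length(p) == 0) return(cbind(start = integer(0), end = integer(0)))
    br <- which(diff(p) != 1)
    cbind(start = p[c(1, br + 1)], end = p[c(br, length(p))] + 1L)
  }
  blocked <- list()
  for (role in names(major_by_role)) {
    r <- runs_of(cols$role == role & !cols$is_intron)
    blocked[[role]] <- data.frame(role = role, start = r[, "start"],
                                  end = r[, "end"],
                                  source = as.character(major_by_role[[role]]),
                                  stringsAsFactors = FALSE)
  }
  introns <- list()
  for (lab in stats::na.omit(unique(cols$intron_label))) {
    r <- runs_of(!is.na(cols$intron_label) & cols$intron_label == lab)
    introns[[lab]] <- data.frame(label = lab, start = r[, "start"],
                                 end = r[, "end"], stringsAsFactors = FALSE)
  }
  cmap <- list()
  for (i in seq_len(n)) {
    up <- alignment$unit_pos[i, kept]
    ok <- !is.na(up)
    cmap[[i]] <- data.frame(unit = alignment$unit_index[i],
                            unit_pos = up[ok], cons_pos = cons_pos[kept][ok],
                            stringsAsFactors = FALSE)
  }
  structure(
    list(sequence = out_seq, mask = mask,
         blocked = if (length(blocked) > 0) do.call(rbind, blocked) else
           data.frame(role = character(0), start = integer(0),
                      end = integer(0), source = character(0)),
         introns = if (length(introns) > 0) do.call(rbind, introns) else
           data.frame(label = character(0), start = integer(0),
                      end = integer(0)),
         column_map = do.call(rbind, cmap),
         n_units = n, dropped_columns = sum(!keep)),
    class = "consensus_reference")
}

#' @export
print.consensus_reference <- function(x, ...) {
  cat(sprintf("consensus repeat: %d bp from %d units; %d degenerate (N) positions, %d dropped columns\n",
              nchar(x$sequence), x$n_units, length(x$mask),
              x$dropped_columns))
  if (nrow(x$blocked) > 0) {
    cat("blocked intervals:\n")
    for (i in seq_len(nrow(x$blocked))) {
      cat(sprintf("  %s [%d, %d)\n", x$blocked$role[i], x$blocked$start[i],
                  x$blocked$end[i]))
    }
  }
  invisible(x)
}

#' Replace a tandem cluster with its consensus repeat in a genome
#'
#' Emits an edited genome in which the cluster interval is replaced by a
#' single consensus unit, plus a coordinate liftover: positions upstream of
#' the cluster are unchanged, positions downstream shift by the length
#' difference, and annotations overlapping the replaced interval are
#' flagged "collapsed" (their consensus coordinates, where a single unit
#' can be identified, come from the consensus column map).
#'
#' @param genome named character vector / DNAStringSet / FASTA path.
#' @param cluster list(chrom, start, end), 0-based half-open.
#' @param consensus a `consensus_reference`.
#' @param annotations optional annotation data.frame (chrom, start, end,
#'   ...) to lift.
#' @return list(genome, annotations, shift, lift) where `lift` is a
#'   vectorized function old position -> new position (NA inside the
#'   replaced interval) for the cluster chromosome.
#' @export
emit_reference <- function(genome, cluster, consensus, annotations = NULL) {
  genome <- as_genome(genome)
  chrom <- cluster$chrom
  old <- genome[[chrom]]
  stopifnot(!is.null(old), cluster$start >= 0, cluster$end <= nchar(old),
            cluster$end > cluster$start)
  cons_len <- nchar(consensus$sequence)
  shift <- cons_len - (cluster$end - cluster$start)
  genome[[chrom]] <- paste0(substr0(old, 0, cluster$start),
                            consensus$sequence,
                            substr0(old, cluster$end, nchar(old)))
  lift <- function(pos) {
    out <- ifelse(pos < cluster$start, pos,
                  ifelse(pos >= cluster$end, pos + shift, NA_real_))
    as.integer(out)
  }
  lifted <- NULL
  if (!is.null(annotations)) {
    lifted <- annotations
    lifted$status <- "unchanged"
    on_chrom <- lifted$chrom == chrom
    overlaps <- on_chrom & lifted$start < cluster$end &
      lifted$end > cluster$start
    downstream <- on_chrom & !overlaps & lifted$start >= cluster$end
    lifted$start[downstream] <- lifted$start[downstream] + shift
    lifted$end[downstream] <- lifted$end[downstream] + shift
    lifted$status[downstream] <- "shifted"
    lifted$status[overlaps] <- "collapsed"
    lifted$start[overlaps] <- NA_integer_
    lifted$end[overlaps] <- NA_integer_
  }
  list(genome = genome, annotations = lifted, shift = shift, lift = lift,
       cluster = cluster)
}
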