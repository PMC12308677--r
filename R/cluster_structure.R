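#' Decompose a tandem cluster region into S-Y1-Y2 repeat units
#'
#' Cassettes are walked in cluster-strand order; each Ser cassette opens a
#' unit and takes the next two Tyr cassettes as Y1 and Y2. Cassette runs
#' that admit no S,Y,Y grouping (e.g. an orphan Tyr, or two Ser with a
#' single Tyr between) produce a structural-anomaly record and the walk
#' skips forward one cassette. A trailing Ser with fewer than two Tyr left
#' becomes a partial unit, retained with `complete = FALSE` and excluded
#' from composition statistics. Unit intervals are delimited at the
#' midpoints between consecutive units and so tile the span from the first
#' to the last cassette.
#'
#' @param cassettes annotation data.frame (id, start, end, isotype), all on
#'   the cluster strand; coordinates 0-based half-open.
#' @param cluster_strand "+" or "-": the strand on which the S,Y,Y grammar
#'   reads left to right.
#' @return data.frame of units (index, start, end, s_id, y1_id, y2_id,
#'   complete) with an `anomalies` attribute (data.frame id, reason).
#' @export
decompose_repeats <- function(cassettes, cluster_strand = "+") {
  ord <- order(cassettes$start)
  if (cluster_strand == "-") ord <- rev(ord)
  cs <- cassettes[ord, , drop = FALSE]
  n <- nrow(cs)
  units <- list(); anomalies <- list()
  i <- 1L
  idx <- 0L
  while (i <= n) {
    if (cs$isotype[i] != "Ser") {
      anomalies[[length(anomalies) + 1L]] <- data.frame(
        id = cs$id[i], reason = "Tyr cassette outside any S,Y,Y unit",
        stringsAsFactors = FALSE)
      i <- i + 1L
      next
    }
    remaining <- n - i
    take <- cs[i:min(n, i + 2L), , drop = FALSE]
    if (remaining >= 2 && all(take$isotype[2:3] == "Tyr")) {
      idx <- idx + 1L
      units[[idx]] <- data.frame(
        index = idx,
        start = min(take$start), end = max(take$end),
        s_id = take$id[1], y1_id = take$id[2], y2_id = take$id[3],
        complete = TRUE, stringsAsFactors = FALSE)
      i <- i + 3L
    } else if (remaining < 2 && (remaining == 0 ||
                                 all(take$isotype[-1] == "Tyr"))) {
      # trailing partial unit
      idx <- idx + 1L
      units[[idx]] <- data.frame(
        index = idx,
        start = min(take$start), end = max(take$end),
        s_id = take$id[1],
        y1_id = if (remaining >= 1) take$id[2] else NA_character_,
        y2_id = NA_character_,
        complete = FALSE, stringsAsFactors = FALSE)
      i <- i + 1L + remaining
    } else {
      anomalies[[length(anomalies) + 1L]] <- data.frame(
        id = cs$id[i],
        reason = "Ser cassette not followed by two Tyr cassettes",
        stringsAsFactors = FALSE)
      i <- i + 1L
    }
  }
  units <- if (length(units) > 0) do.call(rbind, units) else
    data.frame(index = integer(0), start = integer(0), end = integer(0),
               s_id = character(0), y1_id = character(0),
               y2_id = character(0), complete = logical(0))
  # widen unit intervals to the midpoints between genomically adjacent units
  if (nrow(units) > 1) {
    g <- order(units$start)
    for (k in seq_len(length(g) - 1)) {
      a <- g[k]; b <- g[k + 1]
      mid <- (units$end[a] + units$start[b]) %/% 2L
      units$end[a] <- mid
      units$start[b] <- mid
    }
  }
  attr(units, "anomalies") <- if (length(anomalies) > 0)
    do.call(rbind, anomalies) else
    data.frame(id = character(0), reason = character(0))
  units
}

#' Attach family and intron-variant labels to repeat-unit cassettes
#'
#' @param units unit table from [decompose_repeats()].
#' @param gene_labels data.frame (id, rank_label) from
#'   [classify_families()].
#' @param intron_labels optional data.frame (id, var_label) from
#'   [cluster_intron_variants()].
#' @param genes optional annotation data.frame used to carry pseudogene
#'   flags onto cassettes.
#' @return `units` with s_rank/y1_rank/y2_rank (and *_var, *_pseudo when
#'   the corresponding inputs are given). Any cassette id missing from
#'   `gene_labels` is a hard error naming the id.
#' @export
assign_cassettes <- function(units, gene_labels, intron_labels = NULL,
                             genes = NULL) {
  lookup <- function(ids, table, col, required) {
    out <- table[[col]][match(ids, table$id)]
    missing <- !is.na(ids) & is.na(out)
    if (required && any(missing)) {
      stop(sprintf("cassette id '%s' missing from class tables",
                   ids[missing][1]))
    }
    out
  }
  for (slot in c("s", "y1", "y2")) {
    ids <- units[[paste0(slot, "_id")]]
    units[[paste0(slot, "_rank")]] <- lookup(ids, gene_labels, "rank_label",
                                             required = TRUE)
    if (!is.null(intron_labels)) {
      units[[paste0(slot, "_var")]] <- lookup(ids, intron_labels,
                                              "var_label", required = FALSE)
    }
    if (!is.null(genes)) {
      units[[paste0(slot, "_pseudo")]] <- lookup(ids, genes,
                                                 "pseudogene_flag",
                                                 required = FALSE)
    }
  }
  units
}

#' MAJOR fraction at the Y1 and Y2 positions
#'
#' @param units labelled unit table from [assign_cassettes()]; partial
#'   units are excluded.
#' @return data.frame (position, fraction_major, n_units).
#' @export
positional_composition <- function(units) {
  cu <- units[units$complete, , drop = FALSE]
  if (nrow(cu) == 0) stop("no complete units")
  data.frame(
    position = c("Y1", "Y2"),
    fraction_major = c(mean(cu$y1_rank == "MAJOR"),
                       mean(cu$y2_rank == "MAJOR")),
    n_units = nrow(cu), stringsAsFactors = FALSE)
}

#' Segment a cluster into core and variable regions
#'
#' A unit is a MAJOR-pair when both its Y1 and Y2 cassettes carry the MAJOR
#' rank. Each complete unit is scored by the MAJOR-pair fraction of its
#' centered window of `w` units (truncated at the cluster edges); maximal
#' runs of units whose window fraction reaches `tau` form candidate cores.
#' The longest core is the core region (CR, ties to the leftmost), and the
#' nearest disjoint core downstream of it is CR*. Units upstream of CR form
#' the upstream variable region (UVR); units downstream of the last
#' assigned core form the downstream variable region (DVR); everything else
#' (including partial units) is `unassigned`. With the defaults (w = 3,
#' tau = 2/3) a contiguous MAJOR-pair block flanked by pair-free units is
#' recovered exactly.
#'
#' @param units labelled unit table from [assign_cassettes()].
#' @param w window size in units (>= 1).
#' @param tau MAJOR-pair fraction threshold in (0, 1].
#' @return `units` with a `region_label` column; segmentation parameters
#'   are recorded in the `params` attribute.
#' @export
segment_regions <- function(units, w = 3L, tau = 2 / 3) {
  stopifnot(w >= 1, tau > 0, tau <= 1)
  units$region_label <- "unassigned"
  cu_idx <- which(units$complete)
  m <- length(cu_idx)
  pair <- units$y1_rank[cu_idx] == "MAJOR" & units$y2_rank[cu_idx] == "MAJOR"
  cores <- list()
  if (m >= 1) {
    h <- (w - 1L) %/% 2L
    qualifies <- vapply(seq_len(m), function(i) {
      win <- max(1L, i - h):min(m, i + (w - 1L - h))
      mean(pair[win]) >= tau
    }, TRUE)
    r <- rle(qualifies)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      cores[[length(cores) + 1L]] <- c(starts[k], ends[k])
    }
  }
  if (length(cores) > 0) {
    lens <- vapply(cores, function(c) c[2] - c[1] + 1, 1)
    cr_i <- which(lens == max(lens))[1]
    cr <- cores[[cr_i]]
    units$region_label[cu_idx[cr[1]:cr[2]]] <- "CR"
    downstream <- Filter(function(c) c[1] > cr[2], cores)
    last_end <- cr[2]
    if (length(downstream) > 0) {
      starts_ds <- vapply(downstream, `[`, 1, 1)
      cr2 <- downstream[[which.min(starts_ds)]]
      units$region_label[cu_idx[cr2[1]:cr2[2]]] <- "CR*"
      last_end <- max(last_end, cr2[2])
    }
    before <- cu_idx[seq_len(m) < cr[1]]
    after <- cu_idx[seq_len(m) > last_end]
    units$region_label[before] <- "UVR"
    units$region_label[after] <- "DVR"
  }
  attr(units, "params") <- list(w = w, tau = tau)
  units
}
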