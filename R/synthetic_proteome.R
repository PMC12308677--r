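AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Generate a synthetic proteome with planted SP(n)Y-repeat proteins
#'
#' Background proteins are drawn from uniform amino-acid frequencies over
#' the 20 standard residues; repeat proteins are built directly from the
#' requested number of SP(n)Y motifs joined by a linker, mimicking
#' extensin-like tandem-repeat architecture.
#'
#' @param n_background number of background proteins.
#' @param repeat_protein_specs list of lists, each with `n_motifs`,
#'   `n_prolines` (>= 1) and `linker` (possibly "").
#' @param seed integer RNG seed.
#' @param background_length_range integer length-2 range from which
#'   background protein lengths are drawn uniformly.
#' @return list(proteins = data.frame(id, seq), truth = data.frame of
#'   planted motif spans (id, start, end), 0-based half-open).
#' @export
generate_proteome <- function(n_background, repeat_protein_specs = list(),
                              seed = 1L,
                              background_length_range = c(100L, 500L)) {
  stopifnot(n_background >= 0)
  for (sp in repeat_protein_specs) {
    stopifnot(sp$n_prolines >= 1, sp$n_motifs >= 1)
  }
  withr::with_seed(seed, {
    ids <- character(0); seqs <- character(0)
    truth <- list()
    if (n_background > 0) {
      lens <- sample(background_length_range[1]:background_length_range[2],
                     n_background, replace = TRUE)
      ids <- sprintf("bg%04d", seq_len(n_background))
      seqs <- vapply(lens, random_protein, "", alphabet = AA_ALPHABET)
    }
    for (k in seq_along(repeat_protein_specs)) {
      sp <- repeat_protein_specs[[k]]
      motif <- paste0("S", strrep("P", sp$n_prolines), "Y")
      linker <- if (is.null(sp$linker)) "" else sp$linker
      seq <- paste(rep(motif, sp$n_motifs), collapse = linker)
      id <- sprintf("rep%02d", k)
      ids <- c(ids, id); seqs <- c(seqs, seq)
      step <- nchar(motif) + nchar(linker)
      starts <- (seq_len(sp$n_motifs) - 1L) * step
      truth[[k]] <- data.frame(id = id, start = starts,
                               end = starts + nchar(motif),
                               stringsAsFactors = FALSE)
    }
    list(proteins = data.frame(id = ids, seq = seqs,
                               stringsAsFactors = FALSE),
         truth = if (length(truth) > 0) do.call(rbind, truth) else
           data.frame(id = character(0), start = integer(0),
                      end = integer(0)))
  })
}

#' Write a proteome as FASTA
#'
#' @param proteins data.frame (id, seq).
#' @param path output FASTA path.
#' @export
write_proteome <- function(proteins, path) {
  ss <- Biostrings::AAStringSet(setNames(proteins$seq, proteins$id))
  Biostrings::writeXStringSet(ss, path)
}

#' Read a proteome FASTA
#'
#' @param path FASTA path.
#' @return data.frame (id, seq).
#' @export
read_proteome <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  data.frame(id = sub("\\s.*$", "", names(ss)), seq = as.character(ss),
             stringsAsFactors = FALSE, row.names = NULL)
}
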