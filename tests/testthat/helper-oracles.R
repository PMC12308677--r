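# Independent brute-force oracles, deliberately naive: each re-derives its
# answer from first principles so library-backed implementations are checked
# against a second route.

oracle_scan <- function(sequence, motif) {
  n <- nchar(sequence); m <- nchar(motif)
  if (n < m) return(integer(0))
  hits <- integer(0)
  for (off in 0:(n - m)) {
    if (substr(sequence, off + 1, off + m) == motif) hits <- c(hits, off)
  }
  hits
}

# pattern matching with N as wildcard (on the pattern side only)
oracle_pattern_scan <- function(sequence, pattern) {
  n <- nchar(sequence); m <- nchar(pattern)
  if (n < m) return(integer(0))
  pch <- strsplit(pattern, "")[[1]]
  hits <- integer(0)
  for (off in 0:(n - m)) {
    sch <- strsplit(substr(sequence, off + 1, off + m), "")[[1]]
    if (all(pch == "N" | pch == sch)) hits <- c(hits, off)
  }
  hits
}

oracle_msre <- function(sequence) {
  pats <- c(Bsp119I = "TTCGAA", MspI = "CCGG", HpyF3I = "CTNAG")
  offs <- c(Bsp119I = 2L, MspI = 0L, HpyF3I = 0L)
  out <- list()
  for (e in names(pats)) {
    st <- oracle_pattern_scan(sequence, pats[[e]])
    if (length(st) > 0) {
      out[[e]] <- data.frame(enzyme = e, start = st,
                             diag_pos = st + offs[[e]],
                             stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(enzyme = character(0), start = integer(0),
                      diag_pos = integer(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$enzyme), ]
  rownames(res) <- NULL
  res
}

# context from first principles: on the minus strand, work on the literal
# reverse complement string at the mirrored position
oracle_context <- function(reference, pos, strand) {
  if (strand == "-") {
    rc <- paste(rev(chartr("ACGTN", "TGCAN",
                           strsplit(reference, "")[[1]])), collapse = "")
    return(oracle_context(rc, nchar(reference) - 1L - pos, "+"))
  }
  n1 <- substr(reference, pos + 2, pos + 2)
  n2 <- substr(reference, pos + 3, pos + 3)
  acgt <- c("A", "C", "G", "T")
  if (!n1 %in% acgt) return("ambiguous")
  if (n1 == "G") return("CG")
  if (!n2 %in% acgt) return("ambiguous")
  if (n2 == "G") return("CHG") else return("CHH")
}

# exact-string grouping: returns class sizes (descending) and a membership
# map, ignoring all ordering conventions beyond size
oracle_group <- function(seqs) {
  classes <- split(seq_along(seqs), seqs)
  sizes <- sort(vapply(classes, length, 1L), decreasing = TRUE)
  list(n_classes = length(classes), sizes = unname(sizes),
       members = lapply(classes, sort))
}

# left-to-right maximal SP(n)Y scan written as an explicit state walk
oracle_spny <- function(sequence, n_min = 2, n_max = Inf) {
  ch <- strsplit(sequence, "")[[1]]
  n <- length(ch)
  spans <- list()
  i <- 1
  while (i <= n) {
    if (ch[i] == "S") {
      k <- 0
      while (i + 1 + k <= n && ch[i + 1 + k] == "P") k <- k + 1
      k <- min(k, n_max)
      if (k >= n_min && i + 1 + k <= n && ch[i + 1 + k] == "Y") {
        spans[[length(spans) + 1L]] <- c(i - 1L, i + 1L + k)
        i <- i + 2 + k
        next
      }
    }
    i <- i + 1
  }
  if (length(spans) == 0) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  m <- do.call(rbind, spans)
  data.frame(start = m[, 1], end = m[, 2])
}

# small shared fixtures -----------------------------------------------------

test_pool <- function() {
  data.frame(
    role = c("S", "Y1", "Y1", "Y2", "Y2"),
    label = c("S1", "YMAJ", "YMIN", "YMAJ", "YMIN"),
    mature = c("GGAGAGATGGCCGAGTGGTTAAGGCGACAGAC",
               "CCGACCTTAGCTCAGTTGGTAGAGCGGTGGAC",
               "CCGACCTTAGCTCAGTTGATAGAGCGGTGGAC",
               "CCGACCTTAGCTCAGTTGGTAGAGCGGTGGAC",
               "CCGACCTTAGCTCAGTTGATAGAGCGGTGGAC"),
    intron = c("", "ATGCAGATCC", "ATGCAGATCC", "ATGCAGATCC", "ATGCAGATCC"),
    intron_offset = c(0L, 15L, 15L, 15L, 15L),
    stringsAsFactors = FALSE)
}

random_cluster_spec <- function(seed) {
  withr::with_seed(seed, {
    n_units <- sample(3:8, 1)
    assign <- data.frame(
      S = rep("S1", n_units),
      Y1 = sample(c("YMAJ", "YMIN"), n_units, replace = TRUE),
      Y2 = sample(c("YMAJ", "YMIN"), n_units, replace = TRUE),
      stringsAsFactors = FALSE)
  })
  cluster_spec(nrow(assign), test_pool(), assign, spacer_length = 12L,
               flank_length = 40L, seed = seed + 1000L)
}

decompose_generated <- function(cluster) {
  decompose_repeats(cluster$genes[, c("id", "start", "end", "isotype")])
}
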