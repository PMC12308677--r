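#!/usr/bin/env Rscript

# Step 5: methylation workflow. Simulate bisulfite reads over the consensus
# cluster region under a wild-type-like methylome (CG > CHG > CHH) and a
# CG/CHG-hypomethylated condition, call per-cytosine methylation, bin it in
# 20-bp windows, compare conditions, and run the in-silico chop-PCR model
# over the MSRE sites of the consensus repeat.

suppressPackageStartupMessages(library(syytools))
dir.create("results", showWarnings = FALSE)

seed <- 1L
region <- as.character(
  Biostrings::readDNAStringSet("results/consensus_repeat.fa")[[1]])

wt_levels <- c(CG = 0.8, CHG = 0.4, CHH = 0.05)
hypo_levels <- c(CG = 0.3, CHG = 0.1, CHH = 0.05)

run_condition <- function(levels, cond, read_seed) {
  mt <- generate_methylome(region, levels)
  rs <- generate_bisulfite_reads(region, mt, coverage = 200,
                                 read_length = 100, seed = read_seed)
  track <- call_methylome(rs$reads, region)
  write_cx_table(track, sprintf("results/methylome_%s.tsv", cond),
                 chrom = "consensus_repeat_region")
  bin_methylation(track, c(0L, nchar(region)), b = 20L)
}
b_wt <- run_condition(wt_levels, "wt", seed + 12L)
b_hypo <- run_condition(hypo_levels, "hypo", seed + 13L)

write.table(b_wt, "results/binned_methylation_wt.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cmp <- compare_conditions(b_wt, b_hypo)
write.table(cmp$per_bin, "results/condition_deltas_per_bin.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(cmp$per_context, "results/condition_deltas_per_context.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

# chop-PCR over the diagnostic MSRE sites of the consensus repeat: take the
# wild-type per-context levels as the per-site methylation fractions
sites <- find_msre_sites(gsub("N", "A", region))
sites$m <- wt_levels[sites$diag_context]
chop <- do.call(rbind, lapply(split(sites, sites$enzyme), function(s) {
  res <- simulate_chop_pcr(s$m, delta = 1, n_molecules = 100000L,
                           seed = seed + 15L)
  data.frame(enzyme = s$enzyme[1], n_sites = nrow(s),
             analytic_fraction = res$analytic,
             monte_carlo_fraction = res$monte_carlo)
}))
chop <- rbind(chop, data.frame(enzyme = "Mock", n_sites = 0L,
                               analytic_fraction = 1,
                               monte_carlo_fraction = 1))
write.table(chop, "results/chop_pcr.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

print(cmp$per_context, row.names = FALSE)
print(chop, row.names = FALSE)
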