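#!/usr/bin/env Rscript

# Step 2 — per-site methylation states and differential methylation.
#
# Enumerates all strand-specific methylatable sites of the five motifs,
# assigns QC-passing modification calls (coverage >= 25, modQV >= 30) to
# sites for each condition, tabulates the per-motif summary (the shape of a
# published methylome table: counts, percent methylated, mean QV/coverage/
# IPD), and compares states between conditions: per-site gains and losses,
# per-gene change counts, and island/rest x coding/upstream tallies.

suppressMessages(library(symmeth))

in_dir <- "results/simulated_data"
out_dir <- "results/methylation"
if (!file.exists(file.path(in_dir, "genome.fasta")))
  stop("run analysis/01_simulate.R first")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

genome <- load_genome(file.path(in_dir, "genome.fasta"))
genes <- read_annotation(file.path(in_dir, "annotation.tsv"), genome)
island <- genomic_region(20001, 35000, "symbiosis_island")
sites <- scan_motifs(genome, default_motifs())

mod_files <- c(free_living = "mods_free.gff", bacteroid = "mods_bacteroid.gff")
states <- lapply(names(mod_files), function(cond) {
  recs <- qc_filter(read_modifications(file.path(in_dir, mod_files[[cond]])))
  assign_states(sites, recs, cond)
})
names(states) <- names(mod_files)

summary_tbl <- rbind(summarize_motifs(states$free_living),
                     summarize_motifs(states$bacteroid))
cat("Per-motif summary:\n")
print(summary_tbl[c("motif", "mod_type", "condition", "n_motifs",
                    "n_methylated", "pct_methylated")], row.names = FALSE)

m6a <- sites$mod_type == "m6A"   # m4C summarised above, excluded below
diff <- diff_sites(states$free_living[m6a, ], states$bacteroid[m6a, ])
cat("\nMethylation changes:", sum(diff$change != "unchanged"),
    "(", sum(diff$change == "gain"), "gains,",
    sum(diff$change == "loss"), "losses ) of", nrow(diff), "m6A sites\n")
in_isl <- diff$position >= island$start & diff$position <= island$end
cat("Share of changes inside the island:",
    round(100 * mean(in_isl[diff$change != "unchanged"]), 1), "%\n")

ups <- upstream_regions(genes, genome$length, max_len = 500)
gene_meth <- assign_to_genes(diff, genes, ups)
cat("Genes with at least one methylation change:",
    sum(gene_meth$total_changes > 0), "of", nrow(genes), "\n")

tally <- regional_tally(diff, island, genes, ups, genome$length)

write_tsv <- function(df, f) write.table(df, file.path(out_dir, f),
                                         sep = "\t", quote = FALSE,
                                         row.names = FALSE)
write_tsv(summary_tbl, "motif_summary.tsv")
write_tsv(diff, "diff_sites.tsv")
write_tsv(gene_meth, "gene_methylation.tsv")
write_tsv(tally, "regional_tally.tsv")
cat("Wrote tables to", out_dir, "\n")
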