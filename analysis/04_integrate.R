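#!/usr/bin/env Rscript

# Step 4 — integrate methylation with expression and export genome tracks.
#
# Joins the per-gene methylation-change counts with the differential
# expression calls into one table per gene, extracts the candidate list
# (>= 1 methylation state change AND significant expression change),
# reports the headline counts genome-wide and within the symbiosis island,
# and writes 1-kb sliding-window GC and percent-methylated bedGraph tracks
# for both conditions.

suppressMessages(library(symmeth))

sim_dir <- "results/simulated_data"
meth_dir <- "results/methylation"
de_path <- "results/expression/de_results.tsv"
out_dir <- "results/integration"
for (p in c(file.path(meth_dir, "gene_methylation.tsv"), de_path))
  if (!file.exists(p)) stop("run the earlier analysis steps first: missing ", p)
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

genome <- load_genome(file.path(sim_dir, "genome.fasta"))
genes <- read_annotation(file.path(sim_dir, "annotation.tsv"), genome)
island <- genomic_region(20001, 35000, "symbiosis_island")
gene_meth <- read.table(file.path(meth_dir, "gene_methylation.tsv"),
                        header = TRUE, sep = "\t", stringsAsFactors = FALSE)
de <- read.table(de_path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)

summaries <- integrate_meth_expr(gene_meth, de, genes, island)
counts <- integration_counts(summaries)

cat("Candidate genes (methylation change + significant expression change):",
    counts$n_candidates_genome, "of", counts$n_genes, "\n")
cat("Within the island:", counts$n_candidates_island, "of",
    counts$n_island_genes, "island genes (", counts$pct_island, "% )\n")
cat("Island candidates more expressed in the bacteroid:",
    counts$n_island_up_in_b, "; in culture:", counts$n_island_up_in_a, "\n")
cand <- summaries[summaries$candidate, ]
cat("Known symbiosis genes among candidates:",
    sum(cand$is_symbiosis_gene), "\n")

write.table(summaries, file.path(out_dir, "gene_summaries.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(counts, file.path(out_dir, "integration_counts.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# window tracks
gcw <- gc_windows(genome, 1000, 100)
write_bedgraph(gcw, file.path(out_dir, "gc.bedGraph"), genome$name,
               genome$length, "gc_fraction")
sites <- scan_motifs(genome, default_motifs())
for (f in c(free_living = "mods_free.gff", bacteroid = "mods_bacteroid.gff")) {
  cond <- sub("mods_(.*)\\.gff", "\\1", f)
  recs <- qc_filter(read_modifications(file.path(sim_dir, f)))
  st <- assign_states(sites, recs, cond)
  mw <- methylation_windows(st, genome, 1000, 100)
  for (m in unique(mw$motif)) {
    slug <- gsub("[^A-Za-z0-9]+", "_", m)
    sel <- mw$motif == m & mw$mod_type == "m6A"
    if (!any(sel)) next
    write_bedgraph(mw[sel, ], file.path(out_dir,
                   sprintf("meth_%s_%s.bedGraph", slug, cond)),
                   genome$name, genome$length,
                   sprintf("meth_%s_%s", slug, cond))
  }
}
cat("Wrote tables and bedGraph tracks to", out_dir, "\n")
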