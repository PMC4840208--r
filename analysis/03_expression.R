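#!/usr/bin/env Rscript

# Step 3 — differential gene expression.
#
# Quantile-normalizes the two-condition replicate matrix, averages spot
# replicates per gene, and tests each gene with a variance-moderated
# two-sample t (log2 fold change positive = higher in free-living culture);
# Benjamini-Hochberg control with significance at adjusted p < 0.001, the
# convention of the original expression re-analysis.

suppressMessages(library(symmeth))

in_dir <- "results/simulated_data"
out_dir <- "results/expression"
if (!file.exists(file.path(in_dir, "expression.tsv")))
  stop("run analysis/01_simulate.R first")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

header <- strsplit(readLines(file.path(in_dir, "expression.tsv"), n = 1), "\t")[[1]]
arrays <- setdiff(header, c("gene_id", "spot_id"))
conditions <- stats::setNames(sub("_[0-9]+$", "", arrays), arrays)

em <- read_expression(file.path(in_dir, "expression.tsv"), conditions)
em <- quantile_normalize(em)
em <- collapse_spots(em)
de <- differential_expression(em, "free_living", "bacteroid")

cat("Genes tested:", nrow(de), "\n")
cat("Significant at adjusted p < 0.001:", sum(de$significant),
    "(", sum(de$significant & de$log_fc < 0), "higher in bacteroid,",
    sum(de$significant & de$log_fc > 0), "higher in culture )\n")
cat("Largest |log2 FC| among significant genes:",
    round(max(abs(de$log_fc[de$significant])), 2), "\n")

write.table(de, file.path(out_dir, "de_results.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("Wrote", file.path(out_dir, "de_results.tsv"), "\n")
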