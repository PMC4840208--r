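# Joining methylation changes with differential expression; headline
# counts; sliding-window methylation profiles.

#' Join per-gene methylation changes with differential expression
#'
#' One row per annotated gene. A gene missing from either input gets zero
#' changes / a non-significant default; the counts of such genes are
#' reported via attributes \code{n_missing_meth} and \code{n_missing_de}.
#' A candidate gene has at least one methylation state change (coding or
#' upstream) and a significant expression change.
#'
#' @param gene_meth per-gene change table from \code{\link{assign_to_genes}}.
#' @param de differential-expression table from
#'   \code{\link{differential_expression}}.
#' @param genes annotation data.frame.
#' @param island a \code{\link{genomic_region}}; a gene is in the island iff
#'   its start coordinate lies inside it.
#' @return data.frame gene_id, in_island, meth_changes, changes_coding,
#'   changes_upstream, motifs_changed, log_fc, adj_p, de_significant,
#'   candidate, is_symbiosis_gene, product.
#' @export
integrate_meth_expr <- function(gene_meth, de, genes, island) {
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene ids in annotation")
  if (anyDuplicated(de$gene_id)) stop("duplicate gene ids in DE results")
  if (anyDuplicated(gene_meth$gene_id))
    stop("duplicate gene ids in methylation table")
  mi <- match(genes$gene_id, gene_meth$gene_id)
  di <- match(genes$gene_id, de$gene_id)
  out <- data.frame(
    gene_id = genes$gene_id,
    in_island = genes$start >= island$start & genes$start <= island$end,
    meth_changes = ifelse(is.na(mi), 0L, gene_meth$total_changes[mi]),
    changes_coding = ifelse(is.na(mi), 0L, gene_meth$changes_coding[mi]),
    changes_upstream = ifelse(is.na(mi), 0L, gene_meth$changes_upstream[mi]),
    motifs_changed = ifelse(is.na(mi), "", gene_meth$motifs_changed[mi]),
    log_fc = de$log_fc[di],
    adj_p = de$adj_p[di],
    de_significant = ifelse(is.na(di), FALSE, de$significant[di]),
    is_symbiosis_gene = genes$is_symbiosis_gene,
    product = genes$product,
    stringsAsFactors = FALSE)
  out$candidate <- out$meth_changes >= 1L & out$de_significant
  attr(out, "n_missing_meth") <- sum(is.na(mi))
  attr(out, "n_missing_de") <- sum(is.na(di))
  out
}

#' Headline integration counts
#'
#' Candidate counts genome-wide and within the symbiosis island, the island
#' candidate percentage (1 decimal), and the direction split of island
#' candidates (positive log fold change = higher in condition A /
#' free-living; negative = higher in condition B / symbiosis).
#'
#' @param summaries gene summary table from
#'   \code{\link{integrate_meth_expr}}.
#' @return one-row data.frame n_genes, n_meth_changed, n_de_significant,
#'   n_candidates_genome, n_island_genes, n_candidates_island, pct_island,
#'   n_island_up_in_b, n_island_up_in_a.
#' @export
integration_counts <- function(summaries) {
  isl <- summaries$in_island
  cand <- summaries$candidate
  n_island_genes <- sum(isl)
  n_cand_island <- sum(cand & isl)
  if (n_island_genes == 0L && n_cand_island > 0L)
    stop("island candidates without island genes")
  data.frame(
    n_genes = nrow(summaries),
    n_meth_changed = sum(summaries$meth_changes >= 1L),
    n_de_significant = sum(summaries$de_significant),
    n_candidates_genome = sum(cand),
    n_island_genes = n_island_genes,
    n_candidates_island = n_cand_island,
    pct_island = if (n_island_genes > 0L)
      annotated_fraction(n_cand_island, n_island_genes) else NA_real_,
    n_island_up_in_b = sum(cand & isl & summaries$log_fc < 0, na.rm = TRUE),
    n_island_up_in_a = sum(cand & isl & summaries$log_fc > 0, na.rm = TRUE),
    stringsAsFactors = FALSE)
}

#' Sliding-window methylated-site fractions
#'
#' For each motif, the fraction of its methylatable sites (both strands)
#' that are methylated, averaged over overlapping windows. Windows
#' containing no site of the motif yield NA, not 0 (a 0/0 proportion is
#' undefined). Circular genomes wrap across the origin.
#'
#' @param states state table from \code{\link{assign_states}} (one
#'   condition).
#' @param genome a \code{\link{genome_seq}}.
#' @param window window size in bp (default 1000).
#' @param step step between window starts (default 100).
#' @return data.frame motif, mod_type, condition, window_start,
#'   window_size, n_sites, value.
#' @export
methylation_windows <- function(states, genome, window = 1000, step = 100) {
  L <- genome$length
  stopifnot(window >= 1, window <= L, step >= 1)
  starts <- if (genome$circular) seq.int(1L, L, by = step)
            else seq.int(1L, L - window + 1L, by = step)
  grp <- unique(states[c("motif", "mod_type")])
  rows <- list()
  for (g in seq_len(nrow(grp))) {
    s <- states[states$motif == grp$motif[g] &
                states$mod_type == grp$mod_type[g], , drop = FALSE]
    tot <- meth <- numeric(L)
    cnt <- table(factor(s$position, levels = seq_len(L)))
    tot <- as.numeric(cnt)
    mcnt <- table(factor(s$position[s$methylated], levels = seq_len(L)))
    meth <- as.numeric(mcnt)
    if (genome$circular && window > 1L) {
      tot <- c(tot, tot[seq_len(window - 1L)])
      meth <- c(meth, meth[seq_len(window - 1L)])
    }
    ct <- c(0, cumsum(tot)); cm <- c(0, cumsum(meth))
    n_sites <- ct[starts + window] - ct[starts]
    n_meth <- cm[starts + window] - cm[starts]
    rows[[g]] <- data.frame(
      motif = grp$motif[g], mod_type = grp$mod_type[g],
      condition = s$condition[1],
      window_start = starts, window_size = window,
      n_sites = n_sites,
      value = ifelse(n_sites > 0, n_meth / n_sites, NA_real_),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Published per-motif methylome summary for B. diazoefficiens USDA 110
#'
#' The per-motif counts reported for the free-living and bacteroid
#' methylomes of \emph{Bradyrhizobium diazoefficiens} (motif, modified
#' position, modification type, methylated and total site counts, mean
#' modQV/coverage/IPD over methylated sites), shipped as a plain-text table.
#' Used by the worked examples to recompute the published percentages and
#' site differences from the raw counts.
#'
#' @return data.frame condition, motif, modified_position, mod_type,
#'   n_methylated, n_motifs, mean_qv, mean_coverage, mean_ipd.
#' @export
published_motif_counts <- function() {
  path <- system.file("extdata", "bdiazoefficiens_motif_counts.tsv",
                      package = "symmeth", mustWork = TRUE)
  read_tsv(path)
}

#' Published genome-scale constants for B. diazoefficiens USDA 110
#'
#' Coordinates and counts reported for the resequenced genome: symbiosis
#' island boundaries, genome lengths (resequenced and prior reference),
#' island gene counts and candidate-gene counts, and the KEGG-annotated
#' protein counts.
#'
#' @return a named list.
#' @export
published_genome_facts <- function() {
  list(
    genome_length = 9106064,
    previous_genome_length = 9105828,
    island_start = 1000419,
    island_end = 1681419,
    n_island_genes = 583,
    n_island_candidates = 89,
    n_genome_candidates = 768,
    n_kegg_annotated = 3278,
    n_protein_coding = 8265
  )
}
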