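# Differential methylation between two conditions: per-site state changes,
# per-motif summary tables, per-gene change counts, regional tallies.

#' Per-site methylation changes between two conditions
#'
#' Both state tables must cover exactly the same site set. \code{change} is
#' \code{"gain"} for unmethylated in A / methylated in B, \code{"loss"} for
#' the reverse, \code{"unchanged"} otherwise.
#'
#' @param states_a,states_b state tables from \code{\link{assign_states}}
#'   for condition A (reference, free-living by convention) and condition B.
#' @return data.frame motif, mod_type, position, strand, match_start,
#'   methylated_a, methylated_b, change.
#' @export
diff_sites <- function(states_a, states_b) {
  ka <- paste(states_a$motif, states_a$mod_type, states_a$position,
              states_a$strand, sep = "/")
  kb <- paste(states_b$motif, states_b$mod_type, states_b$position,
              states_b$strand, sep = "/")
  if (nrow(states_a) != nrow(states_b) || !setequal(ka, kb) ||
      anyDuplicated(ka) || anyDuplicated(kb))
    stop("site sets of the two conditions do not match")
  ord <- match(ka, kb)
  out <- states_a[c("motif", "mod_type", "position", "strand", "match_start")]
  out$methylated_a <- states_a$methylated
  out$methylated_b <- states_b$methylated[ord]
  out$change <- ifelse(out$methylated_a == out$methylated_b, "unchanged",
                       ifelse(out$methylated_b, "gain", "loss"))
  out
}

#' Per-motif methylation summary
#'
#' One row per (motif, mod_type): number of sites, number methylated,
#' percent methylated (2 decimals, half-up), and means of modQV, coverage
#' and IPD ratio over the methylated sites only. Percent is NA when a motif
#' has zero sites.
#'
#' @param states state table from \code{\link{assign_states}} (one
#'   condition, any number of motifs).
#' @return data.frame motif, modified_position (NA; kept when summarising
#'   via \code{\link{summarize_motifs}} with motif specs), mod_type,
#'   condition, n_motifs, n_methylated, pct_methylated, mean_qv,
#'   mean_coverage, mean_ipd.
#' @export
summarize_motifs <- function(states) {
  grp <- interaction(states$motif, states$mod_type, drop = TRUE)
  rows <- lapply(split(states, grp), function(s) {
    meth <- s[s$methylated, , drop = FALSE]
    data.frame(
      motif = s$motif[1], mod_type = s$mod_type[1],
      condition = s$condition[1],
      n_motifs = nrow(s), n_methylated = nrow(meth),
      pct_methylated = pct_methylated(nrow(meth), nrow(s)),
      mean_qv = if (nrow(meth)) mean(meth$mod_qv) else NA_real_,
      mean_coverage = if (nrow(meth)) mean(meth$coverage) else NA_real_,
      mean_ipd = if (nrow(meth)) mean(meth$ipd_ratio) else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$motif, out$mod_type), , drop = FALSE]
}

#' Summary for a single motif
#'
#' @param states state table restricted to one motif and condition.
#' @return a one-row summary (see \code{\link{summarize_motifs}}).
#' @export
summarize_motif <- function(states) {
  if (length(unique(paste(states$motif, states$mod_type))) > 1L)
    stop("summarize_motif expects states from a single motif")
  summarize_motifs(states)
}

#' Net loss of methylated sites between conditions
#'
#' \code{n_methylated_a - n_methylated_b} for one motif: positive when
#' condition B (e.g. the bacteroid) has fewer methylated sites.
#'
#' @param summary_a,summary_b one-row summaries of the same motif over the
#'   same site universe.
#' @return signed count.
#' @export
methylation_loss <- function(summary_a, summary_b) {
  if (summary_a$motif != summary_b$motif ||
      summary_a$mod_type != summary_b$mod_type)
    stop("summaries are for different motifs")
  if (summary_a$n_motifs != summary_b$n_motifs)
    stop("summaries cover different site universes")
  summary_a$n_methylated - summary_b$n_methylated
}

# membership of positions in an IRanges set
pos_in <- function(pos, ranges) {
  IRanges::overlapsAny(IRanges::IRanges(pos, pos), ranges)
}

#' Attribute changed sites to genes by region membership
#'
#' Each changed site is attributed to every gene whose coding region or
#' upstream (5'-UTR) region contains its position; a site falling in the
#' shared intergenic gap upstream of two divergent genes counts toward both.
#' Sites contained in no coding or upstream region are tallied as
#' intergenic-unassigned (attribute \code{n_intergenic_unassigned}).
#'
#' @param diff diff-site table from \code{\link{diff_sites}}.
#' @param genes annotation data.frame.
#' @param upstream upstream-region table from
#'   \code{\link{upstream_regions}}.
#' @return data.frame gene_id, changes_coding, changes_upstream,
#'   total_changes, motifs_changed (comma-separated), one row per annotated
#'   gene (zero rows included).
#' @export
assign_to_genes <- function(diff, genes, upstream) {
  changed <- diff[diff$change != "unchanged", , drop = FALSE]
  bodies <- IRanges::IRanges(genes$start, genes$end)
  ups <- upstream[upstream$width > 0L, , drop = FALSE]
  upr <- IRanges::IRanges(ups$start, ups$end)
  n <- nrow(genes)
  cc <- cu <- integer(n)
  motifs <- replicate(n, character(0), simplify = FALSE)
  assigned <- logical(nrow(changed))
  if (nrow(changed)) {
    pts <- IRanges::IRanges(changed$position, changed$position)
    ovc <- IRanges::findOverlaps(pts, bodies)
    ovu <- IRanges::findOverlaps(pts, upr)
    if (length(ovc)) {
      qi <- S4Vectors::queryHits(ovc); gi <- S4Vectors::subjectHits(ovc)
      assigned[qi] <- TRUE
      t1 <- table(factor(gi, levels = seq_len(n)))
      cc <- as.integer(t1)
      for (j in seq_along(qi))
        motifs[[gi[j]]] <- union(motifs[[gi[j]]], changed$motif[qi[j]])
    }
    if (length(ovu)) {
      qi <- S4Vectors::queryHits(ovu)
      gi <- match(ups$gene_id[S4Vectors::subjectHits(ovu)], genes$gene_id)
      assigned[qi] <- TRUE
      t2 <- table(factor(gi, levels = seq_len(n)))
      cu <- as.integer(t2)
      for (j in seq_along(qi))
        motifs[[gi[j]]] <- union(motifs[[gi[j]]], changed$motif[qi[j]])
    }
  }
  out <- data.frame(
    gene_id = genes$gene_id,
    changes_coding = cc,
    changes_upstream = cu,
    total_changes = cc + cu,
    motifs_changed = vapply(motifs, function(m) paste(sort(m), collapse = ","), ""),
    stringsAsFactors = FALSE)
  attr(out, "n_intergenic_unassigned") <- sum(!assigned)
  out
}

#' Regional methylation tallies
#'
#' For each motif, region (genome / island / rest) and compartment (coding /
#' upstream): the number of motif sites, methylated sites per condition,
#' changed sites, and densities per kb of compartment sequence within the
#' region. Compartment sequence is the union of gene bodies (coding) or of
#' upstream regions (upstream) intersected with the region.
#'
#' @param diff diff-site table from \code{\link{diff_sites}}.
#' @param island a \code{\link{genomic_region}} for the symbiosis island.
#' @param genes annotation data.frame.
#' @param upstream upstream-region table.
#' @param genome_length genome length in bp.
#' @return data.frame region, compartment, motif, mod_type, compartment_bp,
#'   n_sites, n_meth_a, n_meth_b, n_changed, sites_per_kb, changes_per_kb.
#' @export
regional_tally <- function(diff, island, genes, upstream, genome_length) {
  if (island$end > genome_length) stop("island outside genome")
  isl <- IRanges::IRanges(island$start, island$end)
  coding <- IRanges::reduce(IRanges::IRanges(genes$start, genes$end))
  ups <- upstream[upstream$width > 0L, , drop = FALSE]
  upreg <- IRanges::reduce(IRanges::IRanges(ups$start, ups$end))
  comp_ranges <- list(coding = coding, upstream = upreg)
  in_island_site <- pos_in(diff$position, isl)

  region_bp <- function(comp, region) {
    r <- switch(region,
                genome = comp,
                island = IRanges::intersect(comp, isl),
                rest = IRanges::setdiff(comp, isl))
    sum(IRanges::width(r))
  }
  site_in_region <- function(region) switch(
    region,
    genome = rep(TRUE, nrow(diff)),
    island = in_island_site,
    rest = !in_island_site)

  grp <- unique(diff[c("motif", "mod_type")])
  rows <- list()
  for (g in seq_len(nrow(grp))) {
    gi <- diff$motif == grp$motif[g] & diff$mod_type == grp$mod_type[g]
    for (comp in names(comp_ranges)) {
      in_comp <- pos_in(diff$position, comp_ranges[[comp]])
      for (region in c("genome", "island", "rest")) {
        sel <- gi & in_comp & site_in_region(region)
        bp <- region_bp(comp_ranges[[comp]], region)
        ns <- sum(sel)
        rows[[length(rows) + 1L]] <- data.frame(
          region = region, compartment = comp,
          motif = grp$motif[g], mod_type = grp$mod_type[g],
          compartment_bp = bp,
          n_sites = ns,
          n_meth_a = sum(diff$methylated_a[sel]),
          n_meth_b = sum(diff$methylated_b[sel]),
          n_changed = sum(diff$change[sel] != "unchanged"),
          sites_per_kb = if (bp > 0) 1000 * ns / bp else NA_real_,
          changes_per_kb = if (bp > 0)
            1000 * sum(diff$change[sel] != "unchanged") / bp else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
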