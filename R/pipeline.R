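# End-to-end driver: from genome + annotation + two modification files +
# expression matrix to all integration tables and window tracks.

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

#' Default pipeline configuration
#'
#' @return named list of every tunable threshold with its default:
#'   min_coverage 25, min_qv 30 (call QC); de_alpha 0.001 (BH-adjusted
#'   significance); window 1000 / step 100 bp (sliding windows);
#'   upstream_max_len 500 bp; circular TRUE; include_m4C FALSE (m4C calls
#'   are summarised but excluded from differential analysis); shrink TRUE /
#'   d0 4 (variance moderation).
#' @export
pipeline_defaults <- function() {
  list(min_coverage = 25, min_qv = 30, de_alpha = 0.001,
       window = 1000L, step = 100L, upstream_max_len = 500L,
       circular = TRUE, include_m4C = FALSE, shrink = TRUE, d0 = 4)
}

#' Run the full methylation-expression integration pipeline
#'
#' Stages: load genome and annotation; enumerate motif sites; read and
#' QC-filter both conditions' modification calls; assign per-site states;
#' per-motif summaries; per-site differential methylation; per-gene change
#' attribution; regional tallies; differential expression; gene-level
#' integration and headline counts; GC and per-motif methylation window
#' tracks. All tables are written to \code{out_dir} as TSV, tracks as
#' bedGraph, plus a \code{run_log.yaml} echoing every threshold. Outputs
#' are byte-identical across reruns with the same inputs and config.
#'
#' @param config a named list (or path to a YAML file) with entries:
#'   \code{genome_fasta}, \code{annotation}, \code{modifications_a},
#'   \code{modifications_b}, \code{condition_a}, \code{condition_b},
#'   \code{expression}, \code{arrays} (named list array -> condition),
#'   \code{island_start}, \code{island_end}, \code{out_dir}, and any
#'   overrides of \code{\link{pipeline_defaults}}.
#' @return invisibly, a list with every intermediate table and the output
#'   paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defs <- pipeline_defaults()
  for (k in names(defs)) if (is.null(config[[k]])) config[[k]] <- defs[[k]]
  required <- c("genome_fasta", "annotation", "modifications_a",
                "modifications_b", "condition_a", "condition_b",
                "expression", "arrays", "island_start", "island_end",
                "out_dir")
  miss <- setdiff(required, names(config))
  if (length(miss)) stop("pipeline config missing: ", paste(miss, collapse = ", "))

  genome <- stage("load_genome",
                  load_genome(config$genome_fasta, circular = config$circular))
  genes <- stage("read_annotation", read_annotation(config$annotation, genome))
  island <- genomic_region(config$island_start, config$island_end,
                           "symbiosis_island")
  motifs <- default_motifs(include_m4C = TRUE)
  sites <- stage("scan_motifs", scan_motifs(genome, motifs))
  recs_a <- stage("read_modifications_a",
                  qc_filter(read_modifications(config$modifications_a),
                            config$min_coverage, config$min_qv))
  recs_b <- stage("read_modifications_b",
                  qc_filter(read_modifications(config$modifications_b),
                            config$min_coverage, config$min_qv))
  states_a <- stage("assign_states",
                    assign_states(sites, recs_a, config$condition_a))
  states_b <- stage("assign_states",
                    assign_states(sites, recs_b, config$condition_b))
  summary_tbl <- rbind(summarize_motifs(states_a), summarize_motifs(states_b))

  keep <- if (config$include_m4C) rep(TRUE, nrow(sites))
          else sites$mod_type == "m6A"
  diff <- stage("diff_sites",
                diff_sites(states_a[keep, , drop = FALSE],
                           states_b[keep, , drop = FALSE]))
  ups <- stage("upstream_regions",
               upstream_regions(genes, genome$length, config$upstream_max_len))
  gene_meth <- stage("assign_to_genes", assign_to_genes(diff, genes, ups))
  tally <- stage("regional_tally",
                 regional_tally(diff, island, genes, ups, genome$length))

  arr <- unlist(config$arrays)
  em <- stage("read_expression", read_expression(config$expression, arr))
  em <- stage("quantile_normalize", quantile_normalize(em))
  em <- stage("collapse_spots", collapse_spots(em))
  de <- stage("differential_expression",
              differential_expression(em, config$condition_a,
                                      config$condition_b,
                                      alpha = config$de_alpha,
                                      shrink = config$shrink, d0 = config$d0))

  summaries <- stage("integrate",
                     integrate_meth_expr(gene_meth, de, genes, island))
  counts <- stage("integration_counts", integration_counts(summaries))

  gcw <- stage("gc_windows", gc_windows(genome, config$window, config$step))
  mw_a <- stage("methylation_windows",
                methylation_windows(states_a, genome, config$window, config$step))
  mw_b <- stage("methylation_windows",
                methylation_windows(states_b, genome, config$window, config$step))

  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  wt <- function(df, name) {
    p <- file.path(out_dir, name); write_tsv(df, p); p
  }
  paths$motif_summary <- wt(summary_tbl, "motif_summary.tsv")
  paths$diff_sites <- wt(diff, "diff_sites.tsv")
  paths$gene_methylation <- wt(gene_meth, "gene_methylation.tsv")
  paths$regional_tally <- wt(tally, "regional_tally.tsv")
  paths$de_results <- wt(de, "de_results.tsv")
  paths$gene_summaries <- wt(summaries, "gene_summaries.tsv")
  paths$integration_counts <- wt(counts, "integration_counts.tsv")
  paths$gc_track <- file.path(out_dir, "gc.bedGraph")
  write_bedgraph(gcw, paths$gc_track, genome$name, genome$length, "gc_fraction")
  slug <- function(x) gsub("[^A-Za-z0-9]+", "_", x)
  for (mw in list(mw_a, mw_b)) {
    for (g in unique(paste(mw$motif, mw$mod_type, mw$condition, sep = "\r"))) {
      parts <- strsplit(g, "\r", fixed = TRUE)[[1]]
      sel <- mw$motif == parts[1] & mw$mod_type == parts[2] &
        mw$condition == parts[3]
      nm <- sprintf("meth_%s_%s_%s.bedGraph", slug(parts[1]), parts[2], parts[3])
      p <- file.path(out_dir, nm)
      write_bedgraph(mw[sel, , drop = FALSE], p, genome$name, genome$length,
                     sub("\\.bedGraph$", "", nm))
      paths[[nm]] <- p
    }
  }
  log_path <- file.path(out_dir, "run_log.yaml")
  log_cfg <- config[order(names(config))]
  yaml::write_yaml(log_cfg, log_path)
  paths$run_log <- log_path

  invisible(list(genome = genome, genes = genes, island = island,
                 sites = sites, states_a = states_a, states_b = states_b,
                 motif_summary = summary_tbl, diff = diff,
                 gene_methylation = gene_meth, regional_tally = tally,
                 de = de, gene_summaries = summaries,
                 integration_counts = counts,
                 gc_windows = gcw, meth_windows_a = mw_a, meth_windows_b = mw_b,
                 paths = paths))
}
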