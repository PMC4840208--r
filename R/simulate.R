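# Synthetic-data generator: genome with a lower-GC island, planted motif
# occurrences, two-condition modification calls with QC noise, and a
# two-condition expression matrix with planted log fold changes. Ground
# truth is recorded for every stage.

rate_key <- function(motif, mod_type) paste(motif, mod_type, sep = "|")

#' Simulation configuration with study-condition defaults
#'
#' Defaults emulate the B. diazoefficiens methylome study at desk scale:
#' a GC-rich (0.64) 100-kb circular genome with a lower-GC (0.59) island,
#' per-motif methylation probabilities taken from the published free-living
#' and bacteroid percentages (GANTC 0.9977 -> 0.9746, CRAGGAT m6A 0.9995 ->
#' 0.8749, GAGA(N)6RTG 1.0 -> 0.8260, CAY(N)6TCTC 0.9995 -> 0.8606, the
#' symbiosis-exclusive CCTTGAG 0 -> 0.8006, CRAGGAT m4C 0.1531 -> 0),
#' per-condition mean coverages of 130 and 64, three arrays per condition
#' with array noise sigma 0.25, and planted log2 fold changes recycled from
#' the nine published candidate-gene effect sizes.
#'
#' @param seed integer seed; every draw derives from it.
#' @param ... overrides for any default listed below.
#' @return a \code{sim_config} list.
#' @export
sim_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    genome_len = 100000L,
    gc_background = 0.64,
    gc_island = 0.59,
    island_start = 20001L,
    island_end = 35000L,
    gene_len = 900L,
    gene_gap = 300L,
    first_gene_start = 501L,
    upstream_max_len = 500L,
    plant_min_sites = 60L,
    rates_a = c("GANTC|m6A" = 0.9977, "CRAGGAT|m6A" = 0.9995,
                "GAGA(N)6RTG|m6A" = 1.0, "CAY(N)6TCTC|m6A" = 0.9995,
                "CCTTGAG|m6A" = 0.0, "CRAGGAT|m4C" = 0.1531),
    rates_b = c("GANTC|m6A" = 0.9746, "CRAGGAT|m6A" = 0.8749,
                "GAGA(N)6RTG|m6A" = 0.8260, "CAY(N)6TCTC|m6A" = 0.8606,
                "CCTTGAG|m6A" = 0.8006, "CRAGGAT|m4C" = 0.0),
    coverage_mean_a = 130, coverage_mean_b = 64, coverage_cv = 0.2,
    qv_mean_a = 136, qv_mean_b = 65, qv_sd = 8,
    ipd_mean_a = 5.0, ipd_mean_b = 4.0, ipd_sd = 0.5,
    subthreshold_fraction = 0,
    emit_unmethylated_records = FALSE,
    min_coverage = 25, min_qv = 30,
    condition_a = "free_living", condition_b = "bacteroid",
    arrays_per_condition = 3L,
    n_spots = 2L,
    n_array_only_genes = 1900L,
    baseline_mean = 8, baseline_sd = 1.5,
    expression_sigma = 0.25,
    de_fraction = 0.2,
    de_effects = c(3.06, 5.49, 4.60, 5.06, 4.55, 1.23, 0.89, 5.73, 0.78),
    prob_up_in_b = 0.88,
    de_alpha = 0.001,
    d0 = 4,
    power_threshold = 0.99,
    window = 1000L, step = 100L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown sim_config fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(cfg$island_end <= cfg$genome_len,
            all(cfg$rates_a >= 0 & cfg$rates_a <= 1),
            all(cfg$rates_b >= 0 & cfg$rates_b <= 1))
  structure(cfg, class = "sim_config")
}

# A methylatable base shared by occurrences of two different motifs would
# force one molecule to carry two independently drawn states. Such
# coincidences (a handful per 100 kb, driven by the dense GANTC motif
# landing on another motif's adenine) are eliminated from the simulated
# genome: the occurrence of the commoner motif is destroyed by flipping one
# of its constrained bases outside the other motif's window. Iterates until
# no cross-motif base sharing remains.
eliminate_motif_collisions <- function(chars, motifs, circular = TRUE,
                                       max_iter = 25L) {
  L <- length(chars)
  specs <- stats::setNames(motifs, vapply(motifs, `[[`, "", "name"))
  violate <- c(A = "C", C = "A", G = "T", T = "G", R = "C", Y = "A")
  wrap <- function(p) ((p - 1L) %% L) + 1L
  for (iter in seq_len(max_iter)) {
    genome <- genome_seq(paste(chars, collapse = ""), circular = circular)
    sites <- scan_motifs(genome, motifs)
    key <- paste(sites$position, sites$strand, sites$mod_type)
    dups <- unique(key[duplicated(key)])
    coll_keys <- dups[vapply(dups, function(k)
      length(unique(sites$motif[key == k])) > 1L, TRUE)]
    if (length(coll_keys) == 0L) return(chars)
    counts <- table(sites$motif)
    for (k in coll_keys) {
      rows <- sites[key == k, , drop = FALSE]
      victim <- rows[which.max(counts[rows$motif]), , drop = FALSE]
      others <- rows[rows$motif != victim$motif, , drop = FALSE]
      spec <- specs[[victim$motif]]
      pat <- if (victim$strand == "+") spec$iupac else revcomp(spec$iupac)
      pchars <- strsplit(pat, "", fixed = TRUE)[[1]]
      wpos <- wrap(victim$match_start + seq_len(spec$length) - 1L)
      protected <- unlist(lapply(seq_len(nrow(others)), function(j) {
        ok <- specs[[others$motif[j]]]$length
        wrap(others$match_start[j] + seq_len(ok) - 1L)
      }))
      flippable <- which(pchars %in% names(violate) & !(wpos %in% protected))
      if (length(flippable) == 0L)
        flippable <- which(pchars %in% names(violate))
      j <- flippable[length(flippable)]
      chars[wpos[j]] <- violate[[pchars[j]]]
    }
  }
  chars
}

# resolve degenerate letters to a concrete instance
resolve_iupac <- function(iupac) {
  chars <- strsplit(iupac, "", fixed = TRUE)[[1]]
  paste(vapply(chars, function(ch) switch(
    ch,
    R = sample(c("A", "G"), 1L),
    Y = sample(c("C", "T"), 1L),
    N = sample(c("A", "C", "G", "T"), 1L),
    ch), ""), collapse = "")
}

#' Simulate a genome with a lower-GC island and a tiled gene annotation
#'
#' Bases are i.i.d. with GC probability \code{gc_background} outside the
#' island and \code{gc_island} inside. Each of the four distinct forward
#' motif patterns (GANTC, CRAGGAT, GAGA(N)6RTG, CCTTGAG; the CAY partner
#' arises as the reverse complement of the bipartite motif) is additionally
#' planted \code{plant_min_sites} times at uniform positions, with
#' degenerate letters resolved at random, to guarantee a workable number of
#' sites for the rarer motifs. Genes of fixed length are tiled with fixed
#' intergenic gaps on alternating strands.
#'
#' @param config a \code{\link{sim_config}}. Draws come from the current
#'   RNG state; call \code{set.seed} (or use
#'   \code{\link{simulate_dataset}}) for reproducibility.
#' @return list: \code{genome} (a \code{genome_seq}), \code{genes}
#'   (annotation data.frame), \code{island} (a \code{genomic_region}).
#' @export
simulate_genome <- function(config) {
  L <- config$genome_len
  if (config$island_end - config$island_start + 1 > L)
    stop("island larger than genome")
  gc <- rep(config$gc_background, L)
  gc[config$island_start:config$island_end] <- config$gc_island
  is_gc <- stats::runif(L) < gc
  pick <- stats::runif(L) < 0.5
  chars <- ifelse(is_gc, ifelse(pick, "G", "C"), ifelse(pick, "A", "T"))
  for (pattern in c("GANTC", "CRAGGAT", "GAGANNNNNNRTG", "CCTTGAG")) {
    k <- nchar(pattern)
    for (i in seq_len(config$plant_min_sites)) {
      at <- sample.int(L - k + 1L, 1L)
      inst <- strsplit(resolve_iupac(pattern), "", fixed = TRUE)[[1]]
      chars[at:(at + k - 1L)] <- inst
    }
  }
  chars <- eliminate_motif_collisions(chars, default_motifs(include_m4C = TRUE))
  genome <- genome_seq(paste(chars, collapse = ""), name = "sim_genome",
                       circular = TRUE)
  starts <- seq.int(config$first_gene_start, by = config$gene_len + config$gene_gap,
                    length.out = (L - config$first_gene_start) %/%
                      (config$gene_len + config$gene_gap))
  starts <- starts[starts + config$gene_len - 1L <= L - 100L]
  n <- length(starts)
  strand <- rep(c("+", "-"), length.out = n)
  in_isl <- starts >= config$island_start & starts <= config$island_end
  genes <- data.frame(
    gene_id = ifelse(strand == "+", sprintf("blr%04d", seq_len(n)),
                     sprintf("bll%04d", seq_len(n))),
    start = starts,
    end = starts + config$gene_len - 1L,
    strand = strand,
    product = ifelse(in_isl, "symbiosis island protein", "hypothetical protein"),
    is_symbiosis_gene = in_isl & (seq_len(n) %% 5L == 0L),
    stringsAsFactors = FALSE)
  list(genome = genome, genes = genes,
       island = genomic_region(config$island_start, config$island_end,
                               "symbiosis_island"))
}

#' Simulate modification calls for one condition
#'
#' Each site is methylated independently with its motif's configured rate
#' for the condition; methylation state is shared between motifs whose
#' methylatable base coincides at the same (position, strand, type).
#' Methylated sites emit one record with coverage ~ round(Normal(mean,
#' cv*mean)) truncated at 1, modQV ~ Normal(mean, sd) truncated at 1, and
#' IPD ratio ~ Normal(mean, sd) truncated at 1.1. A configurable fraction of
#' methylated sites is given a sub-threshold modQV to exercise the QC
#' filter. Unmethylated sites emit no record by default
#' (\code{emit_unmethylated_records = TRUE} emits low-QV records instead).
#'
#' @param sites site table from \code{\link{scan_motifs}}.
#' @param config a \code{\link{sim_config}}.
#' @param condition \code{"A"} or \code{"B"} (selects rates/noise).
#' @return list: \code{records} (modification record data.frame, file
#'   order randomised is not needed -- site order), \code{truth} (sites plus
#'   methylated, passes_qc).
#' @export
simulate_modifications <- function(sites, config, condition = c("A", "B")) {
  condition <- match.arg(condition)
  rates <- if (condition == "A") config$rates_a else config$rates_b
  cmean <- if (condition == "A") config$coverage_mean_a else config$coverage_mean_b
  qmean <- if (condition == "A") config$qv_mean_a else config$qv_mean_b
  imean <- if (condition == "A") config$ipd_mean_a else config$ipd_mean_b
  key <- rate_key(sites$motif, sites$mod_type)
  miss <- setdiff(unique(key), names(rates))
  if (length(miss)) stop("no methylation rate configured for: ",
                         paste(miss, collapse = ", "))
  p <- unname(rates[key])
  meth <- stats::runif(nrow(sites)) < p
  # sites sharing a methylatable base share its state
  base_key <- paste(sites$position, sites$strand, sites$mod_type, sep = "/")
  first <- match(base_key, base_key)
  meth <- meth[first]

  n <- nrow(sites)
  coverage <- pmax(1, round(stats::rnorm(n, cmean, config$coverage_cv * cmean)))
  qv <- pmax(1, round(stats::rnorm(n, qmean, config$qv_sd), 1))
  ipd <- pmax(1.1, round(stats::rnorm(n, imean, config$ipd_sd), 2))
  sub <- meth & (stats::runif(n) < config$subthreshold_fraction)
  qv[sub] <- round(stats::runif(sum(sub), 2, config$min_qv - 0.5), 1)
  # share the draws within a duplicated base as well
  coverage <- coverage[first]; qv <- qv[first]; ipd <- ipd[first]; sub <- sub[first]

  passes <- meth & coverage >= config$min_coverage & qv >= config$min_qv
  truth <- sites
  truth$methylated <- meth
  truth$passes_qc <- passes

  emit <- if (config$emit_unmethylated_records) rep(TRUE, n) else meth
  emit <- emit & !duplicated(base_key)
  rec_qv <- qv
  if (config$emit_unmethylated_records)
    rec_qv[!meth] <- round(stats::runif(sum(!meth), 2, 15), 1)
  records <- data.frame(
    position = sites$position[emit], strand = sites$strand[emit],
    mod_type = sites$mod_type[emit], mod_qv = rec_qv[emit],
    coverage = coverage[emit], ipd_ratio = ipd[emit],
    stringsAsFactors = FALSE)
  records <- records[order(records$position, records$strand, records$mod_type), ,
                     drop = FALSE]
  rownames(records) <- NULL
  list(records = records, truth = truth)
}

# closed-form power of the (moderated) two-sample t at raw alpha
moderated_power <- function(effect, sigma, n_per_group, d0, alpha) {
  df_t <- 2 * n_per_group - 2 + d0
  ncp <- abs(effect) / (sigma * sqrt(2 / n_per_group))
  crit <- stats::qt(1 - alpha / 2, df_t)
  1 - stats::pt(crit, df_t, ncp) + stats::pt(-crit, df_t, ncp)
}

# detectability of planted effects under BH: the step-up threshold on raw p
# lies near alpha * R / m, with R the number of comfortably detectable
# effects; a first pass at the raw alpha estimates R, a second pass at the
# BH-effective alpha classifies each effect.
detectable_effects <- function(lfc_true, config) {
  n_genes <- length(lfc_true)
  pw_raw <- moderated_power(lfc_true, config$expression_sigma,
                            config$arrays_per_condition, config$d0,
                            config$de_alpha)
  r_hat <- max(1L, sum(lfc_true != 0 & pw_raw >= 0.5))
  alpha_bh <- config$de_alpha * r_hat / n_genes
  pw <- moderated_power(lfc_true, config$expression_sigma,
                        config$arrays_per_condition, config$d0, alpha_bh)
  lfc_true != 0 & pw >= config$power_threshold
}

#' Simulate a two-condition expression matrix with planted fold changes
#'
#' The array measures a transcriptome-scale gene set: the annotated genes
#' plus \code{n_array_only_genes} additional null genes with no genomic
#' annotation (real two-colour arrays cover the full gene complement, and
#' quantile normalization is only well behaved with thousands of rows --
#' at a few dozen rows it visibly distorts both null and planted fold
#' changes). The background genes are expression-null, so planted effects
#' stay a small fraction of the transcriptome -- the regime in which
#' quantile normalization is valid. Per-gene baselines ~
#' Normal(baseline_mean, baseline_sd); a
#' \code{de_fraction} of the annotated genes receive planted log2 fold changes whose
#' magnitudes recycle the configured effect sizes, directed toward
#' condition B with probability \code{prob_up_in_b}; spot/array noise ~
#' Normal(0, expression_sigma). The truth table records each gene's planted
#' effect and whether it is detectable: closed-form noncentral-t power of
#' the moderated test at the BH-effective significance threshold at least
#' \code{power_threshold}.
#'
#' @param genes annotation data.frame.
#' @param config a \code{\link{sim_config}}.
#' @return list: \code{em} (an \code{\link{expr_matrix}} keyed by spots),
#'   \code{truth} (gene_id, lfc_true, detectable).
#' @export
simulate_expression <- function(genes, config) {
  ids <- genes$gene_id
  if (config$n_array_only_genes > 0L)
    ids <- c(ids, sprintf("array%05d", seq_len(config$n_array_only_genes)))
  ng <- length(ids)
  n_ann <- nrow(genes)
  baseline <- stats::rnorm(ng, config$baseline_mean, config$baseline_sd)
  n_de <- floor(config$de_fraction * n_ann)
  de_idx <- sort(sample.int(n_ann, n_de))
  mag <- rep_len(config$de_effects, n_de)
  up_in_b <- stats::runif(n_de) < config$prob_up_in_b
  lfc_true <- numeric(ng)
  lfc_true[de_idx] <- ifelse(up_in_b, -mag, mag)

  npc <- config$arrays_per_condition
  arrays <- c(paste0(config$condition_a, "_", seq_len(npc)),
              paste0(config$condition_b, "_", seq_len(npc)))
  conds <- rep(c(config$condition_a, config$condition_b), each = npc)
  ns <- config$n_spots
  mu_a <- baseline
  mu_b <- baseline - lfc_true
  spot_gene <- rep(ids, each = ns)
  mu <- cbind(matrix(rep(mu_a, each = ns), ncol = 1)[, rep(1, npc)],
              matrix(rep(mu_b, each = ns), ncol = 1)[, rep(1, npc)])
  noise <- matrix(stats::rnorm(length(spot_gene) * 2 * npc,
                               0, config$expression_sigma),
                  nrow = length(spot_gene))
  vals <- mu + noise
  colnames(vals) <- arrays
  rownames(vals) <- paste0(spot_gene, "_s", rep(seq_len(ns), times = ng))
  em <- expr_matrix(vals, spot_gene, conds)
  truth <- data.frame(gene_id = ids, lfc_true = lfc_true,
                      detectable = detectable_effects(lfc_true, config),
                      stringsAsFactors = FALSE)
  list(em = em, truth = truth)
}

#' Generate a complete synthetic data set with ground truth
#'
#' Seeds the RNG from the config and generates, in order: the genome and
#' annotation, the motif site catalogue, modification calls for both
#' conditions, and the expression matrix. If \code{out_dir} is given, writes
#' genome.fasta, annotation.tsv, mods_free.gff, mods_bacteroid.gff,
#' expression.tsv and truth.json there (same seed => byte-identical files).
#'
#' The recorded truth includes the per-gene expected candidate sets:
#' \code{planted_candidates} (>= 1 QC-passing m6A methylation state change
#' and any planted expression effect) and \code{expected_candidates}
#' (change plus a detectable effect -- the set against which recovery
#' sensitivity is judged; small planted effects below the power threshold
#' are legitimate misses).
#'
#' @param config a \code{\link{sim_config}}.
#' @param out_dir optional output directory (created if needed).
#' @return list: config, genome, genes, island, sites, mods_a, mods_b,
#'   expression (em + truth), truth (gene-level candidate truth), paths
#'   (when written).
#' @export
simulate_dataset <- function(config = sim_config(), out_dir = NULL) {
  set.seed(config$seed)
  g <- simulate_genome(config)
  sites <- scan_motifs(g$genome, default_motifs(include_m4C = TRUE))
  mods_a <- simulate_modifications(sites, config, "A")
  mods_b <- simulate_modifications(sites, config, "B")
  expr <- simulate_expression(g$genes, config)

  m6a <- sites$mod_type == "m6A"
  changed <- mods_a$truth$passes_qc[m6a] != mods_b$truth$passes_qc[m6a]
  ups <- upstream_regions(g$genes, g$genome$length, config$upstream_max_len)
  chpos <- sites$position[m6a][changed]
  bodies <- IRanges::IRanges(g$genes$start, g$genes$end)
  upr <- IRanges::IRanges(ups$start[ups$width > 0], ups$end[ups$width > 0])
  upids <- ups$gene_id[ups$width > 0]
  pts <- IRanges::IRanges(chpos, chpos)
  hit_genes <- unique(c(
    g$genes$gene_id[S4Vectors::subjectHits(IRanges::findOverlaps(pts, bodies))],
    upids[S4Vectors::subjectHits(IRanges::findOverlaps(pts, upr))]))
  meth_changed <- g$genes$gene_id %in% hit_genes
  ti <- match(g$genes$gene_id, expr$truth$gene_id)
  truth_genes <- data.frame(
    gene_id = g$genes$gene_id,
    meth_changed = meth_changed,
    lfc_true = expr$truth$lfc_true[ti],
    detectable = expr$truth$detectable[ti],
    planted_candidate = meth_changed & expr$truth$lfc_true[ti] != 0,
    expected_candidate = meth_changed & expr$truth$detectable[ti],
    stringsAsFactors = FALSE)

  out <- list(config = config, genome = g$genome, genes = g$genes,
              island = g$island, sites = sites,
              mods_a = mods_a, mods_b = mods_b,
              expression = expr, truth = truth_genes)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      genome = file.path(out_dir, "genome.fasta"),
      annotation = file.path(out_dir, "annotation.tsv"),
      mods_a = file.path(out_dir, "mods_free.gff"),
      mods_b = file.path(out_dir, "mods_bacteroid.gff"),
      expression = file.path(out_dir, "expression.tsv"),
      truth = file.path(out_dir, "truth.json"))
    write_genome(g$genome, paths$genome)
    ann <- g$genes
    ann$symbiosis_role <- ifelse(ann$is_symbiosis_gene, "symbiosis", "")
    write_tsv(ann[c("gene_id", "start", "end", "strand", "product",
                    "symbiosis_role")], paths$annotation)
    write_modifications(mods_a$records, paths$mods_a, seqname = g$genome$name)
    write_modifications(mods_b$records, paths$mods_b, seqname = g$genome$name)
    edf <- data.frame(gene_id = expr$em$gene_ids,
                      spot_id = rownames(expr$em$values),
                      expr$em$values, check.names = FALSE,
                      stringsAsFactors = FALSE)
    write_tsv(edf, paths$expression)
    jsonlite::write_json(
      list(seed = config$seed,
           site_truth_a = mods_a$truth[c("motif", "mod_type", "position",
                                         "strand", "methylated", "passes_qc")],
           site_truth_b = mods_b$truth[c("motif", "mod_type", "position",
                                         "strand", "methylated", "passes_qc")],
           gene_truth = truth_genes),
      paths$truth, digits = NA)
    out$paths <- paths
  }
  out
}
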