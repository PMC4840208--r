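# The synthetic-data generator: genome composition, modification calls,
# expression effects, reproducibility, QC exercise.

test_that("genome composition follows the configured GC levels", {
  cfg <- sim_config(seed = 3, genome_len = 20000L, gc_background = 1.0,
                    gc_island = 1.0, island_start = 1000L, island_end = 2000L,
                    plant_min_sites = 0L)
  set.seed(cfg$seed)
  g <- simulate_genome(cfg)
  expect_equal(gc_fraction(g$genome), 1.0)

  cfg2 <- sim_config(seed = 3, genome_len = 50000L, island_start = 10001L,
                     island_end = 25000L, plant_min_sites = 0L)
  set.seed(cfg2$seed)
  g2 <- simulate_genome(cfg2)
  isl_chars <- strsplit(substr(g2$genome$sequence, 10001, 25000), "")[[1]]
  rest_chars <- strsplit(paste0(substr(g2$genome$sequence, 1, 10000),
                                substr(g2$genome$sequence, 25001, 50000)),
                         "")[[1]]
  expect_lt(mean(isl_chars %in% c("G", "C")), mean(rest_chars %in% c("G", "C")))

  expect_error(simulate_genome(sim_config(island_start = 1L,
                                          island_end = 200001L,
                                          genome_len = 100000L)),
               "island")
})

test_that("GANTC site counts match the closed-form i.i.d. expectation", {
  cfg <- sim_config(seed = 5, genome_len = 100000L, plant_min_sites = 0L,
                    gc_island = 0.64)  # uniform composition
  set.seed(cfg$seed)
  g <- simulate_genome(cfg)
  sites <- scan_motif(g$genome, motif_spec("GANTC", "GANTC", 2, "m6A"))
  n_loci <- count_sites(sites, "per_duplex")
  p <- 0.32 * 0.18 * 1 * 0.18 * 0.32   # per-position match probability
  expected <- cfg$genome_len * p
  expect_lt(abs(n_loci - expected), 3 * sqrt(expected))
})

test_that("gene tiling is non-overlapping with fixed lengths and gaps", {
  cfg <- sim_config(seed = 9)
  set.seed(cfg$seed)
  g <- simulate_genome(cfg)
  genes <- g$genes
  expect_true(all(genes$end - genes$start + 1 == cfg$gene_len))
  expect_true(all(diff(genes$start) == cfg$gene_len + cfg$gene_gap))
  expect_false(is.unsorted(genes$start))
  expect_false(anyDuplicated(genes$gene_id) > 0)
})

test_that("modification rates, exclusivity and record emission behave as planted", {
  cfg <- sim_config(seed = 13)
  set.seed(cfg$seed)
  g <- simulate_genome(cfg)
  sites <- scan_motifs(g$genome, default_motifs())
  mods_a <- simulate_modifications(sites, cfg, "A")
  mods_b <- simulate_modifications(sites, cfg, "B")

  # rate 1.0 (GAGA in the free-living state): every site methylated
  gaga <- mods_a$truth$motif == "GAGA(N)6RTG"
  expect_true(all(mods_a$truth$methylated[gaga]))

  # rate 0 (CCTTGAG in the free-living state): no sites, no records
  cct <- mods_a$truth$motif == "CCTTGAG"
  expect_false(any(mods_a$truth$methylated[cct]))
  expect_false(any(paste(mods_a$records$position, mods_a$records$strand) %in%
                     paste(sites$position[sites$motif == "CCTTGAG"],
                           sites$strand[sites$motif == "CCTTGAG"])))

  # binomial band around the planted bacteroid CCTTGAG rate
  n <- sum(cct); p <- cfg$rates_b[["CCTTGAG|m6A"]]
  expect_lt(abs(sum(mods_b$truth$methylated[cct]) - n * p),
            3 * sqrt(n * p * (1 - p)) + 1)

  # one record per methylated base, none for unmethylated sites
  expect_equal(nrow(mods_b$records),
               length(unique(paste(mods_b$truth$position,
                                   mods_b$truth$strand,
                                   mods_b$truth$mod_type)[mods_b$truth$methylated])))
})

test_that("sub-threshold planted sites are never counted methylated", {
  cfg <- sim_config(seed = 17, subthreshold_fraction = 0.3)
  set.seed(cfg$seed)
  g <- simulate_genome(cfg)
  sites <- scan_motifs(g$genome, default_motifs())
  mods <- simulate_modifications(sites, cfg, "B")
  planted_sub <- mods$truth$methylated & !mods$truth$passes_qc
  expect_gt(sum(planted_sub), 0)
  st <- assign_states(sites,
                      qc_filter(mods$records, cfg$min_coverage, cfg$min_qv),
                      "bacteroid")
  key <- function(d) paste(d$position, d$strand, d$mod_type)
  obs <- st$methylated[match(key(mods$truth), key(st))]
  expect_false(any(obs[planted_sub]))
  # and QC-passing truth agrees exactly with the assigned states
  expect_equal(obs, mods$truth$passes_qc)
})

test_that("low-QV record emission mode still yields unmethylated states", {
  cfg <- sim_config(seed = 19, emit_unmethylated_records = TRUE)
  set.seed(cfg$seed)
  g <- simulate_genome(cfg)
  sites <- scan_motifs(g$genome, default_motifs())
  mods <- simulate_modifications(sites, cfg, "B")
  expect_equal(nrow(mods$records),
               length(unique(paste(sites$position, sites$strand, sites$mod_type))))
  st <- assign_states(sites,
                      qc_filter(mods$records, cfg$min_coverage, cfg$min_qv),
                      "bacteroid")
  key <- function(d) paste(d$position, d$strand, d$mod_type)
  obs <- st$methylated[match(key(mods$truth), key(st))]
  expect_equal(obs, mods$truth$passes_qc)
})

test_that("planted expression effects appear in the configured direction mix", {
  cfg <- sim_config(seed = 23)
  genes <- data.frame(gene_id = sprintf("g%03d", 1:80))
  set.seed(cfg$seed)
  ex <- simulate_expression(genes, cfg)
  tr <- ex$truth
  expect_equal(nrow(tr), 80 + cfg$n_array_only_genes)
  planted <- tr$lfc_true != 0
  expect_equal(sum(planted), floor(cfg$de_fraction * 80))
  expect_true(all(abs(tr$lfc_true[planted]) %in% cfg$de_effects))
  # background array-only genes are null
  expect_true(all(tr$lfc_true[-(1:80)] == 0))
  # detectable effects are the large ones only
  expect_true(all(abs(tr$lfc_true[tr$detectable]) >= 3))
  expect_false(any(tr$detectable[abs(tr$lfc_true) < 1.5 & planted]))
  # raw group difference reflects the planted effect
  em <- ex$em
  ia <- em$conditions == cfg$condition_a
  gmeans <- rowsum(em$values, em$gene_ids) / cfg$n_spots
  d <- rowMeans(gmeans[, ia, drop = FALSE]) - rowMeans(gmeans[, !ia, drop = FALSE])
  d <- d[match(tr$gene_id, rownames(gmeans))]
  expect_lt(max(abs(d - tr$lfc_true)), 5 * 0.25 * sqrt(2 / (3 * cfg$n_spots)))
})

test_that("identical seeds reproduce byte-identical data sets", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- sim_config(seed = 29, genome_len = 30000L, island_start = 5001L,
                    island_end = 10000L, n_array_only_genes = 200L,
                    plant_min_sites = 20L)
  simulate_dataset(cfg, d1)
  simulate_dataset(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # a different seed changes the data
  simulate_dataset(sim_config(seed = 31, genome_len = 30000L,
                              island_start = 5001L, island_end = 10000L,
                              n_array_only_genes = 200L,
                              plant_min_sites = 20L), d2)
  expect_false(identical(readLines(file.path(d1, "genome.fasta")),
                         readLines(file.path(d2, "genome.fasta"))))
})

test_that("ground-truth candidate sets are consistent with their definitions", {
  sim <- simulate_dataset(sim_config(seed = 37))
  tr <- sim$truth
  expect_true(all(tr$expected_candidate ==
                    (tr$meth_changed & tr$detectable)))
  expect_true(all(tr$planted_candidate ==
                    (tr$meth_changed & tr$lfc_true != 0)))
  expect_true(all(tr$gene_id %in% sim$genes$gene_id))
})
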