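# Gene-level integration of methylation and expression, headline counts,
# sliding-window methylation profiles, pipeline plumbing.

toy_genes <- function(n = 5, start0 = 1000, len = 500, gap = 500) {
  starts <- start0 + (seq_len(n) - 1) * (len + gap)
  data.frame(gene_id = sprintf("g%02d", seq_len(n)), start = starts,
             end = starts + len - 1, strand = "+",
             product = "", is_symbiosis_gene = FALSE, stringsAsFactors = FALSE)
}

toy_meth <- function(genes, changes) {
  data.frame(gene_id = genes$gene_id,
             changes_coding = changes, changes_upstream = 0L,
             total_changes = changes,
             motifs_changed = ifelse(changes > 0, "GANTC", ""),
             stringsAsFactors = FALSE)
}

toy_de <- function(genes, lfc, adj) {
  data.frame(gene_id = genes$gene_id, log_fc = lfc, t = 1,
             p_value = adj, adj_p = adj, significant = adj < 0.001,
             stringsAsFactors = FALSE)
}

test_that("candidates require both a methylation change and significant DE", {
  genes <- toy_genes(3)
  island <- genomic_region(1, 10)
  gm <- toy_meth(genes, c(1L, 2L, 0L))
  de <- toy_de(genes, c(3.06, 0.4, 2.0), c(1e-5, 0.5, 1e-6))
  gs <- integrate_meth_expr(gm, de, genes, island)
  # the nifE pattern: one GANTC change, logFC 3.06, tiny adjusted p
  expect_true(gs$candidate[1])
  expect_false(gs$candidate[2])  # changed but not significant
  expect_false(gs$candidate[3])  # significant but unchanged
  expect_identical(gs$candidate,
                   gs$meth_changes >= 1L & gs$de_significant)
})

test_that("genes missing from either input get neutral defaults, counted", {
  genes <- toy_genes(3)
  island <- genomic_region(1, 10)
  gm <- toy_meth(genes, c(1L, 1L, 1L))[1:2, ]
  de <- toy_de(genes, c(1, 1, 1), c(1e-5, 1e-5, 1e-5))[c(1, 3), ]
  gs <- integrate_meth_expr(gm, de, genes, island)
  expect_equal(gs$meth_changes[3], 0L)
  expect_false(gs$de_significant[2])
  expect_true(is.na(gs$log_fc[2]))
  expect_equal(attr(gs, "n_missing_meth"), 1L)
  expect_equal(attr(gs, "n_missing_de"), 1L)

  dup <- rbind(gm, gm[1, ])
  expect_error(integrate_meth_expr(dup, de, genes, island), "duplicate")
})

test_that("island membership follows the gene start coordinate", {
  genes <- toy_genes(3, start0 = 900, len = 200, gap = 0)  # starts 900,1100,1300
  island <- genomic_region(1000, 1200)
  gs <- integrate_meth_expr(toy_meth(genes, c(0L, 0L, 0L)),
                            toy_de(genes, c(0, 0, 0), rep(1, 3)),
                            genes, island)
  expect_equal(gs$in_island, c(FALSE, TRUE, FALSE))
})

test_that("integration counts add up and report the direction split", {
  n <- 100
  genes <- toy_genes(n, start0 = 1, len = 10, gap = 0)
  island <- genomic_region(1, 890)  # first 89 genes in the island
  changes <- rep(1L, n)
  lfc <- c(rep(-2, 78), rep(2, 11), rep(-1, 11))  # 78 island up-in-B, 11 up-in-A
  adj <- c(rep(1e-6, 89), rep(0.5, 11))
  gs <- integrate_meth_expr(toy_meth(genes, changes),
                            toy_de(genes, lfc, adj), genes, island)
  ic <- integration_counts(gs)
  expect_equal(ic$n_island_genes, 89L)
  expect_equal(ic$n_candidates_island, 89L)
  expect_equal(ic$n_candidates_genome, 89L)
  expect_equal(ic$n_island_up_in_b, 78L)
  expect_equal(ic$n_island_up_in_a, 11L)
  # island + rest = genome
  expect_equal(ic$n_candidates_island +
                 sum(gs$candidate & !gs$in_island), ic$n_candidates_genome)
  expect_equal(ic$pct_island, 100)

  none <- integration_counts(gs[gs$adj_p > 0.1, ])
  expect_equal(none$n_candidates_genome, 0L)
})

test_that("annotated fractions round half-up to one decimal", {
  expect_equal(annotated_fraction(0, 10), 0)
  expect_equal(annotated_fraction(1, 3), 33.3)
  expect_equal(annotated_fraction(5, 1000), 0.5)
  expect_error(annotated_fraction(1, 0), "denominator")
  expect_error(annotated_fraction(5, 3), "exceeds")
})

test_that("methylation windows average site states, empty windows are NA", {
  g <- genome_seq(strrep("A", 3000), circular = FALSE)
  st <- make_states(c(100, 200, 2500, 2600), c(TRUE, FALSE, TRUE, TRUE), "A")
  mw <- methylation_windows(st, g, window = 1000, step = 500)
  w1 <- mw[mw$window_start == 1, ]        # sites 100, 200 -> 1 of 2
  expect_equal(w1$value, 0.5)
  expect_equal(w1$n_sites, 2)
  w2 <- mw[mw$window_start == 1001, ]     # no sites
  expect_true(is.na(w2$value))
  expect_equal(w2$n_sites, 0)
  w3 <- mw[mw$window_start == 2001, ]     # both methylated
  expect_equal(w3$value, 1)

  full <- make_states(seq(50, 2950, by = 100), TRUE, "A")
  mwf <- methylation_windows(full, g, window = 1000, step = 250)
  expect_true(all(mwf$value[!is.na(mwf$value)] == 1))
})

test_that("methylation windows match a brute-force recount, wrapping included", {
  withr::local_seed(101)
  g <- genome_seq(random_dna(4000), circular = TRUE)
  pos <- sort(sample.int(4000, 300))
  st <- make_states(pos, runif(300) < 0.6, "A")
  mw <- methylation_windows(st, g, window = 700, step = 311)
  for (i in seq_len(nrow(mw))) {
    span <- ((mw$window_start[i] + 0:699 - 1) %% 4000) + 1
    inw <- st$position %in% span
    want <- if (any(inw)) mean(st$methylated[inw]) else NA_real_
    expect_equal(mw$value[i], want)
  }
  # genome-wide consistency: overall state mean equals the summary percent
  s <- summarize_motif(st)
  expect_equal(mean(st$methylated), s$n_methylated / s$n_motifs)
})

test_that("bedGraph export drops missing windows and uses 0-based starts", {
  prof <- data.frame(window_start = c(1, 101, 201), window_size = 100,
                     value = c(0.5, NA, 1))
  p <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(prof, p, "chr", 300, track_name = "t")
  lines <- readLines(p)
  expect_match(lines[1], "track")
  expect_equal(lines[2], "chr\t0\t100\t0.5")
  expect_equal(lines[3], "chr\t200\t300\t1")
  expect_length(lines, 3L)
})

test_that("pipeline errors carry their stage name", {
  cfg <- list(genome_fasta = "no/such.fasta", annotation = "x",
              modifications_a = "x", modifications_b = "x",
              condition_a = "A", condition_b = "B", expression = "x",
              arrays = list(a = "A"), island_start = 1, island_end = 2,
              out_dir = withr::local_tempdir())
  expect_error(run_pipeline(cfg), "load_genome")
  expect_error(run_pipeline(cfg[!names(cfg) %in% "annotation"]), "missing")
})
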