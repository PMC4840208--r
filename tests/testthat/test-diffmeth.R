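# Differential methylation: per-site changes, summaries, gene attribution,
# regional tallies.

test_that("diff_sites partitions sites into gains, losses and unchanged", {
  a <- make_states(1:20, rep(c(TRUE, FALSE), 10), "A")
  same <- diff_sites(a, make_states(1:20, rep(c(TRUE, FALSE), 10), "B"))
  expect_true(all(same$change == "unchanged"))

  # plant 5 gains (unmethylated in A -> methylated in B) and 3 losses
  ma <- rep(FALSE, 20); mb <- rep(FALSE, 20)
  ma[1:8] <- TRUE          # methylated in A
  mb[c(1:5, 9:13)] <- TRUE # keeps 1:5, loses 6:8, gains 9:13
  d <- diff_sites(make_states(1:20, ma, "A"), make_states(1:20, mb, "B"))
  expect_equal(sum(d$change == "gain"), 5L)
  expect_equal(sum(d$change == "loss"), 3L)
  expect_setequal(d$position[d$change == "gain"], 9:13)
  expect_setequal(d$position[d$change == "loss"], 6:8)
  expect_equal(sum(d$change == "unchanged") + 8L, 20L)

  expect_error(diff_sites(a, make_states(2:21, rep(TRUE, 20), "B")),
               "site sets")
})

test_that("diff_sites aligns by site identity, not row order", {
  a <- make_states(1:10, c(rep(TRUE, 5), rep(FALSE, 5)), "A")
  b <- make_states(1:10, c(rep(TRUE, 5), rep(FALSE, 5)), "B")
  d <- diff_sites(a, b[sample(10), ])
  expect_true(all(d$change == "unchanged"))
})

test_that("motif summaries count, percent and average over methylated sites", {
  st <- make_states(1:8, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE), "A")
  st$mod_qv[st$methylated] <- c(40, 50, 60)
  st$coverage[st$methylated] <- c(100, 110, 120)
  st$ipd_ratio[st$methylated] <- c(4, 5, 6)
  s <- summarize_motif(st)
  expect_equal(s$n_motifs, 8L)
  expect_equal(s$n_methylated, 3L)
  expect_equal(s$pct_methylated, 37.5)
  expect_equal(s$mean_qv, 50)
  expect_equal(s$mean_coverage, 110)
  expect_equal(s$mean_ipd, 5)

  none <- summarize_motif(make_states(1:10, rep(FALSE, 10), "A"))
  expect_equal(none$pct_methylated, 0)
  expect_true(is.na(none$mean_qv))

  # order-invariance of the percent
  st2 <- st[sample(8), ]
  expect_equal(summarize_motif(st2)$pct_methylated, 37.5)

  both <- rbind(make_states(1:4, rep(TRUE, 4), "A", motif = "GANTC"),
                make_states(11:14, rep(FALSE, 4), "A", motif = "CCTTGAG"))
  expect_error(summarize_motif(both), "single motif")
  expect_equal(nrow(summarize_motifs(both)), 2L)
})

test_that("methylation_loss is the signed difference of methylated counts", {
  a <- summarize_motif(make_states(1:10, c(rep(TRUE, 9), FALSE), "A"))
  b <- summarize_motif(make_states(1:10, c(rep(TRUE, 6), rep(FALSE, 4)), "B"))
  expect_equal(methylation_loss(a, b), 3L)
  expect_equal(methylation_loss(a, a), 0L)
  wrong <- summarize_motif(make_states(1:10, rep(TRUE, 10), "B", motif = "CCTTGAG"))
  expect_error(methylation_loss(a, wrong), "different motifs")
})

test_that("changed sites are attributed by region membership, divergent genes share", {
  genes <- data.frame(
    gene_id = c("left", "right"),
    start = c(100, 800), end = c(500, 1200),
    strand = c("-", "+"),
    product = "", is_symbiosis_gene = FALSE, stringsAsFactors = FALSE)
  ups <- upstream_regions(genes, 5000, max_len = 500)
  # site inside the 'right' gene body, one in the shared divergent gap
  a <- make_states(c(600, 900), c(FALSE, FALSE), "A")
  b <- make_states(c(600, 900), c(TRUE, TRUE), "B")
  d <- diff_sites(a, b)
  gm <- assign_to_genes(d, genes, ups)
  expect_equal(gm$changes_coding[gm$gene_id == "right"], 1L)
  expect_equal(gm$changes_upstream[gm$gene_id == "right"], 1L)
  expect_equal(gm$changes_upstream[gm$gene_id == "left"], 1L)
  expect_equal(gm$changes_coding[gm$gene_id == "left"], 0L)
  expect_equal(gm$total_changes, gm$changes_coding + gm$changes_upstream)
  expect_equal(attr(gm, "n_intergenic_unassigned"), 0L)
})

test_that("a gene accumulates changes from several motifs", {
  genes <- data.frame(gene_id = "noeE_like", start = 100, end = 1399,
                      strand = "+", product = "sulfotransferase",
                      is_symbiosis_gene = TRUE, stringsAsFactors = FALSE)
  ups <- upstream_regions(genes, 5000, max_len = 500)
  pos <- seq(150, 750, by = 50)  # 13 positions in the body
  a <- rbind(make_states(pos[1:7], rep(TRUE, 7), "A", motif = "GANTC"),
             make_states(pos[8:13], rep(TRUE, 6), "A", motif = "CRAGGAT"))
  b <- rbind(make_states(pos[1:7], rep(FALSE, 7), "B", motif = "GANTC"),
             make_states(pos[8:13], rep(FALSE, 6), "B", motif = "CRAGGAT"))
  gm <- assign_to_genes(diff_sites(a, b), genes, ups)
  expect_equal(gm$total_changes, 13L)
  expect_equal(gm$motifs_changed, "CRAGGAT,GANTC")
})

test_that("intergenic changes outside every region stay unassigned", {
  genes <- data.frame(gene_id = "g", start = 100, end = 200, strand = "+",
                      product = "", is_symbiosis_gene = FALSE,
                      stringsAsFactors = FALSE)
  ups <- upstream_regions(genes, 10000, max_len = 50)
  d <- diff_sites(make_states(5000, FALSE, "A"), make_states(5000, TRUE, "B"))
  gm <- assign_to_genes(d, genes, ups)
  expect_equal(sum(gm$total_changes), 0L)
  expect_equal(attr(gm, "n_intergenic_unassigned"), 1L)
})

test_that("regional tallies normalize per kb and split island from rest", {
  genes <- data.frame(gene_id = c("in_isl", "out"),
                      start = c(1000, 6000), end = c(2999, 7999),
                      strand = "+", product = "", is_symbiosis_gene = FALSE,
                      stringsAsFactors = FALSE)
  ups <- upstream_regions(genes, 10000, max_len = 0)
  island <- genomic_region(500, 4000, "island")
  pos <- seq(1100, 2900, length.out = 10)  # all inside the island gene
  d <- diff_sites(make_states(pos, rep(TRUE, 10), "A"),
                  make_states(pos, rep(FALSE, 10), "B"))
  rt <- regional_tally(d, island, genes, ups, 10000)
  cod <- rt[rt$compartment == "coding", ]
  expect_equal(cod$n_changed[cod$region == "island"], 10L)
  expect_equal(cod$n_changed[cod$region == "rest"], 0L)
  expect_equal(cod$n_changed[cod$region == "genome"], 10L)
  # 10 changes in the 2000-bp island coding compartment
  expect_equal(cod$changes_per_kb[cod$region == "island"], 5)
  expect_equal(cod$compartment_bp[cod$region == "island"], 2000)
  expect_equal(cod$n_meth_a[cod$region == "island"], 10L)
  expect_equal(cod$n_meth_b[cod$region == "island"], 0L)
  expect_error(regional_tally(d, genomic_region(1, 20000), genes, ups, 10000),
               "island")
})

test_that("gain fraction converges to (1-pA)*pB on planted states", {
  withr::local_seed(71)
  n <- 4000; pa <- 0.7; pb <- 0.4
  ma <- runif(n) < pa
  mb <- runif(n) < pb
  d <- diff_sites(make_states(1:n, ma, "A"), make_states(1:n, mb, "B"))
  gain_frac <- mean(d$change == "gain")
  expected <- (1 - pa) * pb
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(gain_frac - expected), 3 * se)
  expect_equal(sum(d$change == "gain") + sum(d$change == "loss") +
                 sum(d$change == "unchanged"), n)
})
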