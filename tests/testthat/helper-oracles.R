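# Independent oracles used across the suite. These deliberately share no
# code with the package implementations they check.

iupac_sets <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"),
                   N = c("A", "C", "G", "T"))

# brute-force degenerate window matcher: tests every window of the (padded,
# for circular genomes) sequence character-by-character against the pattern
brute_match_starts <- function(chars_padded, pattern, n_starts) {
  pat <- strsplit(pattern, "", fixed = TRUE)[[1]]
  ok <- rep(TRUE, n_starts)
  for (j in seq_along(pat)) {
    ok <- ok & chars_padded[seq_len(n_starts) + j - 1L] %in% iupac_sets[[pat[j]]]
  }
  which(ok)
}

# full brute-force site enumeration for one motif, both strands
brute_sites <- function(seqstr, motif, circular = TRUE) {
  L <- nchar(seqstr)
  k <- motif$length
  padded <- if (circular) paste0(seqstr, substr(seqstr, 1L, k - 1L)) else seqstr
  chars <- strsplit(padded, "", fixed = TRUE)[[1]]
  n_starts <- if (circular) L else L - k + 1L
  wrap <- function(p) ((p - 1L) %% L) + 1L
  fs <- brute_match_starts(chars, motif$iupac, n_starts)
  rs <- brute_match_starts(chars, symmeth::revcomp(motif$iupac), n_starts)
  df <- data.frame(
    position = c(wrap(fs + motif$modified_offset - 1L),
                 wrap(rs + k - motif$modified_offset)),
    strand = rep(c("+", "-"), c(length(fs), length(rs))),
    match_start = c(fs, rs),
    stringsAsFactors = FALSE)
  df[order(df$position, df$strand), , drop = FALSE]
}

# independent Benjamini-Hochberg step-up: sort ascending, adj_(i) =
# min_{j>=i} p_(j) * m / j, capped at 1, original order restored
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# circular k-mer multiset of a sequence
circular_kmers <- function(seqstr, k) {
  L <- nchar(seqstr)
  padded <- paste0(seqstr, substr(seqstr, 1L, k - 1L))
  sort(substring(padded, seq_len(L), seq_len(L) + k - 1L))
}

# minimal synthetic state table (no genome needed) for differential tests
make_states <- function(positions, methylated, condition,
                        motif = "GANTC", mod_type = "m6A",
                        strand = "+") {
  data.frame(motif = motif, mod_type = mod_type, position = positions,
             strand = strand, match_start = positions - 1L,
             condition = condition, methylated = methylated,
             mod_qv = ifelse(methylated, 100, NA_real_),
             coverage = ifelse(methylated, 100, NA_real_),
             ipd_ratio = ifelse(methylated, 4, NA_real_),
             stringsAsFactors = FALSE)
}

# run the full pipeline on a simulated data set in a temp dir
run_sim_pipeline <- function(sim, out_dir = withr::local_tempdir(.local_envir = parent.frame())) {
  cfg <- list(
    genome_fasta = sim$paths$genome,
    annotation = sim$paths$annotation,
    modifications_a = sim$paths$mods_a,
    modifications_b = sim$paths$mods_b,
    condition_a = sim$config$condition_a,
    condition_b = sim$config$condition_b,
    expression = sim$paths$expression,
    arrays = as.list(stats::setNames(sim$expression$em$conditions,
                                     colnames(sim$expression$em$values))),
    island_start = sim$config$island_start,
    island_end = sim$config$island_end,
    out_dir = out_dir)
  symmeth::run_pipeline(cfg)
}
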