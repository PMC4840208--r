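# Degenerate-motif definitions and strand-specific site enumeration.

#' Define a methylation motif
#'
#' A degenerate IUPAC motif with the position of its methylatable base.
#' Spacer notation \code{"(N)6"} is expanded to \code{NNNNNN}, so bipartite
#' Type I-style motifs may be written either way.
#'
#' @param name motif display name (e.g. \code{"GAGA(N)6RTG"}).
#' @param iupac motif string over A,C,G,T,R,Y,N (R = A/G, Y = C/T, N = any
#'   unambiguous base).
#' @param modified_offset 1-based position of the methylated base within the
#'   motif.
#' @param mod_type \code{"m6A"} or \code{"m4C"}; the base at
#'   \code{modified_offset} must be compatible (A/R/N for m6A, C/Y/N for
#'   m4C).
#' @return a \code{motif_spec} list.
#' @export
motif_spec <- function(name, iupac, modified_offset, mod_type = c("m6A", "m4C")) {
  mod_type <- match.arg(mod_type)
  iupac <- expand_spacers(toupper(iupac))
  if (grepl("[^ACGTRYN]", iupac))
    stop("motif may only use A,C,G,T,R,Y,N: ", iupac)
  k <- nchar(iupac)
  if (modified_offset < 1 || modified_offset > k)
    stop("modified_offset outside motif: ", modified_offset)
  base <- substr(iupac, modified_offset, modified_offset)
  ok <- switch(mod_type,
               m6A = base %in% c("A", "R", "N"),
               m4C = base %in% c("C", "Y", "N"))
  if (!ok) stop("base '", base, "' at offset ", modified_offset,
                " incompatible with ", mod_type)
  structure(list(name = name, iupac = iupac,
                 modified_offset = as.integer(modified_offset),
                 mod_type = mod_type, length = k),
            class = "motif_spec")
}

# "(N)6" / "(N)_6_" -> "NNNNNN"
expand_spacers <- function(x) {
  while (grepl("\\(N\\)_?([0-9]+)_?", x)) {
    m <- regmatches(x, regexec("\\(N\\)_?([0-9]+)_?", x))[[1]]
    x <- sub("\\(N\\)_?[0-9]+_?",
             paste(rep("N", as.integer(m[2])), collapse = ""), x)
  }
  x
}

#' Reverse complement of an IUPAC motif string
#'
#' @param iupac motif string.
#' @return reverse-complemented string.
#' @export
revcomp <- function(iupac) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(iupac)))
}

#' The five methylated motifs of the B. diazoefficiens methylome
#'
#' GANTC (the alphaproteobacterial CcrM motif, m6A at position 2), CRAGGAT
#' (m6A at position 6 and a weak m4C at position 1), the bipartite Type I
#' duplex pair GAGA(N)6RTG (m6A at 4) / CAY(N)6TCTC (m6A at 2) -- the two
#' strands of one double-stranded motif -- and the symbiosis-specific
#' CCTTGAG (m6A at 6).
#'
#' @param include_m4C include the CRAGGAT m4C specification (default TRUE;
#'   m4C is excluded from differential analysis downstream by default).
#' @return list of \code{\link{motif_spec}}.
#' @export
default_motifs <- function(include_m4C = TRUE) {
  motifs <- list(
    motif_spec("GANTC",        "GANTC",         2L, "m6A"),
    motif_spec("CRAGGAT",      "CRAGGAT",       6L, "m6A"),
    motif_spec("GAGA(N)6RTG",  "GAGANNNNNNRTG", 4L, "m6A"),
    motif_spec("CAY(N)6TCTC",  "CAYNNNNNNTCTC", 2L, "m6A"),
    motif_spec("CCTTGAG",      "CCTTGAG",       6L, "m6A")
  )
  if (include_m4C)
    motifs <- append(motifs, list(motif_spec("CRAGGAT", "CRAGGAT", 1L, "m4C")),
                     after = 2L)
  motifs
}

# matches of an IUPAC pattern on the forward strand of (padded) sequence;
# windows containing any non-ACGT base are discarded so ambiguity bases can
# never host a site (pattern N matches A/C/G/T only).
iupac_match_starts <- function(pattern, subject_dna, has_amb, L, k, circular) {
  hits <- Biostrings::matchPattern(Biostrings::DNAString(pattern), subject_dna,
                                   fixed = c(pattern = FALSE, subject = TRUE))
  s <- Biostrings::start(hits)
  s <- s[s <= L]
  if (any(has_amb)) {
    cs <- c(0L, cumsum(as.integer(has_amb)))
    clean <- (cs[s + k] - cs[s]) == 0L
    s <- s[clean]
  }
  s
}

#' Enumerate strand-specific methylatable sites of a motif
#'
#' Scans both strands: forward matches of the motif, and forward matches of
#' its reverse complement reported as minus-strand sites. \code{position} is
#' the genomic coordinate of the methylatable base itself (for minus-strand
#' sites it counts from the 3' end of the match on the forward coordinate
#' system); \code{match_start} is the forward-strand coordinate of the
#' occurrence. Overlapping occurrences are all reported; circular genomes
#' are scanned across the origin junction and coordinates wrap.
#'
#' @param genome a \code{\link{genome_seq}}.
#' @param motif a \code{\link{motif_spec}}.
#' @return data.frame motif, mod_type, position, strand, match_start,
#'   ordered by (position, strand). Site identity is the (position, strand)
#'   pair.
#' @export
scan_motif <- function(genome, motif) {
  stopifnot(inherits(genome, "genome_seq"), inherits(motif, "motif_spec"))
  L <- genome$length
  k <- motif$length
  if (k > L) stop("motif longer than genome")
  seqstr <- if (genome$circular && k > 1L)
    paste0(genome$sequence, substr(genome$sequence, 1L, k - 1L))
  else genome$sequence
  subject <- Biostrings::DNAString(seqstr)
  has_amb <- !(strsplit(seqstr, "", fixed = TRUE)[[1]] %in% c("A", "C", "G", "T"))
  fs <- iupac_match_starts(motif$iupac, subject, has_amb, L, k, genome$circular)
  rs <- iupac_match_starts(revcomp(motif$iupac), subject, has_amb, L, k,
                           genome$circular)
  wrap <- function(p) ((p - 1L) %% L) + 1L
  n_hits <- length(fs) + length(rs)
  out <- data.frame(
    motif = rep(motif$name, n_hits),
    mod_type = rep(motif$mod_type, n_hits),
    position = c(wrap(fs + motif$modified_offset - 1L),
                 wrap(rs + k - motif$modified_offset)),
    strand = rep(c("+", "-"), c(length(fs), length(rs))),
    match_start = c(fs, rs),
    stringsAsFactors = FALSE
  )
  out[order(out$position, out$strand), , drop = FALSE]
}

#' Enumerate sites for a set of motifs
#'
#' @param genome a \code{genome_seq}.
#' @param motifs list of \code{motif_spec} (default \code{default_motifs()}).
#' @return row-bound site table (see \code{\link{scan_motif}}).
#' @export
scan_motifs <- function(genome, motifs = default_motifs()) {
  do.call(rbind, lapply(motifs, function(m) scan_motif(genome, m)))
}

#' Count motif sites
#'
#' \code{per_strand} counts distinct (position, strand) pairs -- the natural
#' unit for strand-specific single-molecule calls. \code{per_duplex} counts
#' distinct match loci, collapsing the two strands of a palindromic
#' occurrence into one.
#'
#' @param sites site table from \code{\link{scan_motif}} (one motif).
#' @param mode \code{"per_strand"} (default) or \code{"per_duplex"}.
#' @return integer count.
#' @export
count_sites <- function(sites, mode = c("per_strand", "per_duplex")) {
  mode <- match.arg(mode)
  if (nrow(sites) == 0L) return(0L)
  if (length(unique(sites$motif)) > 1L)
    stop("count_sites expects sites from a single motif")
  if (mode == "per_strand")
    nrow(unique(sites[c("position", "strand")]))
  else
    nrow(unique(sites["match_start"]))
}
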