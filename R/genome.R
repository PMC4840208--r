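# Genome representation: sequence, annotation, regions, GC windows.
#
# Coordinates are 1-based with inclusive ends (GFF convention) throughout.

#' Construct a genome sequence object
#'
#' @param sequence DNA string (character scalar); uppercased on construction.
#' @param name replicon name used in output tracks.
#' @param circular is the replicon circular? Circular genomes are scanned and
#'   windowed across the origin junction.
#' @return an object of class \code{genome_seq}: a list with elements
#'   \code{name}, \code{sequence}, \code{circular}, \code{length}.
#' @export
genome_seq <- function(sequence, name = "genome", circular = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) stop("empty genome sequence")
  bad <- gsub("[ACGTRYSWKMBDHVN]", "", sequence)
  if (nchar(bad) > 0L)
    stop("non-IUPAC characters in genome sequence: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ""))
  structure(list(name = name, sequence = sequence, circular = circular,
                 length = nchar(sequence)),
            class = "genome_seq")
}

#' @export
print.genome_seq <- function(x, ...) {
  cat(sprintf("<genome_seq> %s: %s bp, %s\n", x$name,
              format(x$length, big.mark = ","),
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Load a single-replicon genome from FASTA
#'
#' The analysis targets one finished circular contig; multi-record FASTA
#' input is rejected rather than silently concatenated.
#'
#' @param path FASTA file with exactly one record.
#' @param circular circular flag to set on the genome.
#' @return a \code{\link{genome_seq}}.
#' @export
load_genome <- function(path, circular = TRUE) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("empty FASTA: ", path)
  if (length(set) > 1L)
    stop("expected single replicon, got ", length(set), " records in ", path)
  nm <- sub("\\s.*$", "", names(set)[1])
  genome_seq(as.character(set[[1]]), name = nm, circular = circular)
}

#' Write a genome to FASTA
#'
#' @param genome a \code{genome_seq}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_genome <- function(genome, path) {
  set <- Biostrings::DNAStringSet(genome$sequence)
  names(set) <- genome$name
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Rotate a circular genome to start at the replication origin
#'
#' The origin is located by the first forward-strand occurrence (lowest
#' coordinate) of the DnaA binding box; reverse-strand occurrences are
#' ignored. The sequence is rotated so that the box starts at position 1.
#'
#' @param genome a circular \code{genome_seq}.
#' @param box DnaA box sequence; default \code{"TGTTTCACG"}.
#' @return the rotated \code{genome_seq} (same length).
#' @export
rotate_to_origin <- function(genome, box = "TGTTTCACG") {
  stopifnot(inherits(genome, "genome_seq"))
  if (!genome$circular) stop("rotate_to_origin requires a circular genome")
  box <- toupper(box)
  # search across the junction too: the box may straddle the arbitrary cut
  padded <- paste0(genome$sequence, substr(genome$sequence, 1L, nchar(box) - 1L))
  hit <- regexpr(box, padded, fixed = TRUE)[1]
  if (hit < 0L || hit > genome$length)
    stop("DnaA box ", box, " not found on the forward strand")
  if (hit == 1L) return(genome)
  rotated <- paste0(substr(genome$sequence, hit, genome$length),
                    substr(genome$sequence, 1L, hit - 1L))
  genome_seq(rotated, name = genome$name, circular = TRUE)
}

#' Define a genomic region
#'
#' @param start,end 1-based inclusive coordinates, \code{end >= start}.
#' @param label free-text label (e.g. \code{"symbiosis_island"}).
#' @return a \code{genomic_region} list.
#' @export
genomic_region <- function(start, end, label = "region") {
  stopifnot(end >= start, start >= 1)
  structure(list(start = as.numeric(start), end = as.numeric(end),
                 label = label),
            class = "genomic_region")
}

#' Region length (inclusive) and span (end minus start)
#'
#' \code{region_length_bp} is the number of bases under the inclusive
#' convention (\code{end - start + 1}). \code{region_span_bp} is
#' \code{end - start}, the arithmetic conventionally used when a region is
#' quoted by its flanking coordinates (the 681-kb symbiosis island of
#' \emph{B. diazoefficiens} is the span 1,681,419 - 1,000,419).
#'
#' @param region a \code{genomic_region}.
#' @return base pairs.
#' @export
region_length_bp <- function(region) region$end - region$start + 1

#' @rdname region_length_bp
#' @export
region_span_bp <- function(region) region$end - region$start

#' Fraction of the genome covered by a span, as a percent
#'
#' @param span_bp region span in bp.
#' @param genome_bp genome length in bp.
#' @param digits decimals to report (default 1).
#' @return percentage, rounded half-up.
#' @export
fraction_of_genome <- function(span_bp, genome_bp, digits = 1) {
  round_half_up(100 * span_bp / genome_bp, digits)
}

#' Read a gene annotation table
#'
#' Tab-delimited with header columns \code{gene_id}, \code{start},
#' \code{end}, \code{strand}, \code{product} and optional
#' \code{symbiosis_role} (anything non-empty and not "0"/"no" marks a known
#' symbiosis gene).
#'
#' @param path annotation TSV.
#' @param genome optional \code{genome_seq} for coordinate validation.
#' @return data.frame with columns gene_id, start, end, strand, product,
#'   is_symbiosis_gene.
#' @export
read_annotation <- function(path, genome = NULL) {
  ann <- read_tsv(path)
  required <- c("gene_id", "start", "end", "strand")
  miss <- setdiff(required, names(ann))
  if (length(miss)) stop("annotation missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(ann$gene_id))
    stop("duplicate gene_id in annotation: ",
         ann$gene_id[duplicated(ann$gene_id)][1])
  if (any(ann$end < ann$start)) stop("annotation with end < start")
  if (!all(ann$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (!is.null(genome) && any(ann$end > genome$length))
    stop("gene coordinates exceed genome length")
  if (is.null(ann$product)) ann$product <- ""
  if (is.null(ann$symbiosis_role)) ann$symbiosis_role <- ""
  ann$is_symbiosis_gene <-
    !(is.na(ann$symbiosis_role) | ann$symbiosis_role %in% c("", "0", "no", "NA"))
  ann[c("gene_id", "start", "end", "strand", "product", "is_symbiosis_gene")]
}

#' Upstream (5'-UTR) regions for all genes
#'
#' For each gene, the intergenic interval immediately 5' of its start on its
#' own strand, capped at \code{max_len} and truncated at the nearest
#' neighbouring gene body on either strand. Overlapping or abutting genes
#' yield an empty region (width 0). Regions never overlap any annotated gene
#' body. Intervals are clipped at the ends of the coordinate system (no
#' wrap-around across the origin).
#'
#' @param genes annotation data.frame (see \code{\link{read_annotation}}).
#' @param genome_length genome length in bp.
#' @param max_len maximum upstream length in bp (default 500).
#' @return data.frame gene_id, start, end, width (width 0 encodes an empty
#'   region with \code{start = end + 1}).
#' @export
upstream_regions <- function(genes, genome_length, max_len = 500) {
  stopifnot(max_len >= 0)
  bodies <- IRanges::IRanges(start = genes$start, end = genes$end)
  n <- nrow(genes)
  us <- ue <- integer(n)
  for (i in seq_len(n)) {
    if (genes$strand[i] == "+") {
      hi <- genes$start[i] - 1L
      lo <- max(1L, genes$start[i] - max_len)
      if (hi < lo) { us[i] <- genes$start[i]; ue[i] <- genes$start[i] - 1L; next }
      cand <- IRanges::IRanges(lo, hi)
      ov <- IRanges::findOverlaps(cand, bodies)
      if (length(ov))
        lo <- max(lo, max(IRanges::end(bodies)[S4Vectors::subjectHits(ov)]) + 1L)
      us[i] <- lo; ue[i] <- hi
    } else {
      lo <- genes$end[i] + 1L
      hi <- min(genome_length, genes$end[i] + max_len)
      if (hi < lo) { us[i] <- genes$end[i] + 1L; ue[i] <- genes$end[i]; next }
      cand <- IRanges::IRanges(lo, hi)
      ov <- IRanges::findOverlaps(cand, bodies)
      if (length(ov))
        hi <- min(hi, min(IRanges::start(bodies)[S4Vectors::subjectHits(ov)]) - 1L)
      us[i] <- lo; ue[i] <- hi
    }
    if (ue[i] < us[i]) { ue[i] <- us[i] - 1L }  # fully blocked -> empty
  }
  data.frame(gene_id = genes$gene_id, start = us, end = ue,
             width = pmax(0L, ue - us + 1L), stringsAsFactors = FALSE)
}

#' Upstream region of a single gene
#'
#' Convenience wrapper around \code{\link{upstream_regions}}.
#'
#' @param gene_id gene identifier present in \code{genes}.
#' @inheritParams upstream_regions
#' @return a one-row data.frame (see \code{\link{upstream_regions}}).
#' @export
upstream_region <- function(gene_id, genes, genome_length, max_len = 500) {
  all <- upstream_regions(genes, genome_length, max_len)
  row <- all[all$gene_id == gene_id, , drop = FALSE]
  if (nrow(row) == 0L) stop("gene not in annotation: ", gene_id)
  row
}

#' GC fraction in overlapping sliding windows
#'
#' Windows start at 1, 1+step, 1+2*step, ... For a circular genome the final
#' windows wrap across the origin; for a linear genome only fully contained
#' windows are reported. Ambiguity bases count toward the window size but not
#' toward GC.
#'
#' @param genome a \code{genome_seq}.
#' @param window window size in bp (default 1000).
#' @param step step between window starts in bp (default 100).
#' @return data.frame window_start, window_size, value (GC fraction in
#'   [0, 1]), ordered by window_start.
#' @export
gc_windows <- function(genome, window = 1000, step = 100) {
  stopifnot(window >= 1, step >= 1)
  L <- genome$length
  if (window > L) stop("window larger than genome")
  is_gc <- as.integer(strsplit(genome$sequence, "", fixed = TRUE)[[1]] %in% c("G", "C"))
  if (genome$circular) {
    starts <- seq.int(1L, L, by = step)
    x <- c(is_gc, is_gc[seq_len(window - 1L)])
  } else {
    starts <- seq.int(1L, L - window + 1L, by = step)
    x <- is_gc
  }
  cs <- c(0, cumsum(x))
  vals <- (cs[starts + window] - cs[starts]) / window
  data.frame(window_start = starts, window_size = window, value = vals)
}

#' Whole-genome GC fraction
#'
#' @param genome a \code{genome_seq}.
#' @return fraction in [0, 1].
#' @export
gc_fraction <- function(genome) {
  chars <- strsplit(genome$sequence, "", fixed = TRUE)[[1]]
  mean(chars %in% c("G", "C"))
}

#' Write window profiles as bedGraph
#'
#' Standard 4-column bedGraph (0-based half-open intervals). Windows with a
#' missing value (e.g. methylation windows containing no motif site) are
#' omitted. Wrapping windows of circular genomes are clipped at the genome
#' end.
#'
#' @param profile data.frame with window_start, window_size, value.
#' @param path output path.
#' @param chrom chromosome/replicon name.
#' @param genome_length genome length for clipping.
#' @param track_name optional name for the track line.
#' @return the path, invisibly.
#' @export
write_bedgraph <- function(profile, path, chrom, genome_length,
                           track_name = NULL) {
  keep <- !is.na(profile$value)
  p <- profile[keep, , drop = FALSE]
  start0 <- p$window_start - 1
  end <- pmin(p$window_start + p$window_size - 1, genome_length)
  lines <- sprintf("%s\t%d\t%d\t%g", chrom, as.integer(start0),
                   as.integer(end), p$value)
  if (!is.null(track_name))
    lines <- c(sprintf("track type=bedGraph name=\"%s\"", track_name), lines)
  writeLines(lines, path)
  invisible(path)
}
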