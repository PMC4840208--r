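# PacBio-style base-modification GFF: parsing, QC, site-state assignment.
#
# The modifications file is a 9-column GFF3 dialect with one record per
# called base: type = m6A / m4C / modified_base, score = modQV, and
# coverage= / IPDRatio= key-value attributes. It is parsed directly (rather
# than through a generic GFF importer) so malformed lines can be reported
# with their line number.

#' Read a base-modification GFF file
#'
#' @param path modifications GFF. Lines starting with \code{#} are skipped.
#' @return data.frame position, strand, mod_type, mod_qv, coverage,
#'   ipd_ratio (one row per called base, in file order).
#' @export
read_modifications <- function(path) {
  if (!file.exists(path)) stop("modifications file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L)
    return(data.frame(position = integer(), strand = character(),
                      mod_type = character(), mod_qv = numeric(),
                      coverage = numeric(), ipd_ratio = numeric(),
                      stringsAsFactors = FALSE))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L))
    stop("malformed modification record (expected 9 tab-separated columns) ",
         "at line ", idx[which(nf != 9L)[1]], " of ", path)
  m <- matrix(unlist(fields), ncol = 9L, byrow = TRUE)
  strand <- m[, 7]
  if (!all(strand %in% c("+", "-")))
    stop("unknown strand symbol '", strand[!strand %in% c("+", "-")][1],
         "' at line ", idx[which(!strand %in% c("+", "-"))[1]], " of ", path)
  pos <- suppressWarnings(as.integer(m[, 4]))
  qv <- suppressWarnings(as.numeric(m[, 6]))
  if (anyNA(pos))
    stop("non-numeric position at line ", idx[which(is.na(pos))[1]], " of ", path)
  if (anyNA(qv))
    stop("non-numeric score at line ", idx[which(is.na(qv))[1]], " of ", path)
  attr_field <- m[, 9]
  get_attr <- function(key) {
    v <- rep(NA_real_, length(attr_field))
    rx <- regmatches(attr_field,
                     regexec(paste0("(?:^|;)\\s*", key, "=([^;]+)"), attr_field))
    got <- lengths(rx) == 2L
    v[got] <- suppressWarnings(as.numeric(vapply(rx[got], `[`, "", 2L)))
    v
  }
  coverage <- get_attr("coverage")
  ipd <- get_attr("IPDRatio")
  if (anyNA(coverage))
    stop("missing/invalid coverage= attribute at line ",
         idx[which(is.na(coverage))[1]], " of ", path)
  if (anyNA(ipd))
    stop("missing/invalid IPDRatio= attribute at line ",
         idx[which(is.na(ipd))[1]], " of ", path)
  if (any(ipd <= 0))
    stop("non-positive IPDRatio at line ", idx[which(ipd <= 0)[1]], " of ", path)
  data.frame(position = pos, strand = strand, mod_type = m[, 3],
             mod_qv = qv, coverage = coverage, ipd_ratio = ipd,
             stringsAsFactors = FALSE)
}

#' Write modification records as a modifications GFF
#'
#' Inverse of \code{\link{read_modifications}}; used by the synthetic-data
#' generator.
#'
#' @param records data.frame as returned by \code{read_modifications}.
#' @param path output path.
#' @param seqname replicon name for column 1.
#' @param source source tag for column 2.
#' @return the path, invisibly.
#' @export
write_modifications <- function(records, path, seqname = "genome",
                                source = "kinModCall") {
  header <- "##gff-version 3"
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t%s\t%s\t.\tcoverage=%d;IPDRatio=%.2f",
                   seqname, source, records$mod_type,
                   as.integer(records$position), as.integer(records$position),
                   format(records$mod_qv, trim = TRUE), records$strand,
                   as.integer(records$coverage), records$ipd_ratio)
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Quality-control filter for modification calls
#'
#' Keeps calls with \code{coverage >= min_coverage} and
#' \code{mod_qv >= min_qv}; both boundaries inclusive (the protocol's
#' recommended minimums, coverage >= 25 and modQV >= 30).
#'
#' @param records modification record data.frame.
#' @param min_coverage minimum read coverage (default 25).
#' @param min_qv minimum modification quality score (default 30).
#' @return the QC-passing subset, same columns.
#' @export
qc_filter <- function(records, min_coverage = 25, min_qv = 30) {
  records[records$coverage >= min_coverage & records$mod_qv >= min_qv, ,
          drop = FALSE]
}

#' Assign QC-passing calls to motif sites
#'
#' A site is methylated iff a QC-passing record exists at exactly its
#' (position, strand) with matching modification type. The absence of a call
#' is treated as unmethylated (no explicit unmethylated records are
#' expected). Records matching no site are counted as off-motif and reported
#' via the \code{"n_off_motif"} attribute.
#'
#' @param sites site table from \code{\link{scan_motifs}}.
#' @param records QC-filtered modification records.
#' @param condition condition label (e.g. \code{"free_living"}).
#' @return data.frame with the site columns plus condition, methylated
#'   (logical), mod_qv, coverage, ipd_ratio (NA when unmethylated).
#'   Attribute \code{n_off_motif} carries the count of unassigned records.
#' @export
assign_states <- function(sites, records, condition) {
  key <- function(pos, strand, type) paste(pos, strand, type, sep = "/")
  rkey <- key(records$position, records$strand, records$mod_type)
  if (anyDuplicated(rkey))
    stop("duplicate modification records at (position, strand, mod_type): ",
         rkey[duplicated(rkey)][1])
  skey <- key(sites$position, sites$strand, sites$mod_type)
  hit <- match(skey, rkey)
  out <- sites
  out$condition <- condition
  out$methylated <- !is.na(hit)
  out$mod_qv <- records$mod_qv[hit]
  out$coverage <- records$coverage[hit]
  out$ipd_ratio <- records$ipd_ratio[hit]
  n_off <- sum(!(rkey %in% skey))
  attr(out, "n_off_motif") <- n_off
  out
}
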