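# Per-gene differential expression from a two-condition replicate matrix:
# quantile normalization, spot collapsing, (moderated) t statistics, BH.

#' Construct an expression matrix object
#'
#' @param values numeric matrix of log2 intensities, rows = spots (or
#'   genes), columns = arrays.
#' @param gene_ids gene identifier per row (spot replicates share an id).
#' @param conditions condition label per column; exactly two distinct
#'   labels.
#' @return an \code{expr_matrix} list: values, gene_ids, conditions.
#' @export
expr_matrix <- function(values, gene_ids, conditions) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(gene_ids),
            ncol(values) == length(conditions))
  if (length(unique(conditions)) != 2L)
    stop("exactly two conditions are required, got: ",
         paste(unique(conditions), collapse = ", "))
  structure(list(values = values, gene_ids = as.character(gene_ids),
                 conditions = as.character(conditions)),
            class = "expr_matrix")
}

#' Read an expression matrix from TSV
#'
#' Tab-delimited with header: \code{gene_id}, \code{spot_id}, then one
#' column per array. Array-to-condition assignment is supplied separately.
#'
#' @param path expression TSV.
#' @param conditions named character vector mapping array column names to
#'   condition labels, or an unnamed vector in column order.
#' @return an \code{\link{expr_matrix}}.
#' @export
read_expression <- function(path, conditions) {
  df <- read_tsv(path)
  if (!all(c("gene_id", "spot_id") %in% names(df)))
    stop("expression table must start with gene_id and spot_id columns")
  arrays <- setdiff(names(df), c("gene_id", "spot_id"))
  if (!is.null(names(conditions))) {
    miss <- setdiff(arrays, names(conditions))
    if (length(miss)) stop("no condition for arrays: ",
                           paste(miss, collapse = ", "))
    conditions <- conditions[arrays]
  } else if (length(conditions) != length(arrays)) {
    stop("condition vector length does not match array count")
  }
  vals <- as.matrix(df[arrays])
  rownames(vals) <- df$spot_id
  expr_matrix(vals, df$gene_id, conditions)
}

#' Quantile normalization across arrays
#'
#' Makes every array's value distribution identical: values are replaced by
#' the mean of the sorted columns at their rank, ties receiving the mean
#' over their tied ranks. Optionally recentres each array's median to the
#' across-array mean median first -- a within-array step that is
#' rank-preserving, so it leaves between-array contrasts of the final
#' quantile-normalized values unchanged; arrays that are already identical
#' are a fixed point either way.
#'
#' @param em an \code{\link{expr_matrix}} with >= 2 arrays.
#' @param center_arrays recentre array medians first (default TRUE).
#' @return the normalized \code{expr_matrix}.
#' @export
quantile_normalize <- function(em, center_arrays = TRUE) {
  stopifnot(inherits(em, "expr_matrix"))
  if (ncol(em$values) < 2L) stop("need at least two arrays")
  v <- em$values
  if (anyNA(v)) stop("missing values in expression matrix")
  if (center_arrays) {
    meds <- apply(v, 2L, stats::median)
    v <- sweep(v, 2L, meds - mean(meds))
  }
  em$values <- limma::normalizeQuantiles(v, ties = TRUE)
  dimnames(em$values) <- dimnames(v)
  em
}

#' Collapse spot replicates to one row per gene
#'
#' Per-gene mean of its spots on each array.
#'
#' @param em an \code{\link{expr_matrix}} keyed by spots.
#' @return an \code{expr_matrix} with one row per gene, rows ordered by
#'   gene id (first appearance order).
#' @export
collapse_spots <- function(em) {
  stopifnot(inherits(em, "expr_matrix"))
  ids <- factor(em$gene_ids, levels = unique(em$gene_ids))
  sums <- rowsum(em$values, ids)
  counts <- as.integer(table(ids))
  vals <- sums / counts
  expr_matrix(vals, rownames(sums), em$conditions)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control (via \code{stats::p.adjust}).
#'
#' @param p p-values in [0, 1].
#' @return adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-gene differential expression between two conditions
#'
#' Log2 fold change is \code{mean(A) - mean(B)} (positive = higher in
#' condition A; with A = free-living this matches the convention that
#' values above zero are more expressed in culture and below zero during
#' symbiosis). The test statistic is a two-sample t with pooled variance;
#' by default each gene's variance is shrunk toward the across-gene mean
#' variance with prior weight \code{d0} (a light-weight analogue of
#' microarray variance moderation, adding \code{d0} degrees of freedom),
#' which stabilises the test at small replicate numbers. Set
#' \code{shrink = FALSE} for the plain pooled-variance t. P-values are
#' BH-adjusted; significance at \code{adj_p < alpha}.
#'
#' @param em a normalized, spot-collapsed \code{\link{expr_matrix}}.
#' @param condition_a,condition_b the two condition labels; A is the
#'   reference (free-living).
#' @param alpha significance threshold on the adjusted p (default 0.001).
#' @param shrink use variance shrinkage (default TRUE).
#' @param d0 prior degrees of freedom for shrinkage (default 4).
#' @return data.frame gene_id, log_fc, t, p_value, adj_p, significant.
#' @export
differential_expression <- function(em, condition_a, condition_b,
                                    alpha = 0.001, shrink = TRUE, d0 = 4) {
  stopifnot(inherits(em, "expr_matrix"))
  ia <- em$conditions == condition_a
  ib <- em$conditions == condition_b
  if (!any(ia) || !any(ib))
    stop("conditions not found in matrix: ", condition_a, " / ", condition_b)
  na <- sum(ia); nb <- sum(ib)
  if (na < 2L || nb < 2L)
    stop("need >= 2 arrays per condition (got ", na, " and ", nb, ")")
  va <- em$values[, ia, drop = FALSE]
  vb <- em$values[, ib, drop = FALSE]
  ma <- rowMeans(va); mb <- rowMeans(vb)
  ssa <- rowSums((va - ma)^2); ssb <- rowSums((vb - mb)^2)
  df <- na + nb - 2L
  s2 <- (ssa + ssb) / df
  if (shrink) {
    s2 <- (d0 * mean(s2) + df * s2) / (d0 + df)
    df_t <- df + d0
  } else {
    df_t <- df
  }
  lfc <- ma - mb
  se <- sqrt(s2 * (1 / na + 1 / nb))
  tstat <- ifelse(se > 0, lfc / se, ifelse(lfc == 0, 0, sign(lfc) * Inf))
  p <- 2 * stats::pt(-abs(tstat), df = df_t)
  adj <- bh_adjust(p)
  data.frame(gene_id = em$gene_ids, log_fc = lfc, t = tstat,
             p_value = p, adj_p = adj, significant = adj < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}
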