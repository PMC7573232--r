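# Count filtering and normalization ahead of signature derivation, centroid
# scoring and GSEA. Scoring uses plain CPM; the low-count filter and TMM
# scaling belong by default to the GSEA path but are exposed everywhere.

#' Remove genes with zero counts in every sample
#'
#' @param m count matrix (genes x samples).
#' @return the matrix restricted to genes with at least one nonzero count,
#'   row order preserved.
#' @export
remove_zero_genes <- function(m) {
  validate_counts(m)
  keep <- rowSums(m) > 0
  if (!any(keep)) stopf("no expressed genes after removing all-zero rows")
  nhs_log("remove_zero_genes: %d -> %d genes", nrow(m), sum(keep))
  m[keep, , drop = FALSE]
}

#' Filter genes by a per-sample minimum read count
#'
#' A gene is retained only if every sample has at least `min_reads` reads
#' for it — i.e. genes with fewer than `min_reads` reads in at least one
#' sample are discarded.
#'
#' @param m count matrix.
#' @param min_reads minimum reads required in every sample (default 5).
#' @return filtered count matrix, row order preserved.
#' @export
filter_low_counts <- function(m, min_reads = 5) {
  validate_counts(m)
  if (length(min_reads) != 1L || is.na(min_reads) || min_reads < 0) {
    stopf("min_reads must be a single non-negative number")
  }
  keep <- rowSums(m < min_reads) == 0L
  if (!any(keep)) stopf("no genes pass the min_reads = %g filter", min_reads)
  nhs_log("filter_low_counts(min_reads = %g): %d -> %d genes",
          min_reads, nrow(m), sum(keep))
  m[keep, , drop = FALSE]
}

#' Counts-per-million normalization
#'
#' value(g, s) = count(g, s) / libsize(s) * 1e6. With `log2_offset > 0` the
#' result is log2(CPM + offset) and the returned matrix carries
#' `attr(, "log2") = TRUE`.
#'
#' @param m count matrix; every sample must have library size > 0.
#' @param log2_offset offset added before log2 transform; 0 (default)
#'   disables the transform.
#' @param lib_sizes optional per-sample library sizes (e.g. effective sizes
#'   after TMM scaling); defaults to column sums.
#' @return numeric matrix of normalized expression with attributes `units`
#'   ("CPM") and `log2`.
#' @export
cpm <- function(m, log2_offset = 0, lib_sizes = NULL) {
  validate_counts(m)
  if (is.null(lib_sizes)) lib_sizes <- colSums(m)
  if (any(lib_sizes <= 0)) stopf("zero library size in sample '%s'",
                                 colnames(m)[lib_sizes <= 0][1L])
  stopifnot(length(log2_offset) == 1L, log2_offset >= 0)
  v <- t(t(m) / lib_sizes) * 1e6
  islog <- log2_offset > 0
  if (islog) v <- log2(v + log2_offset)
  structure(v, units = "CPM", log2 = islog)
}

#' Trimmed-mean-of-M-values normalization factors
#'
#' For each sample against a reference sample, per-gene M values (log2 ratio
#' of library-size-scaled proportions) and A values (mean log2 proportion)
#' are computed over genes expressed in both samples; the 30% most extreme M
#' (each tail) and 5% most extreme A (each tail) are trimmed; the factor is
#' 2 to the precision-weighted mean of the remaining M values. Factors are
#' rescaled so their geometric mean is 1.
#'
#' @param m count matrix with at least two samples.
#' @param ref_sample sample id to use as reference, or "auto" (default) to
#'   pick the sample whose upper-quartile count proportion is closest to the
#'   mean upper-quartile.
#' @param trim_m,trim_a per-tail trim fractions for M and A values.
#' @return named vector of positive per-sample scaling factors.
#' @export
tmm_factors <- function(m, ref_sample = "auto", trim_m = 0.30, trim_a = 0.05) {
  validate_counts(m)
  if (ncol(m) < 2L) stopf("TMM needs at least 2 samples")
  lib <- colSums(m)
  if (any(lib <= 0)) stopf("zero library size")
  if (identical(ref_sample, "auto")) {
    uq <- apply(m, 2L, function(x) stats::quantile(x, 0.75)) / lib
    ref <- which.min(abs(uq - mean(uq)))
  } else {
    ref <- match(ref_sample, colnames(m))
    if (is.na(ref)) stopf("unknown reference sample '%s'", ref_sample)
  }
  f <- vapply(seq_len(ncol(m)), function(s) {
    if (s == ref) return(1)
    .tmm_pair(m[, s], lib[s], m[, ref], lib[ref], trim_m, trim_a)
  }, numeric(1L))
  names(f) <- colnames(m)
  f / geometric_mean(f)
}

# One TMM factor: sample (obs) against reference.
.tmm_pair <- function(obs, n_obs, ref, n_ref, trim_m, trim_a) {
  both <- obs > 0 & ref > 0
  if (!any(both)) {
    warnf("TMM: no genes expressed in both sample and reference; factor 1")
    return(1)
  }
  o <- obs[both]; r <- ref[both]
  M <- log2((o / n_obs) / (r / n_ref))
  A <- 0.5 * (log2(o / n_obs) + log2(r / n_ref))
  # precision weights: delta-method variance of M
  w <- 1 / ((n_obs - o) / (n_obs * o) + (n_ref - r) / (n_ref * r))
  n <- length(M)
  loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
  keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
  if (!any(keep)) {
    warnf("TMM: no genes survive trimming; factor 1")
    return(1)
  }
  fbar <- sum(w[keep] * M[keep]) / sum(w[keep])
  if (!is.finite(fbar) || abs(fbar) < 1e-6) fbar <- 0
  2^fbar
}
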