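# Nearest-centroid No Help scoring: the score of a query expression profile
# is the Pearson correlation with the No-Help reference centroid minus the
# correlation with the Help centroid, computed over the signature genes
# present in both reference and query. Positive scores mean the profile is
# transcriptionally closer to helpless (non-helped) CD8 T cells.

#' Pearson product-moment correlation
#'
#' Thin validation wrapper around [stats::cor()]: both vectors must have the
#' same length (>= 3) and nonzero variance.
#'
#' @param x,y numeric vectors.
#' @return correlation in [-1, 1].
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stopf("vectors differ in length")
  if (length(x) < 3L) stopf("need at least 3 paired values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stopf("degenerate profile: zero variance")
  stats::cor(x, y)
}

#' Compute the two reference centroids over the signature genes
#'
#' Each centroid is the per-gene arithmetic mean of normalized expression
#' across that condition's replicates, restricted to signature genes present
#' in the reference (matching is case-insensitive on gene id). Signature
#' genes absent from the reference are dropped with a logged count.
#'
#' @param ref_expr normalized expression matrix (genes x samples) for the
#'   reference dataset, e.g. from [cpm()].
#' @param meta metadata for the reference samples.
#' @param signature signature data.frame (needs a gene_id column).
#' @param conditions length-2 vector c(nohelp_label, help_label); defaults
#'   to the signature's reference_conditions attribute.
#' @param min_overlap minimum number of signature genes that must be present
#'   (default 10).
#' @return object of class `nohelp_centroids`: list with gene_ids,
#'   centroid_nohelp, centroid_help, normalization.
#' @export
compute_centroids <- function(ref_expr, meta, signature,
                              conditions = attr(signature, "reference_conditions"),
                              min_overlap = 10) {
  if (is.null(conditions)) stopf("conditions not given and signature carries none")
  meta <- meta[match(colnames(ref_expr), meta$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id)) stopf("metadata does not cover all reference samples")
  for (cond in conditions) {
    if (sum(meta$condition == cond) < 1L) stopf("no samples for condition '%s'", cond)
  }
  key_ref <- norm_gene_ids(rownames(ref_expr))
  key_sig <- norm_gene_ids(signature$gene_id)
  hit <- match(key_sig, key_ref)
  dropped <- sum(is.na(hit))
  if (dropped > 0) {
    nhs_log("compute_centroids: %d signature gene(s) absent from the reference dropped",
            dropped)
  }
  hit <- hit[!is.na(hit)]
  if (length(hit) < min_overlap) {
    stopf("only %d signature genes present in the reference (min_overlap = %d)",
          length(hit), min_overlap)
  }
  sub <- ref_expr[hit, , drop = FALSE]
  cn <- rowMeans(sub[, meta$condition == conditions[1L], drop = FALSE])
  ch <- rowMeans(sub[, meta$condition == conditions[2L], drop = FALSE])
  structure(list(gene_ids = rownames(sub),
                 centroid_nohelp = unname(cn),
                 centroid_help = unname(ch),
                 normalization = list(units = attr(ref_expr, "units"),
                                      log2 = isTRUE(attr(ref_expr, "log2")))),
            class = "nohelp_centroids")
}

#' No Help score of one query profile
#'
#' score = cor(profile, No-Help centroid) - cor(profile, Help centroid),
#' both correlations computed on the identical overlap gene set.
#'
#' @param profile named numeric vector of normalized expression for one
#'   query sample.
#' @param centroids `nohelp_centroids` object.
#' @param min_overlap minimum overlap between profile and centroid genes
#'   (default 10).
#' @return data.frame row with r_nohelp, r_help, no_help_score,
#'   n_genes_used.
#' @export
no_help_score <- function(profile, centroids, min_overlap = 10) {
  if (is.null(names(profile))) stopf("profile must be a named vector")
  hit <- match(norm_gene_ids(centroids$gene_ids), norm_gene_ids(names(profile)))
  use <- !is.na(hit)
  if (sum(use) < min_overlap) {
    stopf("profile/centroid overlap %d below min_overlap = %d",
          sum(use), min_overlap)
  }
  x <- as.numeric(profile[hit[use]])
  rn <- pearson(x, centroids$centroid_nohelp[use])
  rh <- pearson(x, centroids$centroid_help[use])
  data.frame(r_nohelp = rn, r_help = rh, no_help_score = rn - rh,
             n_genes_used = sum(use))
}

#' Score every sample of a query expression matrix
#'
#' @param query_expr normalized expression matrix (genes x samples).
#' @param centroids `nohelp_centroids` object.
#' @param min_overlap passed to [no_help_score()].
#' @return data.frame with one row per sample: sample_id, r_nohelp, r_help,
#'   no_help_score, n_genes_used.
#' @export
score_samples <- function(query_expr, centroids, min_overlap = 10) {
  rows <- lapply(colnames(query_expr), function(s) {
    cbind(sample_id = s,
          no_help_score(query_expr[, s], centroids, min_overlap))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Translate gene identifiers of a profile or matrix
#'
#' Applies a one-to-one source-to-target mapping (see [read_mapping()]);
#' genes without a mapping entry are dropped with a logged count.
#'
#' @param profile named numeric vector or matrix with gene-id rownames.
#' @param mapping data.frame with source_id, target_id.
#' @return the profile with translated gene ids.
#' @export
map_profile <- function(profile, mapping) {
  ids <- if (is.matrix(profile)) rownames(profile) else names(profile)
  if (is.null(ids)) stopf("profile has no gene identifiers")
  hit <- match(norm_gene_ids(ids), norm_gene_ids(mapping$source_id))
  keep <- !is.na(hit)
  if (!any(keep)) stopf("no genes could be mapped")
  if (any(!keep)) nhs_log("map_profile: %d unmapped gene(s) dropped", sum(!keep))
  out <- if (is.matrix(profile)) profile[keep, , drop = FALSE] else profile[keep]
  new_ids <- mapping$target_id[hit[keep]]
  if (is.matrix(out)) rownames(out) <- new_ids else names(out) <- new_ids
  out
}

#' Pooled-variance two-sample t-test
#'
#' Classical (Student's) unpaired two-tailed t-test with pooled variance.
#'
#' @param scores_a,scores_b numeric vectors, each of length >= 2.
#' @return list with test, statistic, df, p_value, groups.
#' @export
compare_two_groups <- function(scores_a, scores_b) {
  nA <- length(scores_a); nB <- length(scores_b)
  if (nA < 2L || nB < 2L) stopf("each group needs >= 2 values")
  df <- nA + nB - 2L
  sp2 <- ((nA - 1) * stats::var(scores_a) + (nB - 1) * stats::var(scores_b)) / df
  dm <- mean(scores_a) - mean(scores_b)
  if (sp2 == 0) {
    if (dm == 0) {
      return(list(test = "students_t", statistic = 0, df = df, p_value = 1,
                  groups = c("a", "b")))
    }
    stopf("zero pooled variance with unequal means")
  }
  tstat <- dm / sqrt(sp2 * (1 / nA + 1 / nB))
  list(test = "students_t", statistic = tstat, df = df,
       p_value = 2 * stats::pt(-abs(tstat), df), groups = c("a", "b"))
}

#' Repeated-measures one-way ANOVA with Tukey contrasts
#'
#' Within-subject one-way ANOVA on a complete subjects-by-conditions table:
#' F = MS_condition / MS_error with the subject-by-condition interaction as
#' the error term. Tukey pairwise p-values come from the studentized-range
#' distribution ([stats::ptukey()]) of the condition means over the same
#' error term.
#'
#' @param score_table numeric matrix, rows = subjects, columns = conditions;
#'   must be complete with >= 2 subjects and >= 2 conditions.
#' @return list with test, statistic (F), df (condition, error), p_value,
#'   and a `tukey` data.frame of pairwise comparisons.
#' @export
compare_matched_groups <- function(score_table) {
  m <- as.matrix(score_table)
  if (anyNA(m)) stopf("incomplete table: every subject needs every condition")
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) stopf("need >= 2 subjects and >= 2 conditions")
  if (is.null(colnames(m))) colnames(m) <- paste0("cond", seq_len(k))
  grand <- mean(m)
  ss_cond <- n * sum((colMeans(m) - grand)^2)
  ss_subj <- k * sum((rowMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df_cond <- k - 1L; df_err <- (n - 1L) * (k - 1L)
  ms_cond <- ss_cond / df_cond; ms_err <- ss_err / df_err
  pairs <- utils::combn(colnames(m), 2L)
  if (ms_err <= 0) {
    if (ms_cond == 0) {
      tk <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                       diff = 0, q = 0, p_value = 1)
      return(list(test = "rm_anova_tukey", statistic = 0,
                  df = c(condition = df_cond, error = df_err), p_value = 1,
                  tukey = tk))
    }
    stopf("zero error variance")
  }
  fstat <- ms_cond / ms_err
  pf_val <- stats::pf(fstat, df_cond, df_err, lower.tail = FALSE)
  se <- sqrt(ms_err / n)
  cm <- colMeans(m)
  diffs <- cm[pairs[1L, ]] - cm[pairs[2L, ]]
  qstat <- abs(diffs) / se
  tk <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                   diff = unname(diffs), q = unname(qstat),
                   p_value = stats::ptukey(qstat, nmeans = k, df = df_err,
                                           lower.tail = FALSE),
                   row.names = NULL)
  list(test = "rm_anova_tukey", statistic = fstat,
       df = c(condition = df_cond, error = df_err), p_value = pf_val,
       tukey = tk)
}

#' Write a score table to TSV
#' @param scores data.frame from [score_samples()] (optionally with a
#'   `group` column).
#' @param path output path.
#' @export
write_scores <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
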