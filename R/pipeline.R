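# End-to-end driver: simulate -> derive signature -> score -> GSEA ->
# group comparisons, with every intermediate written as TSV plus a JSON
# manifest. The analysis scripts and the acceptance machinery are thin
# wrappers around this.

#' Run the full pipeline on a simulated fixture
#'
#' Generates the reference fixture (or reuses one already in `out_dir`),
#' derives the differential-expression signature, computes centroids and
#' No Help scores for the reference samples, the graded mixture query panel
#' and its renamed "species B" copy (via the mapping table), runs GSEA of
#' the true up/down DE sets against the reference contrast, and compares
#' scores between populations (pooled t-test for the two extreme mixture
#' panels; repeated-measures ANOVA with Tukey contrasts across the mixture
#' levels, pairing query draws by their within-level index).
#'
#' All randomness is governed by `config$seed` and `seed`; repeated runs
#' with the same inputs produce byte-identical output files.
#'
#' @param out_dir output directory.
#' @param config simulation configuration (default [simulation_config()]).
#' @param n_perm GSEA permutations (default 1000).
#' @param seed seed for the GSEA permutation null (default the config seed).
#' @param fdr_threshold signature FDR cutoff (default 0.01).
#' @return invisibly, a list with the signature, centroids, score tables,
#'   GSEA table, comparison results, and the file paths written.
#' @export
run_pipeline <- function(out_dir, config = simulation_config(),
                         n_perm = 1000, seed = config$seed,
                         fdr_threshold = 0.01) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fixture_dir <- file.path(out_dir, "fixtures")
  fix <- make_default_fixture(fixture_dir, config = config)

  counts <- read_counts(fix$counts)
  meta <- read_metadata(fix$meta)
  sig <- derive_signature(counts, meta, fdr_threshold = fdr_threshold)
  sig_path <- file.path(out_dir, "signature.tsv")
  write_signature(sig, sig_path)

  expr <- cpm(remove_zero_genes(counts))
  cent <- compute_centroids(expr, meta, sig)

  ref_scores <- score_samples(expr, cent)
  ref_scores$group <- meta$condition[match(ref_scores$sample_id,
                                           meta$sample_id)]
  write_scores(ref_scores, file.path(out_dir, "scores_reference.tsv"))

  query <- read_expression(fix$query)
  qmeta <- utils::read.delim(fix$query_meta)
  q_scores <- score_samples(query, cent)
  q_scores$group <- qmeta$condition[match(q_scores$sample_id,
                                          qmeta$sample_id)]
  write_scores(q_scores, file.path(out_dir, "scores_query.tsv"))

  spb <- read_expression(fix$species_query)
  mapping <- read_mapping(fix$mapping)
  spb_scores <- score_samples(map_profile(spb, mapping), cent)
  write_scores(spb_scores, file.path(out_dir, "scores_speciesB.tsv"))

  sets <- read_gmt(fix$gmt)
  rk <- rank_genes(expr, meta)
  gsea_tab <- run_gsea(rk, sets, n_perm = n_perm, seed = seed)
  utils::write.table(gsea_tab, file.path(out_dir, "gsea.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # comparisons: extreme mixture panels (unpaired) and all levels (matched)
  levels_w <- sort(unique(qmeta$condition))
  hi <- q_scores$no_help_score[q_scores$group == levels_w[length(levels_w)]]
  lo <- q_scores$no_help_score[q_scores$group == levels_w[1L]]
  ttest <- compare_two_groups(hi, lo)
  score_tab <- do.call(cbind, lapply(levels_w, function(lv) {
    q_scores$no_help_score[q_scores$group == lv]
  }))
  colnames(score_tab) <- levels_w
  anova <- compare_matched_groups(score_tab)
  comparisons <- list(extremes_t = ttest[c("statistic", "df", "p_value")],
                      mixture_anova = list(statistic = anova$statistic,
                                           df = as.list(anova$df),
                                           p_value = anova$p_value,
                                           tukey = anova$tukey))
  jsonlite::write_json(comparisons, file.path(out_dir, "comparisons.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  write_run_manifest(file.path(out_dir, "manifest.json"),
                     step = "pipeline", config = unclass(config),
                     n_perm = n_perm, seed = seed,
                     fdr_threshold = fdr_threshold,
                     n_signature_genes = nrow(sig))

  invisible(list(signature = sig, centroids = cent,
                 ref_scores = ref_scores, query_scores = q_scores,
                 speciesB_scores = spb_scores, gsea = gsea_tab,
                 comparisons = list(extremes_t = ttest,
                                    mixture_anova = anova),
                 fixture_paths = fix, out_dir = out_dir))
}
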