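#!/usr/bin/env Rscript
# Step 5 — group statistics on the No Help scores: pooled Student's t-test
# for the two extreme mixture panels (helpless-like w = 1 vs helped-like
# w = 0), and repeated-measures one-way ANOVA with Tukey contrasts across
# all five mixture levels, pairing query draws by their within-level index.

suppressPackageStartupMessages(library(nohelpscore))

qs <- read.delim("results/scores_query.tsv")
levels_w <- sort(unique(qs$group))

hi <- qs$no_help_score[qs$group == levels_w[length(levels_w)]]
lo <- qs$no_help_score[qs$group == levels_w[1]]
tt <- compare_two_groups(hi, lo)
cat(sprintf("Extreme panels (%s vs %s): t = %.2f on %d df, p = %.3g.\n",
            levels_w[length(levels_w)], levels_w[1], tt$statistic, tt$df,
            tt$p_value))

tab <- sapply(levels_w, function(lv) qs$no_help_score[qs$group == lv])
an <- compare_matched_groups(tab)
cat(sprintf("Across all mixture levels: F(%d, %d) = %.2f, p = %.3g.\n",
            an$df["condition"], an$df["error"], an$statistic, an$p_value))
cat("Tukey pairwise comparisons:\n")
print(an$tukey, row.names = FALSE, digits = 3)

out <- list(extremes_t = tt[c("statistic", "df", "p_value")],
            mixture_anova = list(statistic = an$statistic,
                                 df = as.list(an$df), p_value = an$p_value,
                                 tukey = an$tukey))
jsonlite::write_json(out, "results/comparisons.json", auto_unbox = TRUE,
                     pretty = TRUE, digits = NA)
cat("Written to results/comparisons.json.\n")
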