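# Gene-set enrichment analysis: signal-to-noise gene ranking, the weighted
# Kolmogorov-Smirnov-like running-sum enrichment score, and a permutation
# null giving the normalized enrichment score (NES) and p-value.

#' Rank genes by the signal-to-noise metric
#'
#' metric = (mean_A - mean_B) / (sd_A + sd_B), with each group's sd floored
#' at max(0.2 * |group mean|, 1e-8). The list is sorted by metric descending
#' with ties broken lexicographically by gene id, so ranking is
#' deterministic.
#'
#' @param expr normalized expression matrix (genes x samples).
#' @param meta metadata with two conditions, each with >= 2 replicates.
#' @param conditions length-2 vector c(A, B); default "NoHelp"/"Help" when
#'   present, otherwise the sorted labels.
#' @return data.frame with columns gene_id, metric, sorted best-to-worst.
#' @export
rank_genes <- function(expr, meta, conditions = NULL) {
  meta <- meta[match(colnames(expr), meta$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id)) stopf("metadata does not cover all samples")
  labels <- unique(meta$condition)
  if (length(labels) != 2L) stopf("exactly two conditions required")
  if (is.null(conditions)) {
    conditions <- if (setequal(labels, c("NoHelp", "Help"))) c("NoHelp", "Help") else sort(labels)
  }
  ia <- which(meta$condition == conditions[1L])
  ib <- which(meta$condition == conditions[2L])
  if (length(ia) < 2L || length(ib) < 2L) stopf("need >= 2 replicates per condition")
  ma <- rowMeans(expr[, ia, drop = FALSE])
  mb <- rowMeans(expr[, ib, drop = FALSE])
  sa <- apply(expr[, ia, drop = FALSE], 1L, stats::sd)
  sb <- apply(expr[, ib, drop = FALSE], 1L, stats::sd)
  sa <- pmax(sa, 0.2 * abs(ma), 1e-8)
  sb <- pmax(sb, 0.2 * abs(mb), 1e-8)
  metric <- (ma - mb) / (sa + sb)
  ord <- order(-metric, rownames(expr))
  data.frame(gene_id = rownames(expr)[ord], metric = unname(metric[ord]),
             stringsAsFactors = FALSE)
}

#' Top-k up- and down-regulated gene sets from a ranked list
#'
#' @param ranked data.frame from [rank_genes()].
#' @param k set size (default 200, the conventional published-set size).
#' @return list of two `gene_set`s named `top<k>_up`, `top<k>_down`.
#' @export
top_k_sets <- function(ranked, k = 200) {
  n <- nrow(ranked)
  if (n < 2 * k) {
    stopf("ranked list has %d genes, need >= 2k = %d; lower k", n, 2 * k)
  }
  up <- gene_set(sprintf("top%d_up", k), "top upregulated genes",
                 ranked$gene_id[seq_len(k)])
  down <- gene_set(sprintf("top%d_down", k), "top downregulated genes",
                   ranked$gene_id[seq.int(n - k + 1L, n)])
  stats::setNames(list(up, down), c(up$name, down$name))
}

#' Weighted running-sum enrichment score
#'
#' Walk the ranked list: at a gene-set hit the running sum increments by
#' |metric|^p / sum over hits of |metric|^p; at a miss it decrements by
#' 1 / (N - N_hits). The enrichment score is the running-sum value of
#' maximal absolute magnitude. The leading edge contains the hits at or
#' before the extremum for positive ES, and at or after it for negative ES.
#'
#' @param ranked data.frame from [rank_genes()].
#' @param gset `gene_set` (matching to the ranked list is case-insensitive).
#' @param weight_p metric weighting exponent (default 1; 0 gives the
#'   classical unweighted KS statistic).
#' @return list with es, running_sum, leading_edge, n_hits.
#' @export
enrichment_score <- function(ranked, gset, weight_p = 1) {
  stopifnot(weight_p >= 0)
  hit <- norm_gene_ids(ranked$gene_id) %in% norm_gene_ids(gset$genes)
  nh <- sum(hit); N <- nrow(ranked)
  if (nh == 0L) stopf("gene set '%s' has no genes in the ranked list", gset$name)
  w <- abs(ranked$metric[hit])^weight_p
  if (weight_p > 0 && sum(w) == 0) {
    warnf("all hit metrics are zero; falling back to weight_p = 0")
    w <- rep(1, nh)
  }
  step <- numeric(N)
  step[hit] <- w / sum(w)
  if (nh < N) step[!hit] <- -1 / (N - nh)
  running <- cumsum(step)
  idx <- which.max(abs(running))
  es <- running[idx]
  le <- if (es >= 0) {
    ranked$gene_id[hit & seq_len(N) <= idx]
  } else {
    ranked$gene_id[hit & seq_len(N) >= idx]
  }
  list(es = es, running_sum = running, leading_edge = le, n_hits = nh)
}

# Fast ES for permutation nulls: hits given as positions in the ranked list.
# The running sum's candidate extrema sit just before and just after each
# hit, so the score needs only O(n_hits) work per permutation.
.es_from_positions <- function(absw, positions, N) {
  pos <- sort(positions)
  nh <- length(pos)
  w <- absw[pos]
  sw <- sum(w)
  if (sw == 0) w <- rep(1 / nh, nh) else w <- w / sw
  cw <- cumsum(w)
  miss <- if (nh == N) rep(0, nh) else (pos - seq_len(nh)) / (N - nh)
  after <- cw - miss       # value right after each hit
  before <- c(0, cw[-nh]) - miss  # value right before each hit
  mx <- max(after, 0)
  mn <- min(before, 0)
  if (mx >= -mn) mx else mn
}

#' Permutation GSEA test for one gene set
#'
#' Builds a null ES distribution either from random same-size gene sets
#' ("gene_set" mode, the default) or from condition-label permutations with
#' re-ranking ("phenotype" mode; switches to exhaustive enumeration of all
#' label splits when there are at most 10,000). The p-value uses the +1
#' pseudo-count convention over same-sign nulls; NES divides the observed ES
#' by the mean |null ES| of the same sign.
#'
#' @param ranked data.frame from [rank_genes()].
#' @param gset `gene_set`.
#' @param n_perm number of permutations (>= 100; default 1000).
#' @param mode "gene_set" or "phenotype".
#' @param seed integer seed; results are reproducible given the seed.
#' @param weight_p passed to [enrichment_score()].
#' @param expr,meta,conditions required for phenotype mode (to re-rank).
#' @return object of class `gsea_result`: list with set_name, size_used, es,
#'   nes, p_value, n_permutations, leading_edge, seed.
#' @export
gsea_test <- function(ranked, gset, n_perm = 1000,
                      mode = c("gene_set", "phenotype"), seed = 1,
                      weight_p = 1, expr = NULL, meta = NULL,
                      conditions = NULL) {
  mode <- match.arg(mode)
  if (n_perm < 100) stopf("n_perm must be >= 100")
  obs <- enrichment_score(ranked, gset, weight_p)
  N <- nrow(ranked)
  absw <- abs(ranked$metric)^weight_p
  if (mode == "gene_set") {
    null_es <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        .es_from_positions(absw, sample.int(N, obs$n_hits), N)
      }, numeric(1L))
    })
    n_used <- n_perm
  } else {
    if (is.null(expr) || is.null(meta)) stopf("phenotype mode needs expr and meta")
    meta <- meta[match(colnames(expr), meta$sample_id), , drop = FALSE]
    labels <- unique(meta$condition)
    nA <- sum(meta$condition == labels[1L])
    n_samples <- ncol(expr)
    n_splits <- choose(n_samples, nA)
    perm_es <- function(lab) {
      pmeta <- data.frame(sample_id = meta$sample_id, condition = lab,
                          stringsAsFactors = FALSE)
      r <- rank_genes(expr, pmeta, conditions = conditions)
      aw <- abs(r$metric)^weight_p
      pos <- which(norm_gene_ids(r$gene_id) %in% norm_gene_ids(gset$genes))
      .es_from_positions(aw, pos, N)
    }
    if (n_splits <= 10000) {
      combos <- utils::combn(n_samples, nA)
      null_es <- apply(combos, 2L, function(idx) {
        lab <- rep(labels[2L], n_samples); lab[idx] <- labels[1L]
        perm_es(lab)
      })
      n_used <- ncol(combos)
    } else {
      null_es <- with_seed(seed, {
        vapply(seq_len(n_perm), function(i) {
          perm_es(sample(meta$condition))
        }, numeric(1L))
      })
      n_used <- n_perm
    }
  }
  same <- if (obs$es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
  if (length(same) == 0L) {
    warnf("no same-sign null ES for set '%s'; p floored at 1/(1 + n_perm)", gset$name)
    p <- 1 / (1 + n_used)
    nes <- NA_real_
  } else {
    p <- (1 + sum(abs(same) >= abs(obs$es))) / (1 + length(same))
    nes <- obs$es / mean(abs(same))
  }
  structure(list(set_name = gset$name, size_used = obs$n_hits, es = obs$es,
                 nes = nes, p_value = p, n_permutations = n_used,
                 leading_edge = obs$leading_edge, seed = seed),
            class = "gsea_result")
}

#' Run GSEA over a collection of gene sets
#'
#' @param ranked data.frame from [rank_genes()].
#' @param gene_sets list of `gene_set` objects (e.g. from [read_gmt()]).
#' @param ... passed to [gsea_test()].
#' @return data.frame with one row per set: set_name, size_used, es, nes,
#'   p_value, leading_edge (comma-joined).
#' @export
run_gsea <- function(ranked, gene_sets, ...) {
  rows <- lapply(gene_sets, function(gs) {
    r <- gsea_test(ranked, gs, ...)
    data.frame(set_name = r$set_name, size_used = r$size_used, es = r$es,
               nes = r$nes, p_value = r$p_value,
               leading_edge = paste(r$leading_edge, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
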