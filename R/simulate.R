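# Synthetic-data generators: a negative-binomial reference count simulator
# with known differential expression (emulating the 3 vs 3 Help / No-Help
# vaccination design), graded centroid-mixture query profiles (emulating the
# predysfunctional-to-exhausted gradient the score is applied to), renamed
# "cross-species" variants, and the default on-disk fixture used end-to-end.
#
# Every generator is a pure function of (config, seed): the same inputs give
# byte-identical outputs.

#' Simulation configuration
#'
#' Defaults describe the default fixture: a 2,000-gene panel, 3 replicates
#' per condition, 10% DE genes at |log2FC| = 2, NB dispersion 0.1 —
#' the scale of the bulk RNA-seq reference design the pipeline targets.
#' Baseline per-gene means are log-normal (natural-log meanlog 5, sdlog
#' 1.5); library sizes are uniform on [3e5, 6e5].
#'
#' @param n_genes number of genes.
#' @param n_reps_per_condition replicates per condition.
#' @param de_fraction fraction of genes differentially expressed.
#' @param log2_fc_magnitude |log2 fold change| applied to DE genes in the
#'   NoHelp condition (half up, half down).
#' @param dispersion_phi NB dispersion (variance = mu + phi * mu^2).
#' @param mean_log_mu,sd_log_mu log-normal parameters of baseline means.
#' @param libsize_range length-2 range for uniform library sizes.
#' @param seed integer seed.
#' @return list of class `sim_config`.
#' @export
simulation_config <- function(n_genes = 2000, n_reps_per_condition = 3,
                              de_fraction = 0.1, log2_fc_magnitude = 2,
                              dispersion_phi = 0.1, mean_log_mu = 5,
                              sd_log_mu = 1.5, libsize_range = c(3e5, 6e5),
                              seed = 17) {
  stopifnot(n_genes >= 1, n_reps_per_condition >= 1,
            de_fraction >= 0, de_fraction <= 1,
            log2_fc_magnitude >= 0, dispersion_phi >= 0, sd_log_mu > 0,
            length(libsize_range) == 2L, all(libsize_range > 0),
            libsize_range[1L] <= libsize_range[2L])
  structure(list(n_genes = n_genes,
                 n_reps_per_condition = n_reps_per_condition,
                 de_fraction = de_fraction,
                 log2_fc_magnitude = log2_fc_magnitude,
                 dispersion_phi = dispersion_phi,
                 mean_log_mu = mean_log_mu, sd_log_mu = sd_log_mu,
                 libsize_range = libsize_range, seed = seed),
            class = "sim_config")
}

#' Simulate a two-condition reference count matrix with known DE
#'
#' Per-gene baseline means are drawn log-normal; a `de_fraction` subset gets
#' the configured log2 fold change applied to the NoHelp condition (half up,
#' half down); expected counts are per-condition proportions times the
#' sample's library size; counts are NB with dispersion phi (Poisson when
#' phi = 0).
#'
#' @param config a `sim_config`.
#' @return list with `counts` (matrix), `meta` (sample metadata with
#'   conditions "Help"/"NoHelp"), and `truth` (list: de_genes data.frame
#'   with gene_id/direction/log2_fc, and lib_sizes).
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    ng <- config$n_genes; nr <- config$n_reps_per_condition
    gene_ids <- sprintf("g%05d", seq_len(ng))
    mu0 <- stats::rlnorm(ng, config$mean_log_mu, config$sd_log_mu)
    n_de <- round(config$de_fraction * ng)
    de_idx <- sort(sample.int(ng, n_de))
    n_up <- ceiling(n_de / 2)
    lfc <- numeric(ng)
    lfc[de_idx[seq_len(n_up)]] <- config$log2_fc_magnitude
    if (n_de > n_up) lfc[de_idx[(n_up + 1L):n_de]] <- -config$log2_fc_magnitude
    mu_help <- mu0
    mu_nohelp <- mu0 * 2^lfc
    sample_ids <- c(paste0("Help_", seq_len(nr)), paste0("NoHelp_", seq_len(nr)))
    cond <- rep(c("Help", "NoHelp"), each = nr)
    libs <- round(stats::runif(2 * nr, config$libsize_range[1L],
                               config$libsize_range[2L]))
    draw <- function(mu_vec, lib) {
      expected <- mu_vec / sum(mu_vec) * lib
      if (config$dispersion_phi == 0) {
        stats::rpois(ng, expected)
      } else {
        stats::rnbinom(ng, size = 1 / config$dispersion_phi, mu = expected)
      }
    }
    counts <- vapply(seq_along(sample_ids), function(s) {
      draw(if (cond[s] == "Help") mu_help else mu_nohelp, libs[s])
    }, numeric(ng))
    dimnames(counts) <- list(gene_ids, sample_ids)
    list(counts = counts,
         meta = data.frame(sample_id = sample_ids, condition = cond,
                           stringsAsFactors = FALSE),
         truth = list(de_genes = data.frame(
                        gene_id = gene_ids[de_idx],
                        direction = ifelse(lfc[de_idx] > 0,
                                           "up_in_NoHelp", "down_in_NoHelp"),
                        log2_fc = lfc[de_idx],
                        stringsAsFactors = FALSE),
                      lib_sizes = stats::setNames(libs, sample_ids)))
  })
}

#' Simulate query profiles as graded mixtures of the two centroids
#'
#' Each sample is w * No-Help centroid + (1 - w) * Help centroid plus
#' gene-wise Gaussian noise with sd = `noise_sd` times the gene's centroid
#' magnitude (the mean of the two centroid values), floored at 0 so
#' expression stays non-negative.
#'
#' @param centroids `nohelp_centroids` object.
#' @param w mixture weight in [0, 1] toward the No-Help centroid.
#' @param noise_sd relative noise level (>= 0).
#' @param n_samples number of query samples to draw.
#' @param seed integer seed.
#' @return expression matrix (genes x samples) with attribute `true_w`.
#' @export
simulate_query <- function(centroids, w, noise_sd = 0.1, n_samples = 4,
                           seed = 1) {
  stopifnot(w >= 0, w <= 1, noise_sd >= 0, n_samples >= 1)
  base <- w * centroids$centroid_nohelp + (1 - w) * centroids$centroid_help
  scale <- noise_sd * (abs(centroids$centroid_nohelp) +
                       abs(centroids$centroid_help)) / 2
  ng <- length(base)
  m <- with_seed(seed, {
    vapply(seq_len(n_samples), function(s) {
      pmax(0, base + stats::rnorm(ng, 0, scale))
    }, numeric(ng))
  })
  dimnames(m) <- list(centroids$gene_ids,
                      sprintf("w%03d_s%d", round(100 * w), seq_len(n_samples)))
  structure(m, true_w = w)
}

#' Rename gene ids to emulate a second species
#'
#' Rewrites gene ids with a prefix and returns the exact one-to-one mapping
#' back to the originals, as a fixture for the cross-species scoring path.
#'
#' @param m matrix with gene-id rownames.
#' @param prefix string prepended to every gene id ("" gives an identity
#'   mapping).
#' @return list with `matrix` (renamed) and `mapping` (data.frame with
#'   source_id = new ids, target_id = original ids).
#' @export
rename_species <- function(m, prefix = "SPB_") {
  old <- rownames(m)
  new <- paste0(prefix, old)
  out <- m
  rownames(out) <- new
  list(matrix = out,
       mapping = data.frame(source_id = new, target_id = old,
                            stringsAsFactors = FALSE))
}

#' Write the default end-to-end fixture to disk
#'
#' Generates the default reference set (2,000 genes, 3 vs 3, 10% DE at
#' |log2FC| = 2, phi = 0.1, seed 17), a 5-level mixture query panel
#' (w in {0, 0.25, 0.5, 0.75, 1}, 4 samples each) built on centroids over
#' the true DE genes, a renamed "species B" copy of the query panel with its
#' mapping table, and a GMT holding the true up/down DE gene sets. All files
#' are plain text and byte-stable across regenerations.
#'
#' @param dir output directory (created if needed).
#' @param config simulation configuration (default `simulation_config()`).
#' @param weights mixture weights of the query panel.
#' @param n_query_samples samples per mixture level.
#' @param noise_sd relative query noise level.
#' @return invisibly, a named list of the file paths written.
#' @export
make_default_fixture <- function(dir, config = simulation_config(),
                                 weights = c(0, 0.25, 0.5, 0.75, 1),
                                 n_query_samples = 4, noise_sd = 0.1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ref <- simulate_reference(config)
  paths <- list(
    counts = file.path(dir, "ref_counts.tsv"),
    meta = file.path(dir, "ref_meta.tsv"),
    truth = file.path(dir, "truth_de_genes.tsv"),
    query = file.path(dir, "query_expr.tsv"),
    query_meta = file.path(dir, "query_meta.tsv"),
    species_query = file.path(dir, "speciesB_query_expr.tsv"),
    mapping = file.path(dir, "speciesB_gene_mapping.tsv"),
    gmt = file.path(dir, "true_de_sets.gmt"),
    manifest = file.path(dir, "manifest.json"))
  write_counts(ref$counts, paths$counts)
  write_metadata(ref$meta, paths$meta)
  utils::write.table(ref$truth$de_genes, paths$truth, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  # centroids over the true DE genes, on CPM of the reference
  expr <- cpm(ref$counts)
  truth_sig <- data.frame(gene_id = ref$truth$de_genes$gene_id,
                          stringsAsFactors = FALSE)
  cent <- compute_centroids(expr, ref$meta, truth_sig,
                            conditions = c("NoHelp", "Help"))
  panels <- lapply(seq_along(weights), function(i) {
    simulate_query(cent, weights[i], noise_sd = noise_sd,
                   n_samples = n_query_samples, seed = config$seed + i)
  })
  query <- do.call(cbind, panels)
  write_expression(query, paths$query)
  qmeta <- data.frame(
    sample_id = colnames(query),
    condition = rep(sprintf("w%03d", round(100 * weights)),
                    each = n_query_samples),
    true_w = rep(weights, each = n_query_samples))
  utils::write.table(qmeta, paths$query_meta, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sp <- rename_species(query, "SPB_")
  write_expression(sp$matrix, paths$species_query)
  write_mapping(sp$mapping, paths$mapping)
  de <- ref$truth$de_genes
  sets <- list(gene_set("true_up_in_NoHelp", "simulated upregulated genes",
                        de$gene_id[de$direction == "up_in_NoHelp"]),
               gene_set("true_down_in_NoHelp", "simulated downregulated genes",
                        de$gene_id[de$direction == "down_in_NoHelp"]))
  write_gmt(sets, paths$gmt)
  write_run_manifest(paths$manifest, step = "simulate",
                     config = unclass(config), weights = weights,
                     n_query_samples = n_query_samples, noise_sd = noise_sd)
  invisible(paths)
}
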