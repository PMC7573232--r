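test_that("effective library scales track depth and TMM factors", {
  m <- random_counts(100, 4, seed = 11)
  s <- effective_lib_scale(m)
  expect_equal(unname(s), unname(colSums(m)))
  m2 <- cbind(m, s05 = 2 * m[, 1])
  s2 <- effective_lib_scale(m2)
  expect_equal(unname(s2["s05"]), unname(2 * s2["s01"]))
  st <- effective_lib_scale(m, use_tmm = TRUE)
  expect_equal(unname(st), unname(colSums(m) * tmm_factors(m)))
})

test_that("exact test reduces to the two-sided binomial test at phi = 0", {
  for (total in c(1, 7, 20, 50)) {
    for (k in 0:total) {
      p_impl <- nb_exact_test(c(k, 0, 0), c(total - k, 0, 0), phi = 0)
      p_binom <- binom.test(k, total, 0.5)$p.value
      expect_equal(p_impl, min(1, p_binom), tolerance = 1e-9,
                   label = sprintf("T=%d k=%d", total, k))
    }
  }
})

test_that("exact test matches the brute-force NB enumeration oracle", {
  for (phi in c(0.1, 0.5, 2)) {
    for (total in c(5, 17, 42)) {
      for (k in 0:total) {
        p_impl <- nb_exact_test(c(k, 0, 0), c(total - k, 0, 0), phi = phi)
        p_orc <- oracle_exact_p(k, total, nA = 3, nB = 3, phi = phi)
        expect_equal(p_impl, p_orc, tolerance = 1e-10,
                     label = sprintf("phi=%g T=%d k=%d", phi, total, k))
      }
    }
  }
  # unequal group sizes
  for (k in c(0, 4, 10, 19)) {
    p_impl <- nb_exact_test(c(k, 0), c(19 - k, 0, 0), phi = 0.5)
    expect_equal(p_impl, oracle_exact_p(k, 19, nA = 2, nB = 3, phi = 0.5),
                 tolerance = 1e-10)
  }
})

test_that("exact test is symmetric, modal at even splits, and monotone off the mode", {
  expect_equal(nb_exact_test(c(10, 2, 1), c(4, 3, 2), 0.3),
               nb_exact_test(c(4, 3, 2), c(10, 2, 1), 0.3))
  # balanced design, even total: observed split at T/2 is modal, p = 1
  expect_equal(nb_exact_test(c(15, 0, 0), c(15, 0, 0), 0), 1)
  expect_equal(nb_exact_test(c(15, 0, 0), c(15, 0, 0), 0.4), 1)
  # p non-increasing as the split moves away from the conditional mode
  for (phi in c(0, 0.5)) {
    for (total in c(10, 30)) {
      p_seq <- vapply(floor(total / 2):total, function(k) {
        nb_exact_test(c(k, 0, 0), c(total - k, 0, 0), phi)
      }, numeric(1))
      expect_true(all(diff(p_seq) <= 1e-12))
    }
  }
  # zero total is p = 1 by convention
  expect_equal(nb_exact_test(c(0, 0), c(0, 0), 0.1), 1)
})

test_that("per-sample scales are absorbed before conditioning", {
  # a shared scale cancels exactly (pseudo-counts are untouched)
  p1 <- nb_exact_test(c(6, 8, 7), c(20, 25, 22), 0.2)
  p_shared <- nb_exact_test(c(6, 8, 7), c(20, 25, 22), 0.2,
                            scales = rep(3.7, 6))
  expect_equal(p1, p_shared)
  # doubling one sample's counts and its scale is absorbed up to the
  # half-up rounding of the rescaled pseudo-counts
  p2 <- nb_exact_test(c(12, 8, 7), c(20, 25, 22), 0.2,
                      scales = c(2, 1, 1, 1, 1, 1))
  expect_equal(p1, p2, tolerance = 0.05)
})

test_that("BH q-values equal the step-up definition and are permutation-invariant", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_identical(bh_fdr(numeric(0)), numeric(0))
  for (seed in 1:10) {
    p <- withr::with_seed(seed, runif(sample(2:12, 1))^2)
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    perm <- withr::with_seed(seed + 100, sample(length(p)))
    expect_equal(bh_fdr(p[perm]), q[perm], tolerance = 1e-12)
    expect_true(all(diff(q[order(p)]) >= -1e-15))  # monotone in sorted-p order
  }
})

test_that("common dispersion estimation recovers the generating dispersion", {
  s0 <- simulate_reference(simulation_config(n_genes = 2000, dispersion_phi = 0,
                                             de_fraction = 0, seed = 31))
  d0 <- estimate_common_dispersion(s0$counts, s0$meta)
  expect_lte(d0$phi, 0.01)

  s2 <- simulate_reference(simulation_config(n_genes = 2000, dispersion_phi = 0.2,
                                             de_fraction = 0, seed = 32))
  d2 <- estimate_common_dispersion(s2$counts, s2$meta)
  expect_gte(d2$phi, 0.1)
  expect_lte(d2$phi, 0.4)

  # zero within-group variance drives the estimate to the grid floor
  m <- matrix(rep(c(10, 25, 40), each = 4), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  meta <- split_meta(m)
  dz <- estimate_common_dispersion(m, meta)
  expect_lte(dz$phi, 2e-4)

  one <- m[, c(1, 3), drop = FALSE]
  expect_error(estimate_common_dispersion(one, split_meta(one)),
               "not estimable")
})

test_that("derive_signature recovers simulated DE genes and returns none without signal", {
  s <- simulate_reference(simulation_config(n_genes = 1000, seed = 41))
  sig <- derive_signature(s$counts, s$meta)
  truth <- s$truth$de_genes
  expect_gte(mean(truth$gene_id %in% sig$gene_id), 0.6)
  expect_lte(mean(!(sig$gene_id %in% truth$gene_id)), 0.05)
  # direction agrees with the simulated fold change for recovered genes
  hit <- merge(sig, truth, by = "gene_id")
  expect_true(all(hit$direction.x == hit$direction.y))
  # deterministic ordering: q asc, |lfc| desc, gene id
  expect_true(all(diff(sig$q_value) >= 0))
  expect_true(all(sig$q_value < 0.01))

  # duplicated condition matrices carry no signal
  m <- random_counts(300, 3, seed = 42)
  dup <- cbind(m, m)
  colnames(dup) <- paste0("s", 1:6)
  sig0 <- suppressWarnings(derive_signature(dup, split_meta(dup)))
  expect_equal(nrow(sig0), 0L)
})

test_that("signature tables round-trip through TSV", {
  s <- simulate_reference(simulation_config(n_genes = 500, seed = 43))
  sig <- derive_signature(s$counts, s$meta)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_signature(sig, path)
  back <- read_signature(path)
  expect_equal(back$gene_id, sig$gene_id)
  expect_equal(back$q_value, sig$q_value, tolerance = 1e-12)
})

test_that("exact test agrees with edgeR's exact test to first order", {
  skip_if_not_installed("edgeR")
  # equal library sizes so pseudo-count machinery is a no-op in both
  s <- simulate_reference(simulation_config(n_genes = 400, seed = 44,
                                            libsize_range = c(5e5, 5e5)))
  phi <- 0.1
  ia <- s$meta$condition == "NoHelp"
  p_mine <- vapply(seq_len(nrow(s$counts)), function(g) {
    nb_exact_test(s$counts[g, ia], s$counts[g, !ia], phi)
  }, numeric(1))
  dge <- edgeR::DGEList(counts = s$counts, group = s$meta$condition)
  dge$samples$norm.factors <- 1
  dge$common.dispersion <- phi
  et <- edgeR::exactTest(dge, pair = c("Help", "NoHelp"))
  # same conditioning idea but edgeR quantile-adjusts; ranks should agree
  expect_gte(cor(log(p_mine + 1e-300), log(et$table$PValue + 1e-300)), 0.98)
})
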