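test_that("pearson matches an independent two-pass implementation", {
  expect_equal(pearson(1:5, 1:5), 1)
  expect_equal(pearson(1:5, -(1:5)), -1)
  x <- c(1, 2, 3); y <- c(2, 2, 5)
  two_pass <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson(x, y), two_pass, tolerance = 1e-12)
  expect_error(pearson(c(1, 1, 1), y), "degenerate")
  expect_error(pearson(1:3, 1:4), "length")
  expect_error(pearson(1:2, 2:3), "at least 3")
})

make_test_centroids <- function(n_genes = 60, seed = 7) {
  withr::with_seed(seed, {
    cn <- rlnorm(n_genes, 4, 1)
    ch <- cn * 2^rnorm(n_genes, 0, 1)
    structure(list(gene_ids = sprintf("g%03d", seq_len(n_genes)),
                   centroid_nohelp = cn, centroid_help = ch,
                   normalization = list(units = "CPM", log2 = FALSE)),
              class = "nohelp_centroids")
  })
}

swap_centroids <- function(cent) {
  tmp <- cent$centroid_nohelp
  cent$centroid_nohelp <- cent$centroid_help
  cent$centroid_help <- tmp
  cent
}

test_that("centroids are per-condition means over the signature overlap", {
  m <- random_counts(50, 6, seed = 8)
  meta <- split_meta(m, c("NoHelp", "Help"))
  expr <- cpm(m)
  sig <- data.frame(gene_id = rownames(m)[1:20])
  cent <- compute_centroids(expr, meta, sig, conditions = c("NoHelp", "Help"))
  expect_identical(cent$gene_ids, rownames(m)[1:20])
  expect_equal(cent$centroid_nohelp,
               unname(rowMeans(expr[1:20, meta$condition == "NoHelp"])))
  expect_equal(cent$centroid_help,
               unname(rowMeans(expr[1:20, meta$condition == "Help"])))

  # duplicated replicates leave the centroid unchanged
  expr2 <- cbind(expr, expr)
  colnames(expr2) <- paste0("s", 1:12)
  meta2 <- rbind(meta, meta)
  meta2$sample_id <- colnames(expr2)
  cent2 <- compute_centroids(expr2, meta2, sig, conditions = c("NoHelp", "Help"))
  expect_equal(cent2$centroid_nohelp, cent$centroid_nohelp)

  # single replicate per condition: centroid equals the sample profile
  e1 <- expr[, c(1, 4)]
  m1 <- meta[c(1, 4), ]
  cent1 <- compute_centroids(e1, m1, sig, conditions = c("NoHelp", "Help"))
  expect_equal(cent1$centroid_nohelp, unname(e1[1:20, m1$condition == "NoHelp"]))

  # signature genes absent from the reference are dropped; too few is an error
  sig_big <- data.frame(gene_id = c(sig$gene_id, "absent1", "absent2"))
  cent3 <- compute_centroids(expr, meta, sig_big, conditions = c("NoHelp", "Help"))
  expect_identical(cent3$gene_ids, cent$gene_ids)
  sig_tiny <- data.frame(gene_id = c("g0001", "absentX"))
  expect_error(compute_centroids(expr, meta, sig_tiny,
                                 conditions = c("NoHelp", "Help")),
               "min_overlap")
})

test_that("the No Help score is the correlation difference with exact algebra", {
  cent <- make_test_centroids()
  prof <- setNames(cent$centroid_nohelp, cent$gene_ids)
  r <- no_help_score(prof, cent)
  expect_equal(r$r_nohelp, 1)
  expect_equal(r$no_help_score, 1 - pearson(cent$centroid_nohelp, cent$centroid_help))
  expect_gte(r$no_help_score, 0)

  # swap antisymmetry, range, shift/scale invariance on random profiles
  for (seed in 1:25) {
    prof <- withr::with_seed(seed, setNames(rlnorm(60, 4, 1), cent$gene_ids))
    a <- no_help_score(prof, cent)
    b <- no_help_score(prof, swap_centroids(cent))
    expect_identical(a$no_help_score, -b$no_help_score)
    expect_identical(a$r_nohelp, b$r_help)
    expect_true(abs(a$no_help_score) <= 2)
    shifted <- no_help_score(prof + 13.7, cent)
    scaled <- no_help_score(prof * 3.1, cent)
    expect_equal(shifted$no_help_score, a$no_help_score, tolerance = 1e-10)
    expect_equal(scaled$no_help_score, a$no_help_score, tolerance = 1e-10)
  }

  expect_error(no_help_score(setNames(rep(1, 60), cent$gene_ids), cent),
               "degenerate")
  expect_error(no_help_score(setNames(1:5, cent$gene_ids[1:5]), cent),
               "min_overlap")
})

test_that("mixture profiles score monotonically in the mixing weight", {
  cent <- make_test_centroids(n_genes = 150, seed = 12)
  ws <- c(0, 0.25, 0.5, 0.75, 1)
  ok <- vapply(1:50, function(rep) {
    means <- vapply(seq_along(ws), function(i) {
      q <- simulate_query(cent, ws[i], noise_sd = 0.1, n_samples = 4,
                          seed = 1000 + rep * 10 + i)
      mean(score_samples(q, cent)$no_help_score)
    }, numeric(1))
    cor(ws, means, method = "spearman")
  }, numeric(1))
  expect_gte(mean(ok >= 0.95), 0.95)
})

test_that("gene-id mapping preserves scores exactly (renaming invariance)", {
  cent <- make_test_centroids()
  prof <- withr::with_seed(3, setNames(rlnorm(60, 4, 1), cent$gene_ids))
  renamed <- rename_species(as.matrix(prof), "SPB_")
  mapped <- map_profile(renamed$matrix[, 1], renamed$mapping)
  expect_identical(no_help_score(mapped, cent)$no_help_score,
                   no_help_score(prof, cent)$no_help_score)

  # identity mapping, partial coverage, empty result
  idmap <- data.frame(source_id = names(prof), target_id = names(prof))
  expect_identical(map_profile(prof, idmap), prof)
  half <- idmap[1:30, ]
  expect_length(map_profile(prof, half), 30L)
  none <- data.frame(source_id = "zzz", target_id = "yyy")
  expect_error(map_profile(prof, none), "no genes")
})

test_that("pooled t-test matches closed form, permutation oracle, and invariances", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  r <- compare_two_groups(a, b)
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(r$statistic, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(r$p_value, tt$p.value, tolerance = 1e-10)

  # permutation oracle: with moderate group sizes the permutation null of
  # the pooled t statistic tracks the t distribution closely
  ga <- withr::with_seed(31, rnorm(10))
  gb <- withr::with_seed(32, rnorm(10, mean = 0.9))
  rp <- compare_two_groups(ga, gb)
  pooled <- c(ga, gb)
  perm_p <- withr::with_seed(99, {
    obs <- abs(rp$statistic)
    hits <- replicate(1e5, {
      idx <- sample(20, 10)
      g1 <- pooled[idx]; g2 <- pooled[-idx]
      sp2 <- (9 * var(g1) + 9 * var(g2)) / 18
      abs((mean(g1) - mean(g2)) / sqrt(sp2 * 0.2)) >= obs - 1e-12
    })
    mean(hits)
  })
  expect_equal(rp$p_value, perm_p,
               tolerance = 3 * sqrt(perm_p * (1 - perm_p) / 1e5) + 0.02)

  r2 <- compare_two_groups(a * 5.5, b * 5.5)
  expect_equal(r2$statistic, r$statistic, tolerance = 1e-12)
  expect_equal(r2$p_value, r$p_value, tolerance = 1e-12)

  same <- compare_two_groups(c(1, 2), c(1, 2))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(compare_two_groups(c(1, 1), c(2, 2)), "zero pooled variance")
  expect_error(compare_two_groups(1, c(1, 2)), ">= 2")
})

test_that("repeated-measures ANOVA matches the aov decomposition and Tukey is calibrated", {
  tbl <- withr::with_seed(5, matrix(rnorm(12, mean = rep(c(0, 1, 3), each = 4)),
                                    nrow = 4,
                                    dimnames = list(paste0("subj", 1:4),
                                                    c("c1", "c2", "c3"))))
  r <- compare_matched_groups(tbl)
  # independent route: aov on the long table with subject as block
  long <- data.frame(y = as.vector(tbl),
                     subj = factor(rep(rownames(tbl), 3)),
                     cond = factor(rep(colnames(tbl), each = 4)))
  fit <- summary(aov(y ~ cond + subj, data = long))[[1]]
  expect_equal(r$statistic, fit["cond", "F value"], tolerance = 1e-10)
  expect_equal(r$p_value, fit["cond", "Pr(>F)"], tolerance = 1e-10)

  # Tukey p for the most separated pair is smallest
  expect_equal(r$tukey$p_value[which.max(abs(r$tukey$diff))],
               min(r$tukey$p_value))

  # all conditions identical per subject: F = 0, Tukey p = 1
  flat <- matrix(rep(c(1, 2, 3, 4), 3), nrow = 4,
                 dimnames = list(paste0("s", 1:4), c("a", "b", "c")))
  rf <- compare_matched_groups(flat)
  expect_equal(rf$statistic, 0)
  expect_true(all(rf$tukey$p_value == 1))

  # equal-mean pair keeps a large Tukey p
  tbl2 <- tbl; tbl2[, 2] <- tbl2[, 1] + withr::with_seed(8, rnorm(4, 0, 0.01))
  r2 <- compare_matched_groups(tbl2)
  pair12 <- r2$tukey$p_value[r2$tukey$group1 == "c1" & r2$tukey$group2 == "c2"]
  expect_gte(pair12, 0.99)

  expect_error(compare_matched_groups(tbl[1, , drop = FALSE]), ">= 2 subjects")
  tbl[2, 3] <- NA
  expect_error(compare_matched_groups(tbl), "incomplete")
})

test_that("Tukey tail probabilities agree with a Monte-Carlo studentized-range oracle", {
  k <- 3; df <- 6
  for (q in c(1.5, 3, 4.5)) {
    mc <- withr::with_seed(17, {
      draws <- replicate(4e4, {
        z <- rnorm(k)
        s <- sqrt(rchisq(1, df) / df)
        (max(z) - min(z)) / s
      })
      mean(draws >= q)
    })
    p <- ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
    se <- sqrt(mc * (1 - mc) / 4e4)
    expect_lte(abs(p - mc), 3 * se + 1e-4)
  }
})
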