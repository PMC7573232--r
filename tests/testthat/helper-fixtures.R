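# Shared fixture builders; everything is generated in code under fixed seeds.

random_counts <- function(n_genes, n_samples, seed, lambda = 50) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n_genes * n_samples, lambda), nrow = n_genes,
                dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                                sprintf("s%02d", seq_len(n_samples))))
    storage.mode(m) <- "double"
    m
  })
}

# metadata with first half = labels[1], second half = labels[2]
split_meta <- function(m, labels = c("Help", "NoHelp")) {
  n <- ncol(m)
  data.frame(sample_id = colnames(m),
             condition = rep(labels, each = ceiling(n / 2))[seq_len(n)],
             stringsAsFactors = FALSE)
}

# Independent brute-force oracle for the conditional exact test: builds the
# conditional split pmf from the product of the two group NB (or Poisson)
# densities at an arbitrary mean, then applies the same minimum-likelihood
# two-sided rule. A different computational route from the implementation,
# which works with log-gamma ratios and never references a mean.
oracle_exact_p <- function(k_obs, total, nA, nB, phi, mu = 7.3) {
  k <- 0:total
  if (phi == 0) {
    probs <- dpois(k, nA * mu) * dpois(total - k, nB * mu)
  } else {
    probs <- dnbinom(k, size = nA / phi, mu = nA * mu) *
      dnbinom(total - k, size = nB / phi, mu = nB * mu)
  }
  probs <- probs / sum(probs)
  min(1, sum(probs[probs <= probs[k_obs + 1] * (1 + 1e-12)]))
}

# Independent BH step-up: literal q(i) = min_{j >= i} p_(j) * m / j in
# explicit loops, reported in input order.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    vals <- numeric(0)
    for (j in i:m) vals <- c(vals, p[ord[j]] * m / j)
    q_sorted[i] <- min(1, min(vals))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Literal walk-the-list running sum per the weighted KS definition.
oracle_running_sum <- function(metric, hit, weight_p) {
  N <- length(metric)
  nh <- sum(hit)
  w <- abs(metric[hit])^weight_p
  denom_hit <- sum(w)
  run <- numeric(N)
  acc <- 0
  j <- 0
  for (i in seq_len(N)) {
    if (hit[i]) {
      j <- j + 1
      acc <- acc + w[j] / denom_hit
    } else {
      acc <- acc - 1 / (N - nh)
    }
    run[i] <- acc
  }
  run
}
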