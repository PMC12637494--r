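# Independent oracles and small fixture builders used across the suite.

# adjusted Rand index, direct from the pair-counting definition
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# two-sided Fisher p by exhaustive enumeration over margin-constrained tables
enum_fisher_p <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  probs <- dhyper(lo:hi, r1, r2, c1)
  p0 <- dhyper(a, r1, r2, c1)
  sum(probs[probs <= p0 * (1 + 1e-7)])
}

# Ward-D2 agglomeration via the Lance-Williams recurrence on squared
# Euclidean distances; returns the sorted merge heights
ward_heights_lw <- function(x) {
  n <- nrow(x)
  d2 <- as.matrix(dist(x))^2
  size <- rep(1, n)
  active <- rep(TRUE, n)
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    idx <- which(active)
    best <- c(NA, NA); bestv <- Inf
    for (i in idx) for (j in idx) if (i < j && d2[i, j] < bestv) {
      bestv <- d2[i, j]; best <- c(i, j)
    }
    i <- best[1]; j <- best[2]
    heights[step] <- sqrt(bestv)
    ni <- size[i]; nj <- size[j]
    for (k in idx) {
      if (k == i || k == j) next
      nk <- size[k]
      d2[i, k] <- d2[k, i] <-
        ((ni + nk) * d2[i, k] + (nj + nk) * d2[j, k] - nk * d2[i, j]) /
          (ni + nj + nk)
    }
    size[i] <- ni + nj
    active[j] <- FALSE
  }
  sort(heights)
}

# toy genome with balanced planted 8-level blocks (used for the
# subcompartment recovery checks)
block_genome <- function(n_chrom = 2, blocks_per_level = 4,
                         block_size = 1e6, bin_size = 1e5, seed = 1,
                         conditions = "NC") {
  set.seed(seed)
  nb <- 8 * blocks_per_level
  len <- nb * block_size
  chroms <- stats::setNames(rep(len, n_chrom), paste0("chr", seq_len(n_chrom)))
  blocks <- purrr::map_dfr(names(chroms), function(chr) {
    tibble::tibble(chrom = chr,
                   start = seq(0, len - block_size, by = block_size),
                   end = seq(block_size, len, by = block_size),
                   activity = sample(rep(seq(0, 1, length.out = 8),
                                         each = blocks_per_level)))
  })
  sim_genome(chroms, bin_size, blocks = blocks, conditions = conditions)
}

# small symmetric Poisson contact matrix on one or two chromosomes
toy_matrix <- function(mu, chrom = rep("c", nrow(mu)), seed = 1,
                       bin_size = 1e5) {
  set.seed(seed)
  n <- nrow(mu)
  m <- matrix(0, n, n)
  ut <- upper.tri(m, diag = TRUE)
  m[ut] <- rpois(sum(ut), mu[ut])
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  bins <- tibble::tibble(chrom = chrom,
                         start = (seq_len(n) - 1) * bin_size,
                         end = seq_len(n) * bin_size)
  contact_matrix(bins, m)
}
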