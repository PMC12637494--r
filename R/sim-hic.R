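#' Expected contact surface implied by a layout and simulation settings
#'
#' Deterministic mean matrix used by [sim_hic_replicates()]: cis pairs decay
#' as a power law of bin distance, all pairs are modulated by the similarity
#' of the two bins' planted activities (`s = 1 - |a_i - a_j|`, so `s` is in
#' `[0, 1]`, symmetric, with unit diagonal), and planted pairs are multiplied
#' by their fold in their condition.
#'
#' @param layout A [sim_genome()] layout.
#' @param condition Condition whose activity (and planted pairs) apply.
#' @param decay_exponent Cis power-law exponent (distance in bins; the
#'   self-distance term is treated as 1).
#' @param cis_scale,trans_scale Expected counts at unit distance / for trans
#'   pairs, before compartment modulation.
#' @param compartment_affinity Non-negative modulation strength `kappa`:
#'   expected counts scale with `1 + kappa * s`.
#' @param planted_pairs Optional data frame (`bin1`, `bin2`, `condition`,
#'   `fold`), `fold > 0`.
#' @return Symmetric numeric matrix of expected counts.
#' @export
expected_hic_matrix <- function(layout, condition,
                                decay_exponent = 1,
                                cis_scale = 100,
                                trans_scale = 2,
                                compartment_affinity = 0,
                                planted_pairs = NULL) {
  a <- layout$condition_activity[[condition]]
  if (is.null(a)) stop("unknown condition: ", condition)
  stopifnot(compartment_affinity >= 0, cis_scale > 0, trans_scale >= 0)
  n <- nrow(layout$bins)
  s <- 1 - abs(outer(a, a, "-"))
  idx <- seq_len(n)
  d <- abs(outer(idx, idx, "-"))
  cis <- cis_mask(list(bins = layout$bins))
  dpow <- pmax(d, 1)^(-decay_exponent)
  mu <- matrix(trans_scale, n, n)
  mu[cis] <- cis_scale * dpow[cis]
  mu <- mu * (1 + compartment_affinity * s)
  if (!is.null(planted_pairs)) {
    pp <- planted_pairs[planted_pairs$condition == condition, , drop = FALSE]
    if (nrow(pp)) {
      if (any(pp$fold <= 0)) stop("planted fold must be > 0")
      mu[cbind(pp$bin1, pp$bin2)] <- mu[cbind(pp$bin1, pp$bin2)] * pp$fold
      mu[cbind(pp$bin2, pp$bin1)] <- mu[cbind(pp$bin2, pp$bin1)] * pp$fold
    }
  }
  mu
}

#' Plant condition-specific trans gains between subtelomeric bins
#'
#' Picks interchromosomal bin pairs whose members both lie in the terminal
#' fraction of their chromosomes, emulating the subtelomeric trans-contact
#' gains seen under confinement (gained at one condition, optionally
#' partially reverted at another).
#'
#' @param layout A [sim_genome()] layout.
#' @param n_pairs Number of pairs to plant.
#' @param condition Condition in which the fold applies.
#' @param fold Multiplicative gain (> 1 for enrichment).
#' @param terminal_fraction Fraction of each chromosome counted as
#'   subtelomeric (default 0.1, i.e. the terminal 10 percent of each arm end).
#' @param seed Integer seed.
#' @return Tibble (`bin1`, `bin2`, `condition`, `fold`) with `bin1 < bin2`.
#' @export
subtelomeric_pairs <- function(layout, n_pairs, condition, fold,
                               terminal_fraction = 0.1, seed = 1L) {
  set.seed(seed)
  bins <- layout$bins
  lens <- stats::setNames(layout$chromosomes$length, layout$chromosomes$chrom)
  L <- lens[bins$chrom]
  subtel <- bins$start < terminal_fraction * L |
    bins$end > (1 - terminal_fraction) * L
  cand <- bins$bin[subtel]
  if (length(cand) < 2) stop("too few subtelomeric bins")
  pairs <- matrix(nrow = 0, ncol = 2)
  guard <- 0
  while (nrow(pairs) < n_pairs && guard < 1000 * n_pairs) {
    p <- sort(sample(cand, 2))
    guard <- guard + 1
    if (bins$chrom[p[1]] == bins$chrom[p[2]]) next
    if (nrow(pairs) && any(pairs[, 1] == p[1] & pairs[, 2] == p[2])) next
    pairs <- rbind(pairs, p)
  }
  tibble::tibble(bin1 = pairs[, 1], bin2 = pairs[, 2],
                 condition = condition, fold = fold)
}

#' Simulate replicate Hi-C contact maps with planted structure
#'
#' Draws integer, symmetric replicate contact maps per condition around the
#' expected surface of [expected_hic_matrix()], using Poisson or
#' negative-binomial pixel noise. Ground truth (planted per-bin 8-state
#' labels per condition and the planted pair list) is returned alongside.
#'
#' @inheritParams expected_hic_matrix
#' @param layout A [sim_genome()] layout.
#' @param replicates_per_condition Number of replicates per condition.
#' @param noise_model `"poisson"` or `"negative_binomial"`.
#' @param dispersion NB dispersion (variance `mu + dispersion * mu^2`);
#'   ignored for Poisson.
#' @param conditions Conditions to simulate (default: all in the layout).
#' @param seed Integer seed.
#' @return A list with `matrices` (named list: condition -> list of
#'   [contact_matrix()] replicates) and `truth` (list with `bin_label`
#'   tibble over conditions and the `planted_pairs` table).
#' @export
#' @examples
#' gl <- sim_genome(c(chrA = 1e6, chrB = 1e6), bin_size = 1e5)
#' sim <- sim_hic_replicates(gl, replicates_per_condition = 2, seed = 7)
#' sim$matrices$NC[[1]]
sim_hic_replicates <- function(layout,
                               decay_exponent = 1,
                               cis_scale = 100,
                               trans_scale = 2,
                               compartment_affinity = 0,
                               noise_model = c("poisson", "negative_binomial"),
                               dispersion = 0.05,
                               replicates_per_condition = 3,
                               planted_pairs = NULL,
                               conditions = names(layout$condition_activity),
                               seed = 1L) {
  noise_model <- match.arg(noise_model)
  stopifnot(replicates_per_condition >= 1, dispersion >= 0)
  set.seed(seed)
  n <- nrow(layout$bins)
  ut <- upper.tri(matrix(0, n, n), diag = TRUE)

  draw <- function(mu) {
    m <- matrix(0, n, n)
    if (noise_model == "poisson") {
      m[ut] <- rpois(sum(ut), mu[ut])
    } else {
      m[ut] <- rnbinom(sum(ut), mu = mu[ut], size = 1 / max(dispersion, 1e-12))
    }
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    m
  }

  matrices <- lapply(conditions, function(cond) {
    mu <- expected_hic_matrix(layout, cond, decay_exponent, cis_scale,
                              trans_scale, compartment_affinity, planted_pairs)
    lapply(seq_len(replicates_per_condition), function(r)
      contact_matrix(layout$bins, draw(mu)))
  })
  names(matrices) <- conditions

  bin_label <- purrr::map_dfr(conditions, function(cond)
    tibble::add_column(layout_truth_labels(layout, cond),
                       condition = cond, .before = 1))
  list(matrices = matrices,
       truth = list(bin_label = bin_label, planted_pairs = planted_pairs))
}
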