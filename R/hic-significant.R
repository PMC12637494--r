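#' Call significant Hi-C interactions against an expected model
#'
#' Poisson upper-tail test per bin pair (`p = P(X >= obs | mu = expected)`),
#' Benjamini-Hochberg adjustment over all tested pairs, and a log-ratio
#' filter: a pair passes when `q <= fdr` *and* `log2(obs / exp)` reaches the
#' mode-specific threshold (trans default 1.5, cis 2.0). Pairs with zero
#' expected value are excluded from testing.
#'
#' @param cm A [contact_matrix()] of observed counts.
#' @param expected Expected matrix (default [expected_contacts()] of `cm`).
#' @param fdr FDR threshold on the adjusted p-value.
#' @param logratio_trans,logratio_cis Minimum log2 observed/expected for
#'   interchromosomal and intrachromosomal pairs.
#' @return Tibble of tested pairs (`bin1 < bin2`): `bin1`, `bin2`, `cis`,
#'   `observed`, `expected`, `log_ratio`, `p`, `q`, `passes`.
#' @export
significant_interactions <- function(cm, expected = expected_contacts(cm),
                                     fdr = 0.01,
                                     logratio_trans = 1.5,
                                     logratio_cis = 2.0) {
  n <- nrow(cm$counts)
  ut <- which(upper.tri(cm$counts), arr.ind = TRUE)
  exp_v <- expected[ut]
  keep <- exp_v > 0
  ut <- ut[keep, , drop = FALSE]
  exp_v <- exp_v[keep]
  obs <- cm$counts[ut]
  cis <- cm$bins$chrom[ut[, 1]] == cm$bins$chrom[ut[, 2]]
  log_ratio <- log2(obs / exp_v)
  p <- ppois(obs - 1, exp_v, lower.tail = FALSE)
  q <- p.adjust(p, method = "BH")
  thr <- ifelse(cis, logratio_cis, logratio_trans)
  tibble::tibble(bin1 = ut[, 1], bin2 = ut[, 2], cis = cis,
                 observed = obs, expected = exp_v,
                 log_ratio = log_ratio, p = p, q = q,
                 passes = q <= fdr & log_ratio >= thr)
}

#' Replicate consensus of interaction calls
#'
#' Keeps bin pairs that pass in at least `min_reps` replicates (exact pair
#' identity).
#'
#' @param calls List of [significant_interactions()] tibbles on the same
#'   bin grid.
#' @param min_reps Minimum supporting replicates (default 2 of 3).
#' @return Tibble `bin1`, `bin2`, `n_reps` of retained pairs.
#' @export
replicate_consensus_interactions <- function(calls, min_reps = 2) {
  passing <- purrr::map_dfr(calls, function(x)
    x[x$passes, c("bin1", "bin2")])
  if (nrow(passing) == 0L)
    return(tibble::tibble(bin1 = integer(), bin2 = integer(),
                          n_reps = integer()))
  out <- dplyr::summarise(dplyr::group_by(passing, .data$bin1, .data$bin2),
                          n_reps = dplyr::n(), .groups = "drop")
  out[out$n_reps >= min_reps, ]
}
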