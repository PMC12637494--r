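#' Iterative-correction (ICE) balancing weights
#'
#' Computes per-bin weights `w` such that the balanced matrix
#' `w[i] * w[j] * counts[i, j]` has equal row sums over unmasked bins.
#' All-zero bins are masked (`NA` weight). Convergence is declared when the
#' maximum relative deviation of unmasked row sums from their mean falls
#' below `tol`; if the iteration budget is exhausted first, the weights are
#' returned with `converged = FALSE`.
#'
#' @param cm A [contact_matrix()] (or plain symmetric matrix).
#' @param tol Relative row-sum tolerance.
#' @param max_iter Iteration cap.
#' @return For a `contact_matrix` input, the object with `weights` set and
#'   an attribute `converged` on the weights; for a matrix input, the weight
#'   vector.
#' @export
balance_ice <- function(cm, tol = 1e-5, max_iter = 200) {
  m <- if (inherits(cm, "contact_matrix")) cm$counts else as.matrix(cm)
  n <- nrow(m)
  mask <- rowSums(m) == 0
  w <- rep(1, n)
  w[mask] <- NA
  live <- which(!mask)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    bw <- w[live]
    rs <- bw * (m[live, live, drop = FALSE] %*% bw)
    mu <- mean(rs)
    dev <- max(abs(rs / mu - 1))
    if (dev < tol) { converged <- TRUE; break }
    w[live] <- bw / sqrt(rs / mu)
  }
  # scale so unmasked weights average 1
  w[live] <- w[live] / mean(w[live])
  attr(w, "converged") <- converged
  if (inherits(cm, "contact_matrix")) {
    cm$weights <- w
    cm
  } else w
}

#' Exact downsampling of a contact matrix
#'
#' Thins the map to exactly `target_total` contacts by multivariate-
#' hypergeometric sampling of the upper-triangle pixel counts (contacts
#' drawn without replacement), then mirrors to keep symmetry. Per-pixel
#' expectation is `count * target_total / total`.
#'
#' @param cm A [contact_matrix()].
#' @param target_total Desired total contact count (upper triangle plus
#'   diagonal); must not exceed the current total.
#' @param seed Integer seed.
#' @return A downsampled [contact_matrix()] (weights dropped).
#' @export
downsample_contacts <- function(cm, target_total, seed = 1L) {
  set.seed(seed)
  m <- cm$counts
  ut <- which(upper.tri(m, diag = TRUE), arr.ind = TRUE)
  counts <- m[ut]
  total <- sum(counts)
  if (target_total > total) stop("target_total exceeds the matrix total")
  new <- numeric(length(counts))
  remaining <- target_total
  rest <- total
  nz <- which(counts > 0)
  for (k in nz) {
    rest <- rest - counts[k]
    x <- rhyper(1, counts[k], rest, remaining)
    new[k] <- x
    remaining <- remaining - x
    if (remaining == 0) break
  }
  out <- matrix(0, nrow(m), ncol(m))
  out[ut] <- new
  out[lower.tri(out)] <- t(out)[lower.tri(out)]
  contact_matrix(cm$bins, out)
}

#' Expected contacts under a distance-decay / trans-block model
#'
#' Cis pairs: per-chromosome mean count at each genomic (bin) distance
#' (diagonal average). Trans pairs: per chromosome-pair mean count.
#'
#' @param cm A [contact_matrix()].
#' @param balanced Use balanced values (requires weights) instead of raw
#'   counts.
#' @return Numeric matrix of expected values, same shape as the counts.
#' @export
expected_contacts <- function(cm, balanced = FALSE) {
  m <- if (balanced) balanced_counts(cm) else cm$counts
  n <- nrow(m)
  e <- matrix(0, n, n)
  chroms <- unique(cm$bins$chrom)
  for (chr in chroms) {
    idx <- which(cm$bins$chrom == chr)
    sub <- m[idx, idx, drop = FALSE]
    e[idx, idx] <- oe_expected(sub)
  }
  if (length(chroms) > 1) {
    for (i in seq_along(chroms)[-length(chroms)]) {
      for (j in (i + 1):length(chroms)) {
        a <- which(cm$bins$chrom == chroms[i])
        b <- which(cm$bins$chrom == chroms[j])
        mu <- mean(m[a, b], na.rm = TRUE)
        e[a, b] <- mu
        e[b, a] <- mu
      }
    }
  }
  e
}

# per-diagonal mean expected matrix for one chromosome
oe_expected <- function(m) {
  n <- nrow(m)
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  expd <- vapply(0:(n - 1), function(k) mean(m[d == k], na.rm = TRUE),
                 numeric(1))
  e <- expd[d + 1]
  dim(e) <- dim(m)
  e
}
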