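#' Insulation-score TAD boundaries
#'
#' Per bin, the insulation score is the mean (balanced) signal in the
#' `window x window` square straddling the bin, log2-normalized by the
#' chromosome mean score; boundaries are local minima whose prominence (the
#' smaller of the climbs to the flanking maxima between neighbouring minima)
#' is at least `delta_threshold`. The log-normalization makes the boundary
#' set invariant to rescaling the matrix.
#'
#' @param cm A [contact_matrix()]; balanced values are used when weights are
#'   stored.
#' @param window Window half-size in bins (>= 1).
#' @param delta_threshold Minimum prominence in log2 units.
#' @return Tibble `chrom`, `bin` (global bin index), `score` of boundary
#'   bins; chromosomes shorter than `2 * window + 1` yield none.
#' @export
insulation_boundaries <- function(cm, window = 10, delta_threshold = 0.1) {
  stopifnot(window >= 1)
  m <- if (is.null(cm$weights)) cm$counts else balanced_counts(cm)
  m[is.na(m)] <- 0
  out <- tibble::tibble(chrom = character(), bin = integer(),
                        score = numeric())
  for (chr in unique(cm$bins$chrom)) {
    idx <- which(cm$bins$chrom == chr)
    n <- length(idx)
    if (n < 2 * window + 1) next
    sub <- m[idx, idx, drop = FALSE]
    pos <- (window + 1):(n - window)
    ins <- vapply(pos, function(b)
      mean(sub[(b - window):(b - 1), (b + 1):(b + window)]), numeric(1))
    if (all(ins <= 0)) next
    ins <- log2(pmax(ins, 1e-12) / mean(ins))
    mins <- which(diff(sign(diff(c(Inf, ins, Inf)))) > 0)
    keep <- vapply(mins, function(k) {
      left <- if (k > 1) max(ins[1:(k - 1)]) else Inf
      right <- if (k < length(ins)) max(ins[(k + 1):length(ins)]) else Inf
      prev_min <- mins[mins < k]
      next_min <- mins[mins > k]
      if (length(prev_min)) left <- max(ins[max(prev_min):k])
      if (length(next_min)) right <- max(ins[k:min(next_min)])
      min(left, right) - ins[k] >= delta_threshold
    }, logical(1))
    mins <- mins[keep]
    if (length(mins))
      out <- dplyr::bind_rows(out, tibble::tibble(
        chrom = chr, bin = idx[pos[mins]], score = ins[mins]))
  }
  out
}

#' Consensus TAD boundaries across samples
#'
#' Boundaries are clustered across samples by single linkage within
#' `tol_bins`; a cluster is kept when it is supported by at least
#' `min_support` distinct samples, and its consensus position is the median
#' boundary bin. The consensus segmentation tiles each chromosome between
#' consecutive consensus boundaries.
#'
#' @param boundary_sets List of [insulation_boundaries()] tibbles (one per
#'   sample, same bin grid).
#' @param bins Bin table of the shared grid (`bin`, `chrom`, `start`, `end`).
#' @param min_support Minimum number of distinct supporting samples
#'   (default 5, intended for 9 samples).
#' @param tol_bins Single-linkage merge distance in bins.
#' @return List with `boundaries` (tibble `chrom`, `bin`, `support`) and
#'   `segments` (tibble `chrom`, `start`, `end` in bp tiling each
#'   chromosome).
#' @export
consensus_boundaries <- function(boundary_sets, bins, min_support = 5,
                                 tol_bins = 1) {
  bins <- tibble::as_tibble(bins)
  if (!("bin" %in% names(bins)))
    bins <- tibble::add_column(bins, bin = seq_len(nrow(bins)), .before = 1)
  all_b <- purrr::imap_dfr(boundary_sets, function(x, i)
    tibble::tibble(sample = i, chrom = x$chrom, bin = x$bin))
  cons <- tibble::tibble(chrom = character(), bin = integer(),
                         support = integer())
  if (nrow(all_b)) {
    for (chr in unique(all_b$chrom)) {
      d <- all_b[all_b$chrom == chr, ]
      d <- d[order(d$bin), ]
      grp <- cumsum(c(1, diff(d$bin) > tol_bins))
      agg <- dplyr::summarise(
        dplyr::group_by(d, grp = grp),
        bin = as.integer(floor(median(.data$bin))),
        support = dplyr::n_distinct(.data$sample), .groups = "drop")
      agg <- agg[agg$support >= min_support, ]
      if (nrow(agg))
        cons <- dplyr::bind_rows(cons, tibble::tibble(
          chrom = chr, bin = agg$bin, support = agg$support))
    }
  }
  segments <- purrr::map_dfr(unique(bins$chrom), function(chr) {
    cbins <- bins[bins$chrom == chr, ]
    b <- sort(cons$bin[cons$chrom == chr])
    # boundary bin starts a new segment
    cut_starts <- cbins$start[match(b, cbins$bin)]
    starts <- unique(c(min(cbins$start), cut_starts))
    ends <- c(starts[-1], max(cbins$end))
    tibble::tibble(chrom = chr, start = starts, end = ends)
  })
  list(boundaries = cons, segments = segments)
}
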