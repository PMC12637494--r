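#' Build a toy binned genome layout with planted per-bin activity
#'
#' Tiles each chromosome with fixed-size bins (0-based, half-open; a final
#' partial bin is allowed) and attaches a planted "openness" activity in
#' `[0, 1]` per bin (1 = most A-like). Activity is piecewise constant over
#' declared blocks and may differ between conditions through declared switch
#' blocks, which is how subcompartment switches are planted.
#'
#' @param chromosomes Named numeric vector of chromosome lengths in bp, or a
#'   data frame with columns `chrom` and `length`.
#' @param bin_size Bin width in bp.
#' @param blocks Optional data frame (`chrom`, `start`, `end`, `activity`)
#'   of non-overlapping baseline activity blocks; bins outside any block get
#'   `default_activity`.
#' @param switches Optional data frame (`chrom`, `start`, `end`, `condition`,
#'   `activity`) overriding activity in one condition only.
#' @param conditions Character vector of condition names; switch conditions
#'   must be among them.
#' @param default_activity Baseline activity for bins not covered by a block.
#' @return A `genome_layout` list: `chromosomes`, `bin_size`, `bins` (tibble
#'   with `bin`, `chrom`, `start`, `end`, `activity`), and
#'   `condition_activity`, a named list of per-bin activity vectors (one per
#'   condition).
#' @export
#' @examples
#' sim_genome(c(chrA = 2e6), bin_size = 1e5)$bins
sim_genome <- function(chromosomes,
                       bin_size,
                       blocks = NULL,
                       switches = NULL,
                       conditions = c("NC", "C15m", "C4h"),
                       default_activity = 0.5) {
  if (!is.data.frame(chromosomes)) {
    stopifnot(!is.null(names(chromosomes)))
    chromosomes <- tibble::tibble(chrom = names(chromosomes),
                                  length = as.numeric(chromosomes))
  }
  chromosomes <- tibble::as_tibble(chromosomes)
  stopifnot(all(c("chrom", "length") %in% names(chromosomes)),
            bin_size >= 1, all(chromosomes$length >= 1))

  bins <- purrr::pmap_dfr(chromosomes, function(chrom, length) {
    start <- seq(0, length - 1, by = bin_size)
    tibble::tibble(chrom = chrom, start = start,
                   end = pmin(start + bin_size, length))
  })
  bins <- tibble::add_column(bins, bin = seq_len(nrow(bins)), .before = 1)
  bins$activity <- rep(default_activity, nrow(bins))

  apply_blocks <- function(activity, blk) {
    # containment of the bin start decides membership; blocks may not overlap
    for (chr in unique(blk$chrom)) {
      b <- blk[blk$chrom == chr, , drop = FALSE]
      b <- b[order(b$start), , drop = FALSE]
      if (nrow(b) > 1 && any(b$start[-1] < b$end[-nrow(b)]))
        stop("overlapping block declarations on ", chr)
      for (k in seq_len(nrow(b))) {
        sel <- bins$chrom == chr & bins$start >= b$start[k] & bins$start < b$end[k]
        activity[sel] <- b$activity[k]
      }
    }
    activity
  }
  if (!is.null(blocks)) bins$activity <- apply_blocks(bins$activity, blocks)
  if (any(bins$activity < 0 | bins$activity > 1))
    stop("activity must lie in [0, 1]")

  condition_activity <- stats::setNames(
    rep(list(bins$activity), length(conditions)), conditions)
  if (!is.null(switches)) {
    switches <- tibble::as_tibble(switches)
    bad <- setdiff(unique(switches$condition), conditions)
    if (length(bad)) stop("unknown switch condition(s): ",
                          paste(bad, collapse = ", "))
    for (cond in unique(switches$condition)) {
      sw <- switches[switches$condition == cond, , drop = FALSE]
      condition_activity[[cond]] <- apply_blocks(condition_activity[[cond]], sw)
    }
  }

  structure(list(chromosomes = chromosomes, bin_size = bin_size,
                 bins = bins, condition_activity = condition_activity),
            class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("<genome_layout> ", nrow(x$chromosomes), " chromosome(s), ",
      nrow(x$bins), " bins of ", x$bin_size, " bp; conditions: ",
      paste(names(x$condition_activity), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Planted 8-state labels implied by a layout's activity
#'
#' Discretizes a condition's planted per-bin activity into the ordered
#' 8-state alphabet by equal-count octiles (highest activity = `A3`), giving
#' the ground-truth subcompartment track the Hi-C simulator encodes.
#'
#' @param layout A [sim_genome()] layout.
#' @param condition Condition name.
#' @return Tibble `bin`, `chrom`, `start`, `end`, `label`.
#' @export
layout_truth_labels <- function(layout, condition) {
  act <- layout$condition_activity[[condition]]
  if (is.null(act)) stop("unknown condition: ", condition)
  dplyr::mutate(layout$bins[, c("bin", "chrom", "start", "end")],
                label = octile_labels(act))
}

# equal-count octile labels, ties broken by position order (A3 = highest)
octile_labels <- function(score) {
  lab <- rep(NA_character_, length(score))
  ok <- which(!is.na(score))
  if (!length(ok)) return(lab)
  r <- rank(-score[ok], ties.method = "first")
  grp <- floor((r - 1) * 8 / length(ok)) + 1
  lab[ok] <- SUBCOMP_LEVELS[grp]
  lab
}

#' Place genes in bins coupled to planted activity strata
#'
#' Assigns each planted expression cluster's genes to transcription start
#' sites drawn uniformly inside bins whose baseline activity falls in the
#' cluster's declared stratum, emulating the coupling between temporal
#' expression classes and chromatin openness.
#'
#' @param layout A [sim_genome()] layout.
#' @param coupling Data frame (`cluster`, `n_genes`, `min_activity`,
#'   `max_activity`): each cluster's genes are placed in bins with baseline
#'   activity in `[min_activity, max_activity]`.
#' @param seed Integer seed.
#' @return A list with `genes`, a tibble (`gene_id`, `chrom`, `tss`,
#'   `strand`, `cluster`, `bin`), and `truth` (`gene_id`, `cluster`, `bin`).
#' @export
sim_genes <- function(layout, coupling, seed = 1L) {
  coupling <- tibble::as_tibble(coupling)
  stopifnot(all(c("cluster", "n_genes", "min_activity", "max_activity") %in%
                  names(coupling)))
  set.seed(seed)
  bins <- layout$bins
  out <- purrr::pmap_dfr(coupling, function(cluster, n_genes,
                                            min_activity, max_activity) {
    if (n_genes == 0) return(NULL)
    eligible <- which(bins$activity >= min_activity &
                        bins$activity <= max_activity)
    if (!length(eligible))
      stop("no bins with activity in [", min_activity, ", ", max_activity,
           "] for cluster ", cluster)
    b <- sample(eligible, n_genes, replace = TRUE)
    tibble::tibble(
      chrom = bins$chrom[b],
      tss = floor(bins$start[b] +
                    runif(n_genes) * (bins$end[b] - bins$start[b])),
      strand = sample(c("+", "-"), n_genes, replace = TRUE),
      cluster = as.integer(cluster),
      bin = bins$bin[b]
    )
  })
  if (is.null(out) || nrow(out) == 0L) {
    genes <- tibble::tibble(gene_id = character(), chrom = character(),
                            tss = numeric(), strand = character(),
                            cluster = integer(), bin = integer())
    return(list(genes = genes, truth = genes[, c("gene_id", "cluster", "bin")]))
  }
  out <- tibble::add_column(out, gene_id = sprintf("gene_%05d", seq_len(nrow(out))),
                            .before = 1)
  list(genes = out, truth = out[, c("gene_id", "cluster", "bin")])
}
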