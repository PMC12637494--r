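#' Mean balanced trans contact frequency per chromosome pair
#'
#' For every pair of distinct chromosomes, the mean of the balanced values
#' over all trans pixels (zeros included).
#'
#' @param cm A balanced [contact_matrix()].
#' @return Symmetric chromosome-by-chromosome matrix with `NA` diagonal.
#' @export
chromosome_contact_profile <- function(cm) {
  if (is.null(cm$weights)) stop("balancing weights are required")
  b <- balanced_counts(cm)
  chroms <- unique(cm$bins$chrom)
  out <- matrix(NA_real_, length(chroms), length(chroms),
                dimnames = list(chroms, chroms))
  for (i in seq_along(chroms)) {
    for (j in seq_along(chroms)) {
      if (i == j) next
      a <- which(cm$bins$chrom == chroms[i])
      d <- which(cm$bins$chrom == chroms[j])
      out[i, j] <- mean(b[a, d], na.rm = TRUE)
    }
  }
  out
}

#' Contact frequencies to dissimilarities
#'
#' Strictly decreasing transform of a frequency matrix into a dissimilarity
#' matrix with zero diagonal: `inverse` gives `1 / f`, `neglog` gives
#' `-log(f)` shifted so the smallest off-diagonal value is 0. Zeros are
#' replaced by half the smallest positive frequency first.
#'
#' @param profile Symmetric frequency matrix (e.g. from
#'   [chromosome_contact_profile()]).
#' @param mode `"inverse"` or `"neglog"`.
#' @return Symmetric dissimilarity matrix, zero diagonal.
#' @export
freq_to_dissimilarity <- function(profile, mode = c("inverse", "neglog")) {
  mode <- match.arg(mode)
  f <- as.matrix(profile)
  off <- f[row(f) != col(f)]
  if (all(is.na(off) | off == 0)) stop("profile has no positive frequencies")
  minpos <- min(off[off > 0], na.rm = TRUE)
  f[f == 0] <- minpos / 2
  d <- if (mode == "inverse") 1 / f else -log(f)
  if (mode == "neglog") d <- d - min(d[row(d) != col(d)], na.rm = TRUE)
  diag(d) <- 0
  d
}

#' Kruskal nonmetric multidimensional scaling
#'
#' Kruskal's algorithm: the configuration is initialized by classical
#' (Torgerson) scaling, then improved by alternating isotonic regression of
#' the configuration distances on the dissimilarity ranks with Guttman
#' transform updates. Iterations that fail to decrease the Kruskal stress-1
#' terminate the fit, so the accepted stress trace is non-increasing.
#'
#' @param d Symmetric non-negative dissimilarity matrix with zero diagonal.
#' @param k Embedding dimension.
#' @param max_iter Iteration cap.
#' @param tol Stop when the stress improvement falls below `tol`.
#' @return An `mds_fit`: list with `points` (n x k matrix, rownames kept),
#'   `stress` (Kruskal stress-1, in `[0, 1]`), `trace` (accepted stress per
#'   iteration) and `iterations`.
#' @export
nonmetric_mds <- function(d, k = 2, max_iter = 500, tol = 1e-6) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) stop("need at least 3 points")
  if (max(abs(d - t(d))) > 1e-8 || any(d < 0) || any(diag(d) != 0))
    stop("d must be symmetric, non-negative, with zero diagonal")
  lower <- which(lower.tri(d))
  delta <- d[lower]
  ord <- order(delta)

  x <- cmdscale(stats::as.dist(d), k = k)
  if (ncol(x) < k) x <- cbind(x, matrix(0, n, k - ncol(x)))

  config_dist <- function(x) as.matrix(dist(x))[lower]
  stress_of <- function(dv, dhat) sqrt(sum((dv - dhat)^2) / sum(dv^2))
  fit_dhat <- function(dv) {
    dhat <- numeric(length(dv))
    dhat[ord] <- isoreg(dv[ord])$yf
    dhat
  }

  dv <- config_dist(x)
  dhat <- fit_dhat(dv)
  stress <- stress_of(dv, dhat)
  trace <- stress
  iter <- 0
  for (it in seq_len(max_iter)) {
    # Guttman transform with the current monotone targets
    dh <- matrix(0, n, n)
    dh[lower] <- dhat
    dh <- dh + t(dh)
    dm <- matrix(0, n, n)
    dm[lower] <- dv
    dm <- dm + t(dm)
    ratio <- ifelse(dm > 0, dh / dm, 0)
    bmat <- -ratio
    diag(bmat) <- rowSums(ratio)
    x_new <- bmat %*% x / n
    dv_new <- config_dist(x_new)
    dhat_new <- fit_dhat(dv_new)
    s_new <- stress_of(dv_new, dhat_new)
    if (!is.finite(s_new) || s_new > stress - tol) break
    x <- x_new; dv <- dv_new; dhat <- dhat_new; stress <- s_new
    trace <- c(trace, stress)
    iter <- it
  }
  rownames(x) <- rownames(d)
  structure(list(points = x, stress = stress, trace = trace,
                 iterations = iter),
            class = "mds_fit")
}

#' @export
print.mds_fit <- function(x, ...) {
  cat("<mds_fit> ", nrow(x$points), " points in ", ncol(x$points),
      "D; stress ", signif(x$stress, 4), " after ", x$iterations,
      " iteration(s)\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mds_fit <- function(x, ...) {
  tibble::tibble(item = rownames(x$points) %||% as.character(seq_len(nrow(x$points))),
                 dim1 = x$points[, 1],
                 dim2 = if (ncol(x$points) >= 2) x$points[, 2] else NA_real_)
}

#' @exportS3Method generics::glance
glance.mds_fit <- function(x, ...) {
  tibble::tibble(stress = x$stress, iterations = x$iterations,
                 n = nrow(x$points), k = ncol(x$points))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Procrustes alignment of two configurations
#'
#' Optimal translation, rotation/reflection and scaling of `x` onto `x_ref`
#' (symmetric Procrustes); the disparity is the symmetric Procrustes
#' statistic, normalized to `[0, 1]`.
#'
#' @param x_ref,x Matrices with matching row counts.
#' @return List with `aligned` (transformed `x`), `reference` (`x_ref` in
#'   the same centered, unit-scale coordinates, for per-point residuals)
#'   and `disparity`.
#' @export
procrustes_align <- function(x_ref, x) {
  x_ref <- as.matrix(x_ref); x <- as.matrix(x)
  if (nrow(x_ref) != nrow(x)) stop("configurations must match in size")
  if (sum(apply(x_ref, 2, sd)) == 0 || sum(apply(x, 2, sd)) == 0)
    stop("degenerate zero-variance configuration")
  fit <- vegan::procrustes(x_ref, x, symmetric = TRUE)
  ref <- fit$X
  rownames(ref) <- rownames(x_ref)
  rownames(fit$Yrot) <- rownames(x)
  list(aligned = fit$Yrot, reference = ref, disparity = fit$ss)
}

#' Homotypic / heterotypic annotation of interaction anchors
#'
#' Collapses the 8-state track to A/B (`A*` to `A`, `B*` to `B`), assigns
#' each anchor the A/B label with the greatest base-pair overlap, and calls
#' a pair homotypic when both anchors agree (`NA` if either anchor is
#' unlabelled).
#'
#' @param pairs Tibble with anchor columns `chrom1`, `start1`, `end1`,
#'   `chrom2`, `start2`, `end2` (0-based half-open).
#' @param track Subcompartment track tibble.
#' @return `pairs` with added `ab1`, `ab2`, `homotypic` columns.
#' @export
homotypic_annotation <- function(pairs, track) {
  pairs <- tibble::as_tibble(pairs)
  ab <- track[!is.na(track$label), , drop = FALSE]
  ab$label <- substr(ab$label, 1, 1)
  anchor_label <- function(chrom, start, end) {
    gr <- GenomicRanges::GRanges(chrom,
                                 IRanges::IRanges(start = start + 1, end = end))
    tg <- GenomicRanges::GRanges(ab$chrom,
                                 IRanges::IRanges(start = ab$start + 1, end = ab$end))
    hits <- GenomicRanges::findOverlaps(gr, tg)
    if (!length(hits)) return(rep(NA_character_, length(gr)))
    w <- GenomicRanges::width(GenomicRanges::pintersect(
      gr[S4Vectors::queryHits(hits)], tg[S4Vectors::subjectHits(hits)]))
    sc <- tibble::tibble(i = S4Vectors::queryHits(hits),
                         label = ab$label[S4Vectors::subjectHits(hits)], w = w)
    sc <- dplyr::summarise(dplyr::group_by(sc, .data$i, .data$label),
                           w = sum(.data$w), .groups = "drop")
    sc <- dplyr::arrange(sc, .data$i, dplyr::desc(.data$w), .data$label)
    sc <- dplyr::slice_head(dplyr::group_by(sc, .data$i), n = 1)
    out <- rep(NA_character_, length(gr))
    out[sc$i] <- sc$label
    out
  }
  pairs$ab1 <- anchor_label(pairs$chrom1, pairs$start1, pairs$end1)
  pairs$ab2 <- anchor_label(pairs$chrom2, pairs$start2, pairs$end2)
  pairs$homotypic <- ifelse(is.na(pairs$ab1) | is.na(pairs$ab2), NA,
                            pairs$ab1 == pairs$ab2)
  pairs
}

#' Subtelomeric annotation of interaction anchors
#'
#' A pair is subtelomeric when both anchors lie entirely within `window` of
#' either end of their chromosome; `window < 1` is read as a fraction of the
#' chromosome length, otherwise as absolute bp (default 5 Mb).
#'
#' @inheritParams homotypic_annotation
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param window Absolute bp, or a fraction in (0, 1).
#' @return `pairs` with added `subtelomeric1`, `subtelomeric2`,
#'   `subtelomeric` columns.
#' @export
subtelomere_annotation <- function(pairs, chrom_lengths, window = 5e6) {
  pairs <- tibble::as_tibble(pairs)
  near_end <- function(chrom, start, end) {
    L <- unname(chrom_lengths[chrom])
    w <- if (window < 1) window * L else rep(window, length(L))
    end <= w | start >= L - w
  }
  pairs$subtelomeric1 <- near_end(pairs$chrom1, pairs$start1, pairs$end1)
  pairs$subtelomeric2 <- near_end(pairs$chrom2, pairs$start2, pairs$end2)
  pairs$subtelomeric <- pairs$subtelomeric1 & pairs$subtelomeric2
  pairs
}

#' Proportion of each TEC's genes inside a region set
#'
#' @param genes Tibble `gene_id`, `chrom`, `tss`.
#' @param tecs A `tec_assignment` (or tibble `gene_id`, `tec`).
#' @param regions Tibble `chrom`, `start`, `end` (0-based half-open).
#' @return Tibble `tec`, `n_genes`, `n_inside`, `proportion` (in percent
#'   `fraction * 100`; `NA` for empty TECs).
#' @export
tec_overlap_with_regions <- function(genes, tecs, regions) {
  genes <- dplyr::inner_join(tibble::as_tibble(genes),
                             tibble::as_tibble(tecs)[, c("gene_id", "tec")],
                             by = "gene_id")
  inside <- rep(FALSE, nrow(genes))
  if (nrow(regions)) {
    g <- GenomicRanges::GRanges(genes$chrom,
                                IRanges::IRanges(start = genes$tss + 1, width = 1))
    r <- GenomicRanges::GRanges(regions$chrom,
                                IRanges::IRanges(start = regions$start + 1,
                                                 end = regions$end))
    inside <- GenomicRanges::countOverlaps(g, r) > 0
  }
  genes$inside <- inside
  out <- dplyr::summarise(dplyr::group_by(genes, .data$tec),
                          n_genes = dplyr::n(),
                          n_inside = sum(.data$inside), .groups = "drop")
  out$proportion <- ifelse(out$n_genes > 0,
                           100 * out$n_inside / out$n_genes, NA_real_)
  out
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided exact p-value conditional on the margins (point-probability
#' convention) and the sample odds ratio `(a d) / (b c)` (`Inf`/`NaN`
#' flagged via `or_defined`); the conditional-MLE odds ratio is also
#' reported. A zero margin gives `p = 1` with an undefined odds ratio.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return Tibble `odds_ratio` (sample), `odds_ratio_mle`, `p`,
#'   `or_defined`.
#' @export
fisher_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2), all(tab >= 0))
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(tibble::tibble(odds_ratio = NA_real_, odds_ratio_mle = NA_real_,
                          p = 1, or_defined = FALSE))
  }
  ft <- fisher.test(tab)
  or <- (a * d) / (b * c)
  tibble::tibble(odds_ratio = or,
                 odds_ratio_mle = unname(ft$estimate),
                 p = ft$p.value,
                 or_defined = is.finite(or))
}

#' Subcompartment switching versus direction of temporal regulation
#'
#' Cross-tabulates subcompartment opening/closing at gene TSSs against
#' membership in upregulated versus downregulated TECs (stable genes and
#' other TECs excluded) and applies Fisher's exact test. With the default
#' direction map, TECs 2, 5, 6 and 7 count as upregulated at 4 hours and
#' TECs 1, 3 and 4 as downregulated.
#'
#' @param gene_switches Tibble `gene_id`, `direction` (from
#'   [classify_switch()] on TSS labels).
#' @param tecs A `tec_assignment` (or tibble `gene_id`, `tec`).
#' @param up_tecs,down_tecs Integer TEC ids counted as up-/downregulated.
#' @return List with `table` (2x2: opening/closing x up/down) and `test`
#'   (the [fisher_2x2()] tibble).
#' @export
switching_vs_regulation <- function(gene_switches, tecs,
                                    up_tecs = c(2, 5, 6, 7),
                                    down_tecs = c(1, 3, 4)) {
  d <- dplyr::inner_join(tibble::as_tibble(gene_switches),
                         tibble::as_tibble(tecs)[, c("gene_id", "tec")],
                         by = "gene_id")
  d <- d[!is.na(d$direction) & d$direction %in% c("opening", "closing") &
           d$tec %in% c(up_tecs, down_tecs), ]
  reg <- ifelse(d$tec %in% up_tecs, "up", "down")
  tab <- table(factor(d$direction, levels = c("opening", "closing")),
               factor(reg, levels = c("up", "down")))
  list(table = unclass(tab), test = fisher_2x2(tab))
}

#' Gene-set membership versus subcompartment switching
#'
#' 2x2 Fisher test of in-set membership against switching (any direction
#' other than `stable`) at gene TSSs.
#'
#' @param gene_switches Tibble `gene_id`, `direction` (`NA` directions are
#'   dropped).
#' @param gene_set Character vector of gene ids.
#' @return List with `table` (in-set x switched) and `test`.
#' @export
geneset_switching_test <- function(gene_switches, gene_set) {
  if (length(gene_set) == 0L) stop("gene_set must be non-empty")
  d <- tibble::as_tibble(gene_switches)
  d <- d[!is.na(d$direction), ]
  in_set <- d$gene_id %in% gene_set
  switched <- d$direction != "stable"
  tab <- table(factor(in_set, levels = c(TRUE, FALSE)),
               factor(switched, levels = c(TRUE, FALSE)))
  dimnames(tab) <- list(set = c("in_set", "out"),
                        switch = c("switched", "stable"))
  list(table = unclass(tab), test = fisher_2x2(tab))
}

#' Overlap of a label track with feature interval sets
#'
#' For every label and feature set: total Mbp of interval intersection
#' (features merged first), plus per-row z-scores across features and the
#' log2-transformed overlap lengths.
#'
#' @param track Subcompartment (or any label) track tibble.
#' @param feature_sets Named list of interval tibbles (`chrom`, `start`,
#'   `end`).
#' @return List of labels x features matrices: `mbp`, `z` (row-scaled),
#'   `log2_mbp`.
#' @export
track_overlap_matrix <- function(track, feature_sets) {
  track <- track[!is.na(track$label), , drop = FALSE]
  labels <- sort(unique(track$label))
  lev <- intersect(SUBCOMP_LEVELS, labels)
  if (length(lev)) labels <- c(lev, setdiff(labels, lev))
  m <- matrix(0, length(labels), length(feature_sets),
              dimnames = list(labels, names(feature_sets)))
  for (lab in labels) {
    t <- track[track$label == lab, ]
    tg <- GenomicRanges::reduce(GenomicRanges::GRanges(
      t$chrom, IRanges::IRanges(start = t$start + 1, end = t$end)))
    for (fs in names(feature_sets)) {
      f <- feature_sets[[fs]]
      fg <- GenomicRanges::reduce(GenomicRanges::GRanges(
        f$chrom, IRanges::IRanges(start = f$start + 1, end = f$end)))
      ov <- GenomicRanges::intersect(tg, fg)
      m[lab, fs] <- sum(GenomicRanges::width(ov)) / 1e6
    }
  }
  rs <- apply(m, 1, sd)
  rs[is.na(rs) | rs == 0] <- Inf   # constant rows score 0
  z <- (m - rowMeans(m)) / rs
  list(mbp = m, z = z, log2_mbp = log2(m))
}
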