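#' Aggregate contact maps into coarse bin-pair count tables
#'
#' Sums fine-bin counts (upper triangle including the diagonal) into coarse
#' genomic bins (default 5 Mb) per sample, producing the count table for
#' differential contact testing. Column sums equal the source matrices'
#' upper-triangle totals.
#'
#' @param matrices Named list of [contact_matrix()] objects on a shared fine
#'   grid (names become sample names).
#' @param coarse_bin Coarse bin width in bp.
#' @return Tibble with `chrom1`, `cstart1`, `chrom2`, `cstart2` and one
#'   count column per sample; only pairs with a nonzero total are kept.
#' @export
bin_pair_counts <- function(matrices, coarse_bin = 5e6) {
  stopifnot(length(matrices) >= 1)
  if (is.null(names(matrices)))
    names(matrices) <- paste0("sample_", seq_along(matrices))
  bins <- matrices[[1]]$bins
  cb_chrom <- bins$chrom
  cb_start <- floor(bins$start / coarse_bin) * coarse_bin
  key_of <- function(i) paste0(cb_chrom[i], ":", cb_start[i])

  ut <- which(upper.tri(matrices[[1]]$counts, diag = TRUE), arr.ind = TRUE)
  # canonical coarse pair id per fine pixel
  k1 <- key_of(ut[, 1]); k2 <- key_of(ut[, 2])
  swap <- k1 > k2
  pair_key <- paste(ifelse(swap, k2, k1), ifelse(swap, k1, k2), sep = "|")
  counts <- vapply(matrices, function(cm) {
    stopifnot(nrow(cm$bins) == nrow(bins))
    as.numeric(tapply(cm$counts[ut], pair_key, sum))
  }, numeric(length(unique(pair_key))))
  if (!is.matrix(counts))
    counts <- matrix(counts, ncol = length(matrices),
                     dimnames = list(NULL, names(matrices)))
  keys <- sort(unique(pair_key))
  parts <- do.call(rbind, strsplit(keys, "[|:]"))
  out <- tibble::tibble(chrom1 = parts[, 1],
                        cstart1 = as.numeric(parts[, 2]),
                        chrom2 = parts[, 3],
                        cstart2 = as.numeric(parts[, 4]))
  out <- dplyr::bind_cols(out, tibble::as_tibble(counts))
  out[rowSums(counts) > 0, ]
}

#' Simplified negative-binomial differential contact test
#'
#' Tests each coarse bin pair for a contact-frequency difference between two
#' conditions with a negative-binomial Wald test: size factors by
#' median-of-ratios (geometric-mean reference over pairs with all-nonzero
#' counts), per-pair method-of-moments dispersion shrunk toward the
#' genome-wide mean dispersion with a precision weight (the per-pair
#' moment estimate carries few degrees of freedom at replicate-level sample
#' sizes, so it gets weight `shrink_weight`, default 0.2, against the
#' genome-wide target), a Wald statistic on the log2 fold change of
#' normalized condition means with model-based standard errors, and
#' Benjamini-Hochberg adjustment. Pairs with `padj < 0.05` are conventionally
#' called significant; `direction` is `gained`/`lost` by the sign of the
#' fold change (condition B versus A).
#'
#' @param count_table Output of [bin_pair_counts()] (or any tibble whose
#'   sample columns are named in `condition_labels`).
#' @param condition_labels Named character vector mapping sample column
#'   names to condition labels; exactly two conditions, each with at least
#'   two samples. The first condition (by order of levels or first
#'   appearance) is the reference A.
#' @param shrink_weight Weight of the per-pair moment dispersion estimate
#'   against the genome-wide mean dispersion.
#' @return Tibble with the pair columns plus `base_mean`, `log2fc`, `se`,
#'   `stat`, `p`, `padj`, `direction`.
#' @export
nb_differential <- function(count_table, condition_labels,
                            shrink_weight = 0.2) {
  samples <- names(condition_labels)
  stopifnot(all(samples %in% names(count_table)))
  cond <- factor(condition_labels)
  if (nlevels(cond) != 2) stop("exactly two conditions are required")
  if (any(table(cond) < 2)) stop("each condition needs at least 2 samples")
  counts <- as.matrix(count_table[, samples])
  storage.mode(counts) <- "double"

  # median-of-ratios size factors
  pos <- rowSums(counts == 0) == 0
  if (!any(pos)) stop("no pair has all-nonzero counts; cannot size-factor")
  logg <- rowMeans(log(counts[pos, , drop = FALSE]))
  sf <- apply(counts[pos, , drop = FALSE], 2, function(col)
    exp(median(log(col) - logg)))
  norm <- sweep(counts, 2, sf, "/")

  a_lab <- levels(cond)[1]
  ia <- which(cond == a_lab); ib <- which(cond != a_lab)
  mA <- rowMeans(norm[, ia, drop = FALSE])
  mB <- rowMeans(norm[, ib, drop = FALSE])
  nA <- length(ia); nB <- length(ib)

  # method-of-moments dispersion on normalized counts, pooled over conditions
  vA <- apply(norm[, ia, drop = FALSE], 1, var)
  vB <- apply(norm[, ib, drop = FALSE], 1, var)
  mu_pool <- (mA * nA + mB * nB) / (nA + nB)
  v_pool <- (vA * (nA - 1) + vB * (nB - 1)) / (nA + nB - 2)
  mom <- (v_pool - mu_pool) / mu_pool^2
  mom[!is.finite(mom)] <- 0
  # untruncated mean is the (nearly) unbiased genome-wide target; the
  # per-pair estimate is truncated at 0 before blending
  target <- max(mean(mom, na.rm = TRUE), 0)
  disp <- pmax(shrink_weight * pmax(mom, 0) +
                 (1 - shrink_weight) * target, 0)

  pc <- 0.5  # pseudocount guard for empty means
  log2fc <- log2((mB + ifelse(mB == 0, pc, 0)) /
                   (mA + ifelse(mA == 0, pc, 0)))
  # delta-method SE of the log2 ratio with NB variance of each mean
  varA <- (mA + disp * mA^2) / nA
  varB <- (mB + disp * mB^2) / nB
  se <- sqrt(varA / pmax(mA, pc)^2 + varB / pmax(mB, pc)^2) / log(2)
  stat <- log2fc / se
  p <- 2 * pnorm(-abs(stat))
  p[mA == 0 & mB == 0] <- 1
  padj <- p.adjust(p, method = "BH")

  pair_cols <- setdiff(names(count_table), samples)
  out <- tibble::as_tibble(count_table[, pair_cols])
  dplyr::bind_cols(out, tibble::tibble(
    base_mean = mu_pool, log2fc = log2fc, se = se, stat = stat,
    p = p, padj = padj,
    direction = ifelse(log2fc >= 0, "gained", "lost")))
}
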