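#' Continuous chromatin openness score from a contact matrix
#'
#' Simplified eight-state subcompartment ranker: per chromosome, the
#' observed/expected matrix (expected = per-diagonal mean within the
#' chromosome) is turned into a Pearson correlation matrix whose leading
#' eigenvector is the openness score, sign-oriented so its correlation with
#' the supplied activity covariate is positive, and scaled to unit standard
#' deviation per chromosome so scores are comparable genome-wide. Bins with
#' zero coverage get `NA`; degenerate (constant or all-zero) chromosomes get
#' all-`NA` scores with a warning.
#'
#' @param cm A [contact_matrix()] (balanced values are used when weights are
#'   stored, otherwise raw counts).
#' @param activity Per-bin orientation covariate (planted activity in
#'   simulations; gene density in real use).
#' @param chromosomes Optional subset of chromosomes to score.
#' @return Numeric per-bin score vector aligned with `cm$bins` (`NA`
#'   outside scored chromosomes or for unusable bins).
#' @export
subcompartment_rank <- function(cm, activity,
                                chromosomes = unique(cm$bins$chrom)) {
  stopifnot(length(activity) == nrow(cm$bins))
  m <- if (is.null(cm$weights)) cm$counts else balanced_counts(cm)
  score <- rep(NA_real_, nrow(cm$bins))
  for (chr in chromosomes) {
    idx <- which(cm$bins$chrom == chr)
    if (length(idx) < 16) {
      warning("chromosome ", chr, " has fewer than 16 bins; skipped")
      next
    }
    sub <- m[idx, idx, drop = FALSE]
    sub[is.na(sub)] <- 0
    usable <- rowSums(sub) > 0
    if (!any(usable)) {
      warning("all-zero matrix on ", chr, "; scores set to NA")
      next
    }
    oe <- oe_matrix(sub[usable, usable, drop = FALSE])
    sds <- apply(oe, 2, sd)
    if (all(sds == 0) || sum(sds > 0) < 2) {
      warning("degenerate (constant) matrix on ", chr, "; scores set to NA")
      next
    }
    ok <- sds > 0
    cc <- suppressWarnings(cor(oe[ok, ok, drop = FALSE]))
    cc[is.na(cc)] <- 0
    ev <- eigen(cc, symmetric = TRUE)$vectors[, 1]
    v <- rep(NA_real_, sum(usable))
    v[ok] <- ev
    a <- activity[idx][usable]
    orient <- suppressWarnings(cor(v, a, use = "complete.obs"))
    if (!is.na(orient) && orient < 0) v <- -v
    if (sd(v, na.rm = TRUE) > 0) v <- v / sd(v, na.rm = TRUE)
    score[idx[usable]] <- v
  }
  score
}

# observed / expected with expected = per-diagonal mean
oe_matrix <- function(m) {
  n <- nrow(m)
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  expd <- vapply(0:(n - 1), function(k) mean(m[d == k]), numeric(1))
  e <- expd[d + 1]
  dim(e) <- dim(m)
  oe <- m / e
  oe[e == 0] <- 0
  oe
}

#' Discretize openness scores into the 8-state alphabet
#'
#' Non-`NA` bins are split into eight equal-count quantile groups
#' (genome-wide by default, per chromosome on request): the highest octile
#' is `A3`, the lowest `B3`. Ties are broken by bin order; `NA` scores stay
#' `NA`.
#'
#' @param cm A [contact_matrix()] providing the bin table.
#' @param score Per-bin openness score (e.g. from [subcompartment_rank()]).
#' @param per_chromosome Rank within each chromosome instead of genome-wide.
#' @return A subcompartment track tibble: `bin`, `chrom`, `start`, `end`,
#'   `label`.
#' @export
rank_to_labels <- function(cm, score, per_chromosome = FALSE) {
  stopifnot(length(score) == nrow(cm$bins))
  if (sum(!is.na(score)) < 8)
    stop("need at least 8 scored bins for octile labels")
  bins <- cm$bins[, c("bin", "chrom", "start", "end")]
  if (per_chromosome) {
    lab <- rep(NA_character_, length(score))
    for (chr in unique(bins$chrom)) {
      i <- bins$chrom == chr
      lab[i] <- octile_labels(score[i])
    }
  } else {
    lab <- octile_labels(score)
  }
  dplyr::mutate(bins, label = lab)
}

#' Consensus subcompartment labels across replicates
#'
#' A bin keeps a label only when at least `min_agree` replicates carry
#' exactly that label; otherwise it is `NA`.
#'
#' @param tracks List of subcompartment track tibbles over identical bins.
#' @param min_agree Minimum agreeing replicates (default 2 of 3).
#' @return Consensus track tibble (`bin`, `chrom`, `start`, `end`, `label`).
#' @export
consensus_labels <- function(tracks, min_agree = 2) {
  stopifnot(length(tracks) >= 1)
  ref <- tracks[[1]][, c("bin", "chrom", "start", "end")]
  for (t in tracks[-1]) {
    if (!identical(as.data.frame(t[, c("chrom", "start", "end")]),
                   as.data.frame(ref[, c("chrom", "start", "end")])))
      stop("replicate tracks must share an identical bin table")
  }
  labs <- do.call(cbind, lapply(tracks, function(t) as.character(t$label)))
  consensus <- apply(labs, 1, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_character_)
    tab <- sort(table(v), decreasing = TRUE)
    if (tab[1] >= min_agree) names(tab)[1] else NA_character_
  })
  dplyr::mutate(ref, label = consensus)
}

#' Map transcription start sites to subcompartment labels
#'
#' Each gene receives the label of the bin containing its TSS (0-based,
#' half-open containment). TSSs outside the grid, or on chromosomes absent
#' from the track, give `NA` (with a warning for unknown chromosomes).
#'
#' @param genes Tibble with `gene_id`, `chrom`, `tss`.
#' @param track Subcompartment track tibble.
#' @return `genes` with an added `label` column.
#' @export
map_tss_to_label <- function(genes, track) {
  genes <- tibble::as_tibble(genes)
  unknown <- setdiff(unique(genes$chrom), unique(track$chrom))
  if (length(unknown))
    warning("chromosome(s) not in track: ", paste(unknown, collapse = ", "))
  tss_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(start = genes$tss + 1, width = 1))
  track_gr <- GenomicRanges::GRanges(
    track$chrom, IRanges::IRanges(start = track$start + 1, end = track$end))
  hit <- GenomicRanges::findOverlaps(tss_gr, track_gr, select = "first")
  genes$label <- track$label[hit]
  genes
}

#' Classify a subcompartment switch
#'
#' Vectorized classification of label changes on the ordered 8-state axis:
#' a change toward a more A-like (lower-rank) state is *opening*, toward a
#' more B-like state *closing*; entering the facultative band (`A1`, `A0`,
#' `B0`, `B1`) from outside is a facultative *gain*, leaving it a *loss*.
#' `NA` in either label yields `NA` calls.
#'
#' @param label_from,label_to Character vectors of 8-state labels.
#' @return Tibble `label_from`, `label_to`, `direction` (`stable`,
#'   `opening`, `closing`), `facultative` (`none`, `gain`, `loss`).
#' @export
classify_switch <- function(label_from, label_to) {
  rf <- subcomp_rank(label_from)
  rt <- subcomp_rank(label_to)
  bad <- (!is.na(label_from) & is.na(rf)) | (!is.na(label_to) & is.na(rt))
  if (any(bad)) stop("labels must come from the 8-state alphabet")
  direction <- dplyr::case_when(
    is.na(rf) | is.na(rt) ~ NA_character_,
    rt == rf ~ "stable",
    rt < rf ~ "opening",
    TRUE ~ "closing")
  in_fac_from <- label_from %in% FACULTATIVE_LEVELS
  in_fac_to <- label_to %in% FACULTATIVE_LEVELS
  facultative <- dplyr::case_when(
    is.na(rf) | is.na(rt) ~ NA_character_,
    in_fac_to & !in_fac_from ~ "gain",
    in_fac_from & !in_fac_to ~ "loss",
    TRUE ~ "none")
  tibble::tibble(label_from = label_from, label_to = label_to,
                 direction = direction, facultative = facultative)
}

#' Subcompartment switch matrix in Mbp
#'
#' 8x8 matrix whose cell (x, y) is the total megabase-pairs labelled x in
#' condition A and y in condition B; bins with `NA` in either track are
#' excluded, so the diagonal holds the stable Mbp.
#'
#' @param track_a,track_b Subcompartment tracks over identical bins.
#' @return 8x8 numeric matrix (rows = condition A labels, columns =
#'   condition B labels, in rank order `A3`..`B3`), in Mbp.
#' @export
switch_matrix <- function(track_a, track_b) {
  if (!identical(as.data.frame(track_a[, c("chrom", "start", "end")]),
                 as.data.frame(track_b[, c("chrom", "start", "end")])))
    stop("tracks must share an identical bin table")
  keep <- !is.na(track_a$label) & !is.na(track_b$label)
  mbp <- (track_a$end - track_a$start)[keep] / 1e6
  fa <- factor(track_a$label[keep], levels = SUBCOMP_LEVELS)
  fb <- factor(track_b$label[keep], levels = SUBCOMP_LEVELS)
  m <- tapply(mbp, list(fa, fb), sum, default = 0)
  m <- unclass(m)
  m[is.na(m)] <- 0
  m
}
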