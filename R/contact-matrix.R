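#' Construct a binned contact matrix
#'
#' Lightweight container for a symmetric binned Hi-C contact map: a bin
#' table (0-based, half-open intervals), a dense symmetric count matrix and
#' optional per-bin balancing weights.
#'
#' @param bins Data frame with `chrom`, `start`, `end` (and optionally
#'   `bin`); rows index the matrix.
#' @param counts Symmetric non-negative numeric matrix, one row/column per
#'   bin.
#' @param weights Optional per-bin positive balancing weights (`NA` for
#'   masked bins).
#' @return A `contact_matrix` object.
#' @export
contact_matrix <- function(bins, counts, weights = NULL) {
  bins <- tibble::as_tibble(bins)
  stopifnot(all(c("chrom", "start", "end") %in% names(bins)))
  if (!("bin" %in% names(bins)))
    bins <- tibble::add_column(bins, bin = seq_len(nrow(bins)), .before = 1)
  counts <- as.matrix(counts)
  if (nrow(counts) != nrow(bins) || ncol(counts) != nrow(bins))
    stop("counts dimensions must match the bin table")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (max(abs(counts - t(counts))) > 1e-8) stop("counts must be symmetric")
  if (!is.null(weights)) {
    stopifnot(length(weights) == nrow(bins))
    if (any(!is.na(weights) & weights <= 0)) stop("weights must be positive or NA")
  }
  structure(list(bins = bins, counts = counts, weights = weights),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("<contact_matrix> ", nrow(x$bins), " bins on ",
      length(unique(x$bins$chrom)), " chromosome(s); total count ",
      format(sum(x$counts[upper.tri(x$counts, diag = TRUE)])),
      if (is.null(x$weights)) "; unbalanced" else "; balanced", "\n", sep = "")
  invisible(x)
}

#' Balanced matrix values
#'
#' Applies stored per-bin weights: `b[i, j] = w[i] * w[j] * counts[i, j]`.
#' Masked bins (`NA` weight) give `NA` rows/columns.
#'
#' @param cm A [contact_matrix()] with weights (raw counts returned, with a
#'   warning, if weights are absent).
#' @return Numeric matrix of balanced values.
#' @export
balanced_counts <- function(cm) {
  if (is.null(cm$weights)) {
    warning("no balancing weights stored; returning raw counts")
    return(cm$counts)
  }
  tcrossprod(cm$weights) * cm$counts
}

# logical matrix: TRUE for intrachromosomal pairs
cis_mask <- function(cm) outer(cm$bins$chrom, cm$bins$chrom, "==")

#' Write / read a contact matrix as plain text
#'
#' Coordinate-list TSV (`bin1`, `bin2`, `count`; upper triangle including
#' the diagonal, 1-based bin ids) alongside a BED-like bin table.
#'
#' @param cm A [contact_matrix()].
#' @param pixels_file,bins_file Paths for the pixel list and bin table.
#' @return `write_contacts()` returns `cm` invisibly; `read_contacts()`
#'   returns a [contact_matrix()].
#' @export
write_contacts <- function(cm, pixels_file, bins_file) {
  ut <- which(upper.tri(cm$counts, diag = TRUE) & cm$counts > 0, arr.ind = TRUE)
  px <- data.frame(bin1 = ut[, 1], bin2 = ut[, 2],
                   count = cm$counts[ut])
  px <- px[order(px$bin1, px$bin2), ]
  utils::write.table(px, pixels_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(as.data.frame(cm$bins[, c("chrom", "start", "end")]),
                     bins_file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(cm)
}

#' @rdname write_contacts
#' @export
read_contacts <- function(pixels_file, bins_file) {
  bins <- utils::read.table(bins_file, sep = "\t",
                            col.names = c("chrom", "start", "end"))
  px <- utils::read.table(pixels_file, sep = "\t", header = TRUE)
  n <- nrow(bins)
  m <- matrix(0, n, n)
  m[cbind(px$bin1, px$bin2)] <- px$count
  m[cbind(px$bin2, px$bin1)] <- px$count
  contact_matrix(bins, m)
}
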