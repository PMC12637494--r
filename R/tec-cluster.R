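#' Ward-D2 linkage of temporal log fold-change profiles
#'
#' Agglomerative hierarchical clustering of the gene-by-timepoint log2
#' fold-change vectors under the Ward-D2 criterion on Euclidean distances.
#'
#' @param lfc Data frame with a `gene_id` column and the four numeric
#'   timepoint columns (`C15m`, `C1h`, `C4h`, `C24h`).
#' @return An [stats::hclust] tree with gene ids as labels.
#' @export
ward_linkage <- function(lfc) {
  x <- lfc_values(lfc)
  if (nrow(x) < 2) stop("need at least 2 genes")
  if (any(!is.finite(x))) stop("log fold changes must be finite")
  hclust(dist(x), method = "ward.D2")
}

# extract the numeric matrix (genes x 4) with gene ids as rownames
lfc_values <- function(lfc) {
  lfc <- tibble::as_tibble(lfc)
  stopifnot("gene_id" %in% names(lfc))
  tp <- c("C15m", "C1h", "C4h", "C24h")
  if (!all(tp %in% names(lfc)))
    tp <- names(lfc)[vapply(lfc, is.numeric, logical(1))]
  x <- as.matrix(lfc[, tp])
  rownames(x) <- lfc$gene_id
  x
}

#' Adaptive branch pruning of a dendrogram
#'
#' Cuts a merge tree into clusters by recursive adaptive pruning rather than
#' a single static height, working on the merge structure alone. The branch
#' statistic is the *trimmed height*: the height of the sub-branch still
#' holding at least 90 percent of a branch's leaves, which makes it robust
#' to outliers chained loosely above a cluster's core. A node is a
#' *significant split* when both child branches hold at least
#' `min_cluster_size` leaves and the mean of the children's trimmed heights
#' is at most `grid[deep_split + 1]` times the node's height -- a
#' pronounced height gap. The grid `c(0.52, 0.56, 0.60, 0.64, 0.68)` is
#' calibrated for this ratio statistic: under Ward linkage the trimmed
#' ratio of a balanced split of homogeneous data concentrates near
#' `sqrt(1/2) ~ 0.71`, so the most conservative setting (`deep_split = 0`)
#' demands a gap well below that baseline and the most aggressive setting
#' approaches it; higher `deep_split` therefore accepts weaker gaps and
#' yields at least as many (smaller) clusters. Clusters are the trimmed
#' cores of the maximal gap-free branches of size `>= min_cluster_size`
#' that are themselves tightly attached (trimmed height at most slightly
#' above the split threshold times the attachment height); loosely attached
#' diffuse branches -- the irregular background -- and small side branches
#' are shed to label 0, and residual loose members inside accepted clusters
#' are left to the downstream silhouette gate.
#' Labels are renumbered by decreasing cluster size (ties by smallest
#' member index).
#'
#' @param tree An [stats::hclust] dendrogram.
#' @param min_cluster_size Minimum number of leaves a cluster may have.
#' @param deep_split Integer 0--4 controlling cut aggressiveness.
#' @return Integer vector of labels in leaf order (0 = unassigned).
#' @export
dynamic_tree_cut <- function(tree, min_cluster_size = 100, deep_split = 0) {
  stopifnot(inherits(tree, "hclust"))
  if (min_cluster_size < 1) stop("min_cluster_size must be >= 1")
  if (!deep_split %in% 0:4) stop("deep_split must be in 0..4")
  alpha <- c(0.52, 0.56, 0.60, 0.64, 0.68)[deep_split + 1]
  accept <- alpha + 0.03  # tight-attachment bound for gap-free branches

  n <- nrow(tree$merge) + 1L
  labels <- integer(n)
  if (n == 1L) return(labels)

  # per internal node: height, size; hclust merge rows are ordered by
  # height, so children precede parents
  m <- tree$merge
  h <- tree$height
  size <- numeric(n - 1L)
  node_size <- function(k) if (k < 0) 1L else size[k]
  for (i in seq_len(n - 1L)) {
    size[i] <- node_size(m[i, 1]) + node_size(m[i, 2])
  }
  big <- function(k) node_size(k) >= min_cluster_size

  # trimmed branch core: descend the unique path of sub-branches still
  # holding >= 90% of the branch's leaves; the node where that stops is the
  # branch core, its height the branch height with up to 10% loosely
  # chained leaves ignored
  trim_node <- function(k) {
    if (k < 0) return(k)
    thr <- ceiling(0.9 * size[k])
    while (k > 0) {
      s1 <- node_size(m[k, 1]); s2 <- node_size(m[k, 2])
      nxt <- if (s1 >= s2) m[k, 1] else m[k, 2]
      if (node_size(nxt) < thr) return(k)
      k <- nxt
    }
    k
  }
  trimmed_h <- function(k) { k <- trim_node(k); if (k < 0) 0 else h[k] }
  # iterate the trim to its fixpoint: balanced branches stop immediately,
  # gradually chained tails are peeled layer by layer
  core_node <- function(k) {
    repeat {
      k2 <- trim_node(k)
      if (identical(k2, k)) return(k)
      k <- k2
    }
  }

  sig <- logical(n - 1L)          # node is a significant split
  has_split <- logical(n - 1L)    # subtree contains a significant split
  for (i in seq_len(n - 1L)) {
    sig[i] <- h[i] > 0 && big(m[i, 1]) && big(m[i, 2]) &&
      mean(c(trimmed_h(m[i, 1]), trimmed_h(m[i, 2]))) <= alpha * h[i]
    has_split[i] <- sig[i] ||
      (m[i, 1] > 0 && has_split[m[i, 1]]) ||
      (m[i, 2] > 0 && has_split[m[i, 2]])
  }

  leaves_of <- function(k) {
    out <- integer(0); stack <- k
    while (length(stack)) {
      j <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      if (j < 0) out <- c(out, -j) else stack <- c(stack, m[j, 1], m[j, 2])
    }
    out
  }

  next_label <- 0L
  assign_node <- function(k, attach_h) {
    if (!big(k)) return(invisible())            # shed: stays 0
    if (k < 0 || !has_split[k]) {
      # gap-free branch: accept as a cluster only if tightly attached, and
      # assign its trimmed core; leaves chained loosely above it stay 0
      if (trimmed_h(k) <= accept * attach_h) {
        core <- core_node(k)
        if (big(core)) {
          next_label <<- next_label + 1L
          labels[leaves_of(core)] <<- next_label
        }
      }
      return(invisible())
    }
    assign_node(m[k, 1], h[k])
    assign_node(m[k, 2], h[k])
  }
  assign_node(n - 1L, Inf)  # root is the last merge

  renumber_by_size(labels)
}

# renumber non-zero labels 1..K by decreasing size; ties by smallest member
renumber_by_size <- function(labels) {
  ids <- setdiff(unique(labels), 0L)
  if (!length(ids)) return(labels)
  sizes <- vapply(ids, function(i) sum(labels == i), integer(1))
  firsts <- vapply(ids, function(i) which(labels == i)[1], integer(1))
  ord <- ids[order(-sizes, firsts)]
  out <- labels
  for (k in seq_along(ord)) out[labels == ord[k]] <- k
  out
}

#' Per-gene silhouette widths
#'
#' Standard silhouette `s(i) = (b - a) / max(a, b)` on the Euclidean
#' distances of the log fold-change vectors, computed over genes with
#' non-zero labels only; genes with label 0 get `NA`. Singleton clusters
#' score 0. With fewer than two non-empty clusters, a warning is raised and
#' all scores are 0.
#'
#' @param lfc Log fold-change table (see [ward_linkage()]).
#' @param labels Integer labels aligned with `lfc` rows (0 = unassigned).
#' @return Numeric vector of silhouette widths in `[-1, 1]` (`NA` for
#'   label-0 genes).
#' @export
silhouette_scores <- function(lfc, labels) {
  x <- lfc_values(lfc)
  stopifnot(length(labels) == nrow(x))
  out <- rep(NA_real_, nrow(x))
  keep <- which(labels != 0)
  if (!length(keep)) return(out)
  lab <- labels[keep]
  if (length(unique(lab)) < 2) {
    warning("fewer than 2 clusters; all silhouette widths set to 0")
    out[keep] <- 0
    return(out)
  }
  sil <- cluster::silhouette(lab, dist(x[keep, , drop = FALSE]))
  out[keep] <- sil[, "sil_width"]
  out
}

#' Gate preliminary clusters into temporal expression clusters (TECs)
#'
#' Genes whose silhouette width falls below the threshold, or that the cut
#' left unassigned, are placed in TEC0 (irregular/nonresponsive); remaining
#' clusters are renumbered 1..K by decreasing size (ties by smallest member
#' index).
#'
#' @param lfc Log fold-change table.
#' @param labels Preliminary labels from [dynamic_tree_cut()].
#' @param scores Silhouette widths from [silhouette_scores()].
#' @param threshold Silhouette gate (default 0.1; genes strictly below go to
#'   TEC0).
#' @param min_cluster_size,deep_split Recorded parameters (metadata only).
#' @return A `tec_assignment` tibble: `gene_id`, `tec`, `silhouette`.
#' @export
assign_tecs <- function(lfc, labels, scores, threshold = 0.1,
                        min_cluster_size = NA, deep_split = NA) {
  stopifnot(length(labels) == length(scores))
  tec <- labels
  tec[is.na(scores) | scores < threshold] <- 0L
  tec <- renumber_by_size(tec)
  out <- tibble::tibble(gene_id = tibble::as_tibble(lfc)$gene_id,
                        tec = as.integer(tec),
                        silhouette = scores)
  structure(out, class = c("tec_assignment", class(out)),
            params = list(silhouette_threshold = threshold,
                          min_cluster_size = min_cluster_size,
                          deep_split = deep_split))
}

#' Full TEC assignment pipeline
#'
#' Ward-D2 linkage, adaptive tree cut, silhouette widths, and the TEC0 gate
#' in one call.
#'
#' @inheritParams ward_linkage
#' @inheritParams dynamic_tree_cut
#' @param silhouette_threshold Silhouette gate for TEC0 (default 0.1).
#' @return A `tec_assignment` tibble (see [assign_tecs()]).
#' @export
#' @examples
#' sim <- sim_expression_lfc(genes_per_cluster = 60, n_irregular = 40,
#'                           seed = 2)
#' tecs <- tec_cluster(sim$lfc, min_cluster_size = 30)
#' glance(tecs)
tec_cluster <- function(lfc, min_cluster_size = 100, deep_split = 0,
                        silhouette_threshold = 0.1) {
  tree <- ward_linkage(lfc)
  labels <- dynamic_tree_cut(tree, min_cluster_size, deep_split)
  scores <- silhouette_scores(lfc, labels)
  assign_tecs(lfc, labels, scores, silhouette_threshold,
              min_cluster_size = min_cluster_size, deep_split = deep_split)
}

#' @exportS3Method generics::tidy
tidy.tec_assignment <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @exportS3Method generics::glance
glance.tec_assignment <- function(x, ...) {
  assigned <- x$tec != 0
  tibble::tibble(
    n_genes = nrow(x),
    n_tecs = length(setdiff(unique(x$tec), 0L)),
    tec0_fraction = mean(!assigned),
    min_silhouette_assigned =
      if (any(assigned)) min(x$silhouette[assigned]) else NA_real_
  )
}

#' Per-TEC temporal summary profiles
#'
#' Mean, median, standard deviation and size per TEC and timepoint (members
#' only).
#'
#' @param lfc Log fold-change table.
#' @param tecs A `tec_assignment` (or tibble with `gene_id`, `tec`).
#' @return Tibble `tec`, `timepoint`, `mean`, `median`, `sd`, `n`; empty
#'   TECs yield `n = 0` rows with `NA` moments.
#' @export
tec_profiles <- function(lfc, tecs) {
  long <- tidyr::pivot_longer(tibble::as_tibble(lfc),
                              cols = -"gene_id",
                              names_to = "timepoint", values_to = "lfc")
  long <- dplyr::inner_join(long, tibble::as_tibble(tecs)[, c("gene_id", "tec")],
                            by = "gene_id")
  long$timepoint <- factor(long$timepoint,
                           levels = c("C15m", "C1h", "C4h", "C24h"))
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$tec, .data$timepoint),
    mean = mean(.data$lfc), median = median(.data$lfc),
    sd = sd(.data$lfc), n = dplyr::n(), .groups = "drop")
  # TECs with no member genes are kept as explicit n = 0 rows
  tidyr::complete(out, tec = sort(unique(tibble::as_tibble(tecs)$tec)),
                  .data$timepoint, fill = list(n = 0L))
}
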