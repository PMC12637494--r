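#' Default temporal log fold-change archetypes
#'
#' Seven archetypal log2 fold-change trajectories over the four confinement
#' contrasts (15 minutes, 1 hour, 4 hours, 24 hours, each versus the
#' non-confined control). The shapes emulate the observed temporal classes:
#' clusters 1, 3 and 4 are transiently up at 15 minutes and settle down-
#' regulated by 4 hours, while clusters 2, 5, 6 and 7 dip at 15 minutes and
#' settle upregulated -- cluster 7 most strongly (an early dip near -1.6
#' followed by stable means above 3).
#'
#' @return A 7 x 4 numeric matrix; rows are archetypes, columns are the
#'   timepoints `C15m`, `C1h`, `C4h`, `C24h` (log2 units).
#' @export
#' @examples
#' tec_archetypes()
tec_archetypes <- function() {
  m <- rbind(
    `1` = c(1.10, -0.25, -1.10, -1.10),
    `2` = c(-0.851, 1.184, 0.443, 0.63),
    `3` = c(0.40, -2.00, -3.20, -3.00),
    `4` = c(2.50, -1.00, -2.50, -2.20),
    `5` = c(-0.60, -0.25, 1.75, 1.90),
    `6` = c(-0.40, 2.10, 2.60, 2.40),
    `7` = c(-1.574, 1.00, 3.20, 3.20)
  )
  colnames(m) <- c("C15m", "C1h", "C4h", "C24h")
  m
}

#' Simulate temporal log fold-change profiles with planted clusters
#'
#' Generates a gene-by-timepoint log2 fold-change table in which each planted
#' cluster's members equal an archetype trajectory plus iid Gaussian noise,
#' and an additional "irregular" background class is pure Gaussian noise
#' around zero. The planted membership is returned as ground truth (cluster
#' `0` marks irregular genes).
#'
#' @param archetypes Numeric matrix with one row per planted cluster and 4
#'   columns (log2 fold change at `C15m`, `C1h`, `C4h`, `C24h`). Defaults to
#'   [tec_archetypes()].
#' @param genes_per_cluster Number of member genes per archetype.
#' @param n_irregular Number of irregular background genes.
#' @param noise_sd Gaussian noise standard deviation around each archetype
#'   (log2 units).
#' @param irregular_sd Standard deviation of the irregular class (log2 units).
#' @param seed Integer seed; the generator is fully reproducible under a
#'   fixed seed.
#' @return A list with `lfc`, a tibble (`gene_id`, `C15m`, `C1h`, `C4h`,
#'   `C24h`), and `truth`, a tibble (`gene_id`, `cluster`) with `cluster = 0`
#'   for irregular genes.
#' @export
#' @examples
#' sim <- sim_expression_lfc(genes_per_cluster = 20, n_irregular = 10, seed = 1)
#' dplyr::count(sim$truth, cluster)
sim_expression_lfc <- function(archetypes = tec_archetypes(),
                               genes_per_cluster = 200,
                               n_irregular = 420,
                               noise_sd = 0.3,
                               irregular_sd = 2,
                               seed = 1L) {
  if (is.null(archetypes) || nrow(as.matrix(archetypes)) == 0L) {
    archetypes <- matrix(numeric(0), nrow = 0, ncol = 4)
  }
  archetypes <- as.matrix(archetypes)
  if (ncol(archetypes) != 4 && nrow(archetypes) > 0)
    stop("archetypes must have 4 columns (C15m, C1h, C4h, C24h)")
  if (nrow(archetypes) > 0 && any(!is.finite(archetypes)))
    stop("archetype values must be finite")
  stopifnot(genes_per_cluster >= 0, n_irregular >= 0,
            noise_sd >= 0, irregular_sd >= 0)

  timepoints <- c("C15m", "C1h", "C4h", "C24h")
  n_clusters <- nrow(archetypes)
  n_member <- n_clusters * genes_per_cluster
  n_total <- n_member + n_irregular

  set.seed(seed)
  cluster <- c(rep(seq_len(n_clusters), each = genes_per_cluster),
               rep(0L, n_irregular))
  values <- matrix(0, nrow = n_total, ncol = 4,
                   dimnames = list(NULL, timepoints))
  if (n_member > 0) {
    base <- archetypes[cluster[seq_len(n_member)], , drop = FALSE]
    values[seq_len(n_member), ] <- base +
      rnorm(n_member * 4L, sd = noise_sd)
  }
  if (n_irregular > 0) {
    values[n_member + seq_len(n_irregular), ] <-
      rnorm(n_irregular * 4L, sd = irregular_sd)
  }
  gene_id <- sprintf("gene_%05d", seq_len(n_total))

  lfc <- tibble::as_tibble(values)
  lfc <- tibble::add_column(lfc, gene_id = gene_id, .before = 1)
  truth <- tibble::tibble(gene_id = gene_id, cluster = as.integer(cluster))
  list(lfc = lfc, truth = truth)
}
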