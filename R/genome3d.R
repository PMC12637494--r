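#' Initialize a beads-on-string model from a genome segmentation
#'
#' One spherical bead per segment (e.g. consensus TAD), one chain per
#' chromosome. Bead radii are proportional to the cube root of segment
#' length and scaled so the summed bead volume equals
#' `occupancy * (4/3) * pi * R^3`. Chains start as random walks with
#' touching-step lengths, rejection-sampled to stay inside the nucleus.
#'
#' @param segments Tibble `chrom`, `start`, `end` tiling each chromosome.
#' @param nucleus_radius Nuclear radius R in micrometres (default 5).
#' @param occupancy Fraction of the nuclear volume occupied by beads
#'   (default 0.15; must be < 1).
#' @param seed Integer seed.
#' @return A `bead_model` whose `beads` tibble has `chrom`, `start`, `end`,
#'   `x`, `y`, `z`, `radius`.
#' @export
init_beads <- function(segments, nucleus_radius = 5, occupancy = 0.15,
                       seed = 1L) {
  segments <- tibble::as_tibble(segments)
  stopifnot(all(c("chrom", "start", "end") %in% names(segments)))
  if (occupancy >= 1) stop("occupancy must be < 1")
  set.seed(seed)
  len <- segments$end - segments$start
  stopifnot(all(len > 0))
  radius <- len^(1 / 3)
  radius <- radius * (occupancy * nucleus_radius^3 / sum(radius^3))^(1 / 3)

  n <- nrow(segments)
  coords <- matrix(NA_real_, n, 3)
  for (chr in unique(segments$chrom)) {
    idx <- which(segments$chrom == chr)
    repeat {
      ok <- TRUE
      for (k in seq_along(idx)) {
        i <- idx[k]
        placed <- FALSE
        for (try in 1:200) {
          if (k == 1) {
            p <- runif(3, -1, 1) * nucleus_radius
          } else {
            u <- rnorm(3); u <- u / sqrt(sum(u^2))
            step <- radius[idx[k - 1]] + radius[i]
            p <- coords[idx[k - 1], ] + u * step
          }
          if (sqrt(sum(p^2)) + radius[i] <= nucleus_radius) {
            coords[i, ] <- p; placed <- TRUE; break
          }
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (ok) break
    }
  }
  beads <- dplyr::mutate(segments, x = coords[, 1], y = coords[, 2],
                         z = coords[, 3], radius = radius)
  structure(list(beads = beads, nucleus_radius = nucleus_radius,
                 occupancy = occupancy, seed = seed, loss = NA_real_),
            class = "bead_model")
}

#' Monte-Carlo optimization of a bead model
#'
#' Metropolis optimization with single-bead Gaussian displacement proposals
#' and geometric temperature decay of a squared-penalty loss: chain
#' continuity (adjacent beads at touching distance), attraction constraints
#' (pairs pulled to touching), excluded volume between non-adjacent beads,
#' and nuclear containment. Returns the best configuration seen and its
#' (non-increasing) best-loss trace.
#'
#' @param model A `bead_model` from [init_beads()].
#' @param constraints Data frame (`bead1`, `bead2`) of attraction pairs
#'   (row indices into `model$beads`), or `NULL`.
#' @param steps Number of Metropolis steps (`<= 0` returns the input
#'   unchanged).
#' @param t0 Initial temperature.
#' @param cooling Geometric cooling factor per step.
#' @param sigma Proposal displacement standard deviation (micrometres).
#' @param seed Integer seed.
#' @return The optimized `bead_model`, with `loss` set and attributes
#'   `trace` (best-loss trace) and `acceptance`.
#' @export
mc_optimize <- function(model, constraints = NULL, steps = 20000,
                        t0 = 1, cooling = 0.999, sigma = 0.2, seed = 1L) {
  if (steps <= 0) return(model)
  set.seed(seed)
  beads <- model$beads
  con <- constraint_matrix(constraints, nrow(beads))
  chain <- as.integer(factor(beads$chrom, levels = unique(beads$chrom)))
  fit <- mc_optimize_cpp(as.matrix(beads[, c("x", "y", "z")]), beads$radius,
                         chain, con, model$nucleus_radius,
                         as.integer(steps), t0, cooling, sigma,
                         trace_every = max(1L, as.integer(steps / 200)))
  model$beads$x <- fit$coords[, 1]
  model$beads$y <- fit$coords[, 2]
  model$beads$z <- fit$coords[, 3]
  model$loss <- fit$loss
  attr(model, "trace") <- fit$trace
  attr(model, "acceptance") <- fit$acceptance
  model
}

constraint_matrix <- function(constraints, n_beads) {
  if (is.null(constraints) || nrow(constraints) == 0L)
    return(matrix(integer(0), ncol = 2))
  con <- as.matrix(constraints[, c("bead1", "bead2")])
  storage.mode(con) <- "integer"
  if (any(con < 1 | con > n_beads)) stop("constraints reference invalid beads")
  con - 1L  # 0-based for the kernel
}

#' Loss of a bead configuration
#'
#' @param model A `bead_model`.
#' @param constraints As in [mc_optimize()].
#' @return The scalar squared-penalty loss.
#' @export
model_loss <- function(model, constraints = NULL) {
  beads <- model$beads
  chain <- as.integer(factor(beads$chrom, levels = unique(beads$chrom)))
  total_loss_cpp(as.matrix(beads[, c("x", "y", "z")]), beads$radius, chain,
                 constraint_matrix(constraints, nrow(beads)),
                 model$nucleus_radius)
}

#' Ensemble of independently optimized bead models
#'
#' @inheritParams init_beads
#' @inheritParams mc_optimize
#' @param n_models Ensemble size (the reference workflow uses 100 models
#'   per condition).
#' @return A `bead_ensemble` (list of optimized `bead_model`s, each carrying
#'   its seed and final loss).
#' @export
model_ensemble <- function(segments, constraints = NULL, n_models = 100,
                           nucleus_radius = 5, occupancy = 0.15,
                           steps = 20000, t0 = 1, cooling = 0.999,
                           sigma = 0.2, seed = 1L) {
  models <- lapply(seq_len(n_models), function(k) {
    s <- seed + k - 1L
    m <- init_beads(segments, nucleus_radius, occupancy, seed = s)
    m <- mc_optimize(m, constraints, steps, t0, cooling, sigma, seed = s)
    m$seed <- s
    m
  })
  structure(models, class = "bead_ensemble")
}

#' Annotate beads by largest overlap
#'
#' Assigns each bead the label of the interval track with the largest
#' overlapped base pairs (`by = "overlap"`), or -- for gene sets -- the
#' label carried by the largest number of overlapping genes
#' (`by = "genes"`, expecting `chrom`, `tss`, `label` columns). Ties go to
#' the lexicographically smallest label; beads with no overlap get `NA`.
#'
#' @param model A `bead_model`.
#' @param annotation Tibble: either intervals (`chrom`, `start`, `end`,
#'   `label`) or genes (`chrom`, `tss`, `label`).
#' @param by `"overlap"` or `"genes"`.
#' @return The model with a `label` column on its beads.
#' @export
annotate_beads <- function(model, annotation, by = c("overlap", "genes")) {
  by <- match.arg(by)
  beads <- model$beads
  bead_gr <- GenomicRanges::GRanges(
    beads$chrom, IRanges::IRanges(start = beads$start + 1, end = beads$end))
  annotation <- annotation[!is.na(annotation$label), , drop = FALSE]
  if (by == "overlap") {
    ann_gr <- GenomicRanges::GRanges(
      annotation$chrom,
      IRanges::IRanges(start = annotation$start + 1, end = annotation$end))
    hits <- GenomicRanges::findOverlaps(bead_gr, ann_gr)
    ov <- GenomicRanges::width(GenomicRanges::pintersect(
      bead_gr[S4Vectors::queryHits(hits)], ann_gr[S4Vectors::subjectHits(hits)]))
    score <- tibble::tibble(bead = S4Vectors::queryHits(hits),
                            label = annotation$label[S4Vectors::subjectHits(hits)],
                            w = ov)
  } else {
    ann_gr <- GenomicRanges::GRanges(
      annotation$chrom, IRanges::IRanges(start = annotation$tss + 1, width = 1))
    hits <- GenomicRanges::findOverlaps(bead_gr, ann_gr)
    score <- tibble::tibble(bead = S4Vectors::queryHits(hits),
                            label = annotation$label[S4Vectors::subjectHits(hits)],
                            w = 1L)
  }
  best <- dplyr::summarise(dplyr::group_by(score, .data$bead, .data$label),
                           w = sum(.data$w), .groups = "drop")
  best <- dplyr::arrange(best, .data$bead, dplyr::desc(.data$w), .data$label)
  best <- dplyr::slice_head(dplyr::group_by(best, .data$bead), n = 1)
  model$beads$label <- NA_character_
  model$beads$label[best$bead] <- as.character(best$label)
  model
}

#' Radial positioning statistics per label
#'
#' Pools bead center distances across all models of an ensemble by label and
#' reports the median distance, its standard deviation and the bead count,
#' plus pairwise Wilcoxon rank-sum tests between labels with Holm
#' adjustment.
#'
#' @param ensemble A `bead_ensemble` whose beads carry a `label` column
#'   (see [annotate_beads()]).
#' @param per_model Summarise per-model medians instead of pooling beads.
#' @return List with `summary` (tibble `label`, `median`, `sd`, `n`) and
#'   `pairwise` (tibble `label1`, `label2`, `p`, `p_holm`).
#' @export
radial_stats <- function(ensemble, per_model = FALSE) {
  stopifnot(length(ensemble) >= 1)
  pooled <- purrr::imap_dfr(ensemble, function(m, i)
    tibble::tibble(model = i, label = m$beads$label, d = radial_distances(m)))
  pooled <- pooled[!is.na(pooled$label), ]
  if (any(table(pooled$label) == 0)) warning("labels with 0 beads excluded")
  if (per_model) {
    pooled <- dplyr::summarise(
      dplyr::group_by(pooled, .data$model, .data$label),
      d = median(.data$d), .groups = "drop")
  }
  summary <- dplyr::summarise(
    dplyr::group_by(pooled, .data$label),
    median = median(.data$d), sd = sd(.data$d), n = dplyr::n(),
    .groups = "drop")
  labs <- sort(unique(pooled$label))
  pairs <- if (length(labs) >= 2) utils::combn(labs, 2) else
    matrix(character(0), nrow = 2)
  pairwise <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    a <- pooled$d[pooled$label == pairs[1, k]]
    b <- pooled$d[pooled$label == pairs[2, k]]
    exact <- length(a) < 25 && length(b) < 25
    p <- suppressWarnings(
      wilcox.test(a, b, exact = exact, correct = TRUE)$p.value)
    tibble::tibble(label1 = pairs[1, k], label2 = pairs[2, k], p = p)
  })
  if (nrow(pairwise)) pairwise$p_holm <- p.adjust(pairwise$p, method = "holm")
  list(summary = summary, pairwise = pairwise)
}

#' Per-bead radial shift between two ensembles
#'
#' For each bead (identical segmentation required) the median center
#' distance across models is computed in each ensemble; the per-bead shift
#' `delta = median_b - median_a` is tested against zero with a two-sided
#' Wilcoxon signed-rank test.
#'
#' @param ensemble_a,ensemble_b Two `bead_ensemble`s on the same
#'   segmentation.
#' @return List with `shifts` (tibble `chrom`, `start`, `end`, `median_a`,
#'   `median_b`, `delta`), `p` (signed-rank p-value) and `median_shift`.
#' @export
per_bead_median_shift <- function(ensemble_a, ensemble_b) {
  pos_cols <- intersect(c("chrom", "start", "end"),
                        names(ensemble_a[[1]]$beads))
  seg_a <- ensemble_a[[1]]$beads[, pos_cols, drop = FALSE]
  seg_b <- ensemble_b[[1]]$beads[, intersect(pos_cols,
                                             names(ensemble_b[[1]]$beads)),
                                 drop = FALSE]
  if (nrow(seg_a) != nrow(ensemble_b[[1]]$beads) ||
      !identical(as.data.frame(seg_a), as.data.frame(seg_b)))
    stop("ensembles must share an identical segmentation")
  med_of <- function(ens) {
    d <- vapply(ens, radial_distances, numeric(nrow(ens[[1]]$beads)))
    apply(as.matrix(d), 1, median)
  }
  ma <- med_of(ensemble_a)
  mb <- med_of(ensemble_b)
  delta <- mb - ma
  p <- if (all(delta == 0)) 1 else
    suppressWarnings(wilcox.test(delta, mu = 0, exact = FALSE,
                                 correct = TRUE)$p.value)
  list(shifts = dplyr::mutate(seg_a, median_a = ma, median_b = mb,
                              delta = delta),
       p = p, median_shift = median(delta))
}
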