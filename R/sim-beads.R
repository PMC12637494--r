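#' Simulate bead ensembles with planted radial gradients
#'
#' Draws isotropic bead clouds in a nuclear sphere with group-specific radial
#' distributions: each labelled group's beads sit at distances
#' `Normal(mean_radius, sd)` from the nuclear center (truncated to
#' `[0, nucleus_radius]`) with uniformly random directions. This is the
#' ground-truth fixture for the radial-position analytics.
#'
#' @param n_models Number of independent models in the ensemble.
#' @param groups Data frame (`label`, `mean_radius`, `sd`, optionally `n`)
#'   in micrometres; `n` beads per group per model (default 100).
#' @param nucleus_radius Nuclear radius R in micrometres.
#' @param seed Integer seed.
#' @return A `bead_ensemble`: list of `bead_model` objects whose `beads`
#'   tibble has `label`, `x`, `y`, `z`, `radius` (bead radius 0 for point
#'   clouds).
#' @export
#' @examples
#' groups <- data.frame(label = c("A", "B"), mean_radius = c(3, 4),
#'                      sd = 0, n = 10)
#' ens <- sim_bead_cloud(2, groups, seed = 1)
#' radial_distances(ens[[1]])
sim_bead_cloud <- function(n_models, groups, nucleus_radius = 5, seed = 1L) {
  groups <- tibble::as_tibble(groups)
  stopifnot(all(c("label", "mean_radius", "sd") %in% names(groups)))
  if (!("n" %in% names(groups))) groups$n <- 100L
  if (any(groups$sd < 0)) stop("sd must be non-negative")
  if (any(groups$mean_radius < 0 | groups$mean_radius > nucleus_radius))
    stop("mean_radius must lie in [0, nucleus_radius]")
  set.seed(seed)

  models <- lapply(seq_len(n_models), function(m) {
    beads <- purrr::pmap_dfr(groups, function(label, mean_radius, sd, n) {
      r <- pmin(pmax(rnorm(n, mean_radius, sd), 0), nucleus_radius)
      u <- matrix(rnorm(3 * n), ncol = 3)
      u <- u / sqrt(rowSums(u^2))
      tibble::tibble(label = as.character(label),
                     x = r * u[, 1], y = r * u[, 2], z = r * u[, 3],
                     radius = 0)
    })
    structure(list(beads = beads, nucleus_radius = nucleus_radius,
                   occupancy = NA_real_, seed = seed, loss = NA_real_),
              class = "bead_model")
  })
  structure(models, class = "bead_ensemble")
}

#' @export
print.bead_model <- function(x, ...) {
  cat("<bead_model> ", nrow(x$beads), " beads; R = ", x$nucleus_radius,
      " um", if (!is.na(x$loss)) paste0("; loss ", signif(x$loss, 4)), "\n",
      sep = "")
  invisible(x)
}

#' @export
print.bead_ensemble <- function(x, ...) {
  cat("<bead_ensemble> ", length(x), " model(s) of ",
      if (length(x)) nrow(x[[1]]$beads) else 0, " beads\n", sep = "")
  invisible(x)
}

#' Distances of bead centers from the nuclear center
#'
#' @param model A `bead_model`.
#' @return Numeric vector of Euclidean center distances (micrometres).
#' @export
radial_distances <- function(model) {
  with(model$beads, sqrt(x^2 + y^2 + z^2))
}
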