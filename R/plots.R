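#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-TEC temporal profiles
#'
#' Line-and-ribbon summary of the mean log2 fold change per TEC over the
#' confinement timepoints.
#'
#' @param profiles Output of [tec_profiles()].
#' @return A ggplot object.
#' @export
plot_tec_profiles <- function(profiles) {
  ggplot2::ggplot(profiles,
                  ggplot2::aes(x = .data$timepoint, y = .data$mean,
                               group = .data$tec)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         fill = "grey80") +
    ggplot2::geom_line(colour = "red") +
    ggplot2::facet_wrap(~tec) +
    ggplot2::labs(x = NULL, y = "log2 fold change vs NC") +
    ggplot2::theme_minimal()
}

#' Plot a subcompartment switch matrix
#'
#' Heatmap of the Mbp switching between the eight states across two
#' conditions.
#'
#' @param m An 8x8 matrix from [switch_matrix()].
#' @param from,to Axis titles (condition names).
#' @return A ggplot object.
#' @export
plot_switch_matrix <- function(m, from = "condition A", to = "condition B") {
  d <- tibble::as_tibble(as.table(m), .name_repair = ~c("from", "to", "mbp"))
  d$from <- factor(d$from, levels = rev(SUBCOMP_LEVELS))
  d$to <- factor(d$to, levels = SUBCOMP_LEVELS)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$to, y = .data$from,
                                  fill = .data$mbp)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(x = to, y = from, fill = "Mbp") +
    ggplot2::theme_minimal()
}

#' @describeIn nonmetric_mds Scatter plot of the 2D configuration with item
#'   labels.
#' @param object An `mds_fit`.
#' @param ... Ignored.
#' @exportS3Method ggplot2::autoplot
autoplot.mds_fit <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$dim1, y = .data$dim2,
                                  label = .data$item)) +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::geom_text(vjust = -0.7, size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "MDS 1", y = "MDS 2",
                  subtitle = sprintf("stress = %.3f", object$stress)) +
    ggplot2::theme_minimal()
}

#' Plot radial positioning summaries
#'
#' Median +/- sd of bead center distances per label.
#'
#' @param stats Output of [radial_stats()].
#' @return A ggplot object.
#' @export
plot_radial_summary <- function(stats) {
  d <- stats$summary
  lev <- intersect(SUBCOMP_LEVELS, d$label)
  if (length(lev)) d$label <- factor(d$label, levels = c(lev, setdiff(d$label, lev)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$label, y = .data$median)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$median - .data$sd,
                                          ymax = .data$median + .data$sd)) +
    ggplot2::labs(x = NULL, y = "distance from nuclear center (µm)") +
    ggplot2::theme_minimal()
}
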