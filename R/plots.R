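#' Scree plot of a PCA result
#'
#' @param object a `pca_result`.
#' @param n_modes number of leading modes to show.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.pca_result <- function(object, n_modes = 10, ...) {
  df <- tidy.pca_result(object)
  df <- df[seq_len(min(n_modes, nrow(df))), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mode, y = .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$cumulative_fraction)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$cumulative_fraction)) +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%",
                                                             100 * v)) +
    ggplot2::labs(x = "mode", y = "variance fraction",
                  title = "Coordinate-covariance PCA spectrum") +
    ggplot2::theme_minimal()
}

#' Per-cycle minimum-metric plot of a campaign
#'
#' @param object a `stepwise_campaign`.
#' @param ... unused.
#' @return a ggplot of the per-cycle minimum progress metric, with the
#'   initial value at cycle 0.
#' @export
autoplot.stepwise_campaign <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(cycle = 0L, min_metric = object$initial_metric),
    object$series[, c("cycle", "min_metric")])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cycle, y = .data$min_metric)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "cycle", y = "minimum progress metric",
                  title = "Step-by-step campaign convergence") +
    ggplot2::theme_minimal()
}

#' Plot a reweighted free-energy profile
#'
#' @param profile tibble from [reweight_profile()].
#' @param reference optional function of the bin center giving a
#'   reference profile (e.g. the analytic potential), drawn dashed after
#'   min-shifting.
#' @return a ggplot.
#' @export
plot_free_energy_profile <- function(profile, reference = NULL) {
  p <- ggplot2::ggplot(profile,
                       ggplot2::aes(x = .data$center,
                                    y = .data$free_energy)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "observable", y = "free energy",
                  title = "Reweighted free-energy profile") +
    ggplot2::theme_minimal()
  if (!is.null(reference)) {
    ref <- reference(profile$center)
    ref <- ref - min(ref)
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(center = profile$center, free_energy = ref),
      linetype = "dashed", colour = "grey40")
  }
  p
}

#' Plot a targeted-MD RMSD schedule against the measured RMSD
#'
#' @param series tibble from [tmd_rmsd_series()].
#' @return a ggplot with the measured best-fit RMSD (solid) and the
#'   scheduled reference (dashed).
#' @export
plot_tmd_schedule <- function(series) {
  long <- tidyr::pivot_longer(series, c("rmsd", "rmsd_target"),
                              names_to = "kind", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value,
                                     linetype = .data$kind)) +
    ggplot2::geom_line() +
    ggplot2::scale_linetype_manual(
      values = c(rmsd = "solid", rmsd_target = "dashed"),
      labels = c(rmsd = "measured", rmsd_target = "scheduled")) +
    ggplot2::labs(x = "time", y = "best-fit RMSD", linetype = NULL,
                  title = "Targeted-MD steering") +
    ggplot2::theme_minimal()
}

#' Scatter plot of two labelled distance pairs
#'
#' The pair-vs-pair state-separation view: each frame becomes one point
#' in the plane of two site-pair distances.
#'
#' @param series tibble from [distance_pairs_series()] containing exactly
#'   two pairs.
#' @param colour optional per-frame grouping vector (e.g. run id).
#' @return a ggplot.
#' @export
plot_pair_scatter <- function(series, colour = NULL) {
  pairs <- unique(series$pair)
  if (length(pairs) != 2) stop("need exactly two pairs", call. = FALSE)
  wide <- tidyr::pivot_wider(series, id_cols = c("frame", "time"),
                             names_from = "pair",
                             values_from = "distance")
  if (!is.null(colour)) wide$colour <- colour
  p <- ggplot2::ggplot(wide,
                       ggplot2::aes(x = .data[[pairs[1]]],
                                    y = .data[[pairs[2]]])) +
    ggplot2::labs(title = "Site-pair distance scatter") +
    ggplot2::theme_minimal()
  if (is.null(colour)) {
    p + ggplot2::geom_point(alpha = 0.5)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$colour),
                            alpha = 0.5) +
      ggplot2::labs(colour = NULL)
  }
}
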