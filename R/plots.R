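#' Plot an averaged density profile
#'
#' Draws the normalised density against position along the line, in the
#' orientation density-profile figures conventionally use, optionally
#' marking detected peaks.
#'
#' @param object a `density_profile` from [extract_profile()].
#' @param peaks optional peak tibble from [detect_peaks()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot density_profile
#' @export
autoplot.density_profile <- function(object, peaks = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$position_nm, .data$density)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(
      x = "position along line (nm)",
      y = "normalized density",
      title = attr(object, "line_id")
    ) +
    ggplot2::theme_minimal()
  if (!is.null(peaks) && nrow(peaks)) {
    p <- p + ggplot2::geom_vline(
      data = peaks,
      ggplot2::aes(xintercept = .data$position_nm),
      linetype = "dashed", colour = "darkgreen", linewidth = 0.3
    )
  }
  p
}

#' Plot recovery bias per quantity
#'
#' Mean recovered value minus ground truth, with +/- 1 SD error bars, for
#' every quantity of a [run_recovery()] result.
#'
#' @param object a `recovery_result`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot recovery_result
#' @export
autoplot.recovery_result <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(
    s,
    ggplot2::aes(paste(.data$variant, .data$quantity, sep = "\n"),
                 .data$bias_nm)
  ) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$bias_nm - .data$sd_nm,
                                          ymax = .data$bias_nm + .data$sd_nm)) +
    ggplot2::labs(x = NULL, y = "bias (recovered - true, nm)") +
    ggplot2::theme_minimal()
}

#' Plot the depth distribution of a lamella census
#'
#' Depth below the sample surface per cell, split by live/dead state.
#'
#' @param object a `lamella_census`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot lamella_census
#' @export
autoplot.lamella_census <- function(object, ...) {
  ggplot2::ggplot(object$cells,
                  ggplot2::aes(.data$state, .data$depth_nm / 1000)) +
    ggplot2::geom_violin(fill = "grey85", colour = NA) +
    ggplot2::geom_boxplot(width = 0.15, outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.08, size = 0.8, alpha = 0.6) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = NULL, y = "depth below surface (µm)") +
    ggplot2::theme_minimal()
}
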