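#' Plot a hypnogram
#'
#' Stage trace over time with artifact epochs marked.
#'
#' @param grid a scored `phenomap_grid`.
#' @return a ggplot.
#' @export
plot_hypnogram <- function(grid) {
  df <- as_tibble(grid)
  df$stage <- factor(df$stage, levels = rev(STAGE_TOKENS))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$timestamp, y = .data$stage)) +
    ggplot2::geom_step(ggplot2::aes(group = 1), linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = NULL, title = "Hypnogram") +
    ggplot2::theme_minimal()
}

#' Heatmap of an ROI test map
#'
#' Displays -log10(p) per ROI (the "jet map" view of the group comparison),
#' or the onset timepoint when `map = "onset"`.
#'
#' @param object a `phenomap_roi_test`.
#' @param map "p" or "onset".
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.phenomap_roi_test <- function(object, map = c("p", "onset"), ...) {
  map <- match.arg(map)
  m <- if (map == "p") -log10(object$p) else object$onset
  df <- tibble(
    row = rep(seq_len(nrow(m)), ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    value = as.numeric(m)
  )
  lab <- if (map == "p") "-log10 p" else "onset timepoint"
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = lab) +
    ggplot2::theme_minimal()
}

#' Stage-conditioned photometry means
#'
#' Per-class mean with SD error bars, per channel.
#'
#' @param object a `phenomap_photometry_summary`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.phenomap_photometry_summary <- function(object, ...) {
  df <- object$class_means
  ggplot2::ggplot(df, ggplot2::aes(.data$stage_class, .data$mean,
                                   fill = .data$channel)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd,
                   ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(width = 0.9), width = 0.2
    ) +
    ggplot2::labs(x = NULL, y = "epoch-mean z", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
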