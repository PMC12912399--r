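# ggplot2 visualizations and broom-style tidiers for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidiers for ROI rankings
#'
#' `tidy()` returns the ranking table (one row per ROI); `glance()` a
#' one-row summary.
#'
#' @param x A `roi_ranking` from [rank_rois()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy roi_ranking
#' @export
tidy.roi_ranking <- function(x, ...) {
  x$ranking
}

#' @rdname tidy.roi_ranking
#' @method glance roi_ranking
#' @export
glance.roi_ranking <- function(x, ...) {
  tibble::tibble(
    n_rois = nrow(x$ranking),
    n_activities = length(x$activities),
    top_roi_index = x$ranking$roi_index[1],
    top_roi_name = x$ranking$roi_name[1],
    top_os_sum = x$ranking$os_sum[1],
    top_group_size = sum(x$ranking$top_group),
    method_mode = x$method_mode
  )
}

#' Tidiers for Bland-Altman results
#'
#' `tidy()` returns the per-window measurements; `glance()` the bias and
#' limits of agreement.
#'
#' @param x A `bland_altman` from [bland_altman()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy bland_altman
#' @export
tidy.bland_altman <- function(x, ...) {
  x$windows
}

#' @rdname tidy.bland_altman
#' @method glance bland_altman
#' @export
glance.bland_altman <- function(x, ...) {
  tibble::tibble(
    n_windows = x$n,
    mean_diff = x$mean_diff,
    loa_lower = x$loa_lower,
    loa_upper = x$loa_upper
  )
}

#' Stacked overall-score bar chart of an ROI ranking
#'
#' One bar per ROI (descending summed OS), stacked by activity; members of
#' the top group are outlined.
#'
#' @param object A `roi_ranking`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot roi_ranking
#' @export
autoplot.roi_ranking <- function(object, ...) {
  os <- object$os
  order_levels <- rev(object$ranking$roi_name)
  os$roi_name <- factor(os$roi_name, levels = order_levels)
  ggplot2::ggplot(os, ggplot2::aes(x = .data$roi_name, y = .data$os,
                                   fill = .data$activity)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "summed overall score (OS)",
                  fill = "activity") +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot
#'
#' Window differences against window means, with the bias line, 1.96 SD
#' limits of agreement, and the +-10 BPM acceptability band.
#'
#' @param object A `bland_altman`.
#' @param threshold_bpm Acceptability band half-width (BPM); `NULL` to omit.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bland_altman
#' @export
autoplot.bland_altman <- function(object, threshold_bpm = 10, ...) {
  p <- ggplot2::ggplot(object$windows,
                       ggplot2::aes(x = .data$mean_bpm, y = .data$diff_bpm))
  if (!is.null(threshold_bpm)) {
    p <- p + ggplot2::annotate(
      "rect", xmin = -Inf, xmax = Inf,
      ymin = -threshold_bpm, ymax = threshold_bpm,
      alpha = 0.15, fill = "green4"
    )
  }
  p +
    ggplot2::geom_hline(yintercept = object$mean_diff,
                        linetype = "solid") +
    ggplot2::geom_hline(yintercept = c(object$loa_lower, object$loa_upper),
                        linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "mean of estimate and reference (BPM)",
                  y = "estimate - reference (BPM)") +
    ggplot2::theme_minimal()
}

#' Plot estimated against reference heart rate
#'
#' @param paired A `paired_hr` tibble from [align_hr()].
#' @return A ggplot object.
#' @export
plot_hr_series <- function(paired) {
  df <- tidyr::pivot_longer(paired, c("estimate", "reference"),
                            names_to = "series", values_to = "bpm")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$bpm,
                                   color = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "heart rate (BPM)", color = NULL) +
    ggplot2::theme_minimal()
}
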