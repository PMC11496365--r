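#' Heatmap of a time-savings ROC map
#'
#' Mirrors the summary-plot layout: ROC space colored by the mean
#' diseased time saving, red for savings (negative \eqn{\delta W_D}),
#' blue for delays, with the cell values printed.
#'
#' @param object A `roc_map` from [delta_map()].
#' @param label_cells Print the \eqn{\delta W_D} values on the tiles.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot roc_map
#' @export
autoplot.roc_map <- function(object, label_cells = TRUE, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                            fill = .data$delta_w_d)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(
      low = "#b2182b", mid = "#f7f7f7", high = "#2166ac", midpoint = 0,
      name = expression(delta * W[D] ~ "(min)")
    ) +
    ggplot2::labs(
      x = "False-positive rate (1 - Sp)", y = "True-positive rate (Se)",
      title = "Mean time savings for diseased images across ROC space"
    ) +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
  if (label_cells) {
    p <- p + ggplot2::geom_text(
      ggplot2::aes(label = sprintf("%.0f", .data$delta_w_d)), size = 2.6
    )
  }
  p
}

#' Per-run deltas from a simulation batch
#'
#' Histogram of the per-run mean diseased wait differences with the two
#' 95% intervals (run percentiles and normal theory) marked.
#'
#' @param object A `cadt_sim` from [run_batch()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cadt_sim
#' @export
autoplot.cadt_sim <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(object$per_run, ggplot2::aes(x = .data$delta_w_d)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", color = "grey30") +
    ggplot2::geom_vline(xintercept = s$delta_w_d, linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = c(s$delta_w_d_lo, s$delta_w_d_hi),
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = c(s$delta_w_d_lo_norm,
                                       s$delta_w_d_hi_norm),
                        linetype = "dotted") +
    ggplot2::labs(
      x = expression("per-run mean" ~ delta * W[D] ~ "(min)"),
      y = "runs",
      title = "Paired-simulation distribution of diseased time savings",
      subtitle = "dashed: 95% run percentiles; dotted: normal-theory CI"
    ) +
    ggplot2::theme_minimal()
}

#' Time savings along an ROC curve
#'
#' @param curve_tbl A tibble from [delta_along_curve()].
#' @param against Plot the savings against `"fpr"` or `"tpr"`.
#' @return A ggplot object.
#' @export
plot_delta_curve <- function(curve_tbl, against = c("fpr", "tpr")) {
  against <- match.arg(against)
  ggplot2::ggplot(curve_tbl,
                  ggplot2::aes(x = .data[[against]], y = .data$delta_w_d)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = toupper(against),
                  y = expression(delta * W[D] ~ "(min)"),
                  title = "Diseased time savings along the ROC curve") +
    ggplot2::theme_minimal()
}
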