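# ggplot2 visualizations for the main result types.

raster_df <- function(m, value = "value") {
  df <- expand.grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df[[value]] <- as.vector(m)
  tibble::as_tibble(df)
}

#' Plot a figure-ground field
#'
#' Displays the BOS following the standard hue/saturation convention: hue
#' encodes the decoded figure direction, saturation-like alpha encodes BOS
#' strength.
#'
#' @param object an `fg_field`.
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.fg_field <- function(object, ...) {
  df <- raster_df(object$magnitude, "magnitude")
  df$angle_deg <- as.vector(object$angle) * 180 / pi
  mx <- max(df$magnitude)
  if (mx > 0) df$magnitude <- df$magnitude / mx
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$angle_deg,
                                      alpha = .data$magnitude)) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradientn(
      colours = c("red", "yellow", "green", "cyan", "blue", "magenta", "red"),
      limits = c(0, 360), name = "figure direction (deg)") +
    ggplot2::scale_alpha_identity() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, title = "Border ownership field") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.fg_field
#' @export
plot.fg_field <- function(x, ...) print(autoplot.fg_field(x, ...))

#' Plot a model run
#'
#' Grouping-map view of an [fg_run()] result: polarity-combined grouping
#' activity summed across scales, warmer colors for higher activity.
#'
#' @param object an `fg_result`.
#' @param what `"grouping"` or `"field"`.
#' @param ... passed on.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.fg_result <- function(object, what = c("grouping", "field"), ...) {
  what <- match.arg(what)
  if (what == "field") return(autoplot.fg_field(object$field, ...))
  df <- raster_df(object$grouping_map, "activity")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$activity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(option = "inferno", name = "G activity") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, title = "Grouping (proto-object) map") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.fg_result
#' @export
plot.fg_result <- function(x, ...) print(autoplot.fg_result(x, ...))

#' Plot a precision-recall curve
#'
#' @param object a `pr_curve` from [pr_sweep()].
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pr_curve <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Recall", y = "Precision",
                  subtitle = sprintf("best F = %.3f, AP = %.3f",
                                     object$best_f, object$ap)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.pr_curve
#' @export
plot.pr_curve <- function(x, ...) print(autoplot.pr_curve(x, ...))
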