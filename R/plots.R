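# ggplot2 views of the main result types.

#' Plate heatmap of Z-scores for one line
#'
#' @param zscores Output of [plate_zscores()] (optionally after
#'   [inhibition()]).
#' @param plate One plate id.
#' @param line One line id.
#' @return A ggplot: the 96-well grid coloured by Z.
#' @export
plot_plate_zscores <- function(zscores, plate, line) {
  df <- zscores |>
    dplyr::filter(.data$plate_id == plate, .data$line_id == line) |>
    dplyr::mutate(row = substr(.data$well_id, 1, 1),
                  col = as.integer(substr(.data$well_id, 2, 3)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col,
                                   y = factor(.data$row, levels = rev(LETTERS[1:8])),
                                   fill = .data$z)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", midpoint = 0,
                                  na.value = "grey80") +
    ggplot2::scale_x_continuous(breaks = 1:12) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Z",
                  title = sprintf("%s - %s", plate, line)) +
    ggplot2::theme_minimal()
}

#' Down-sampling Z curve plot
#'
#' @param zcurve Output of [downsample_zcurve()].
#' @param z_threshold Detection threshold drawn as a reference line.
#' @return A ggplot of Z against the simulated read reduction, one line per
#'   (plate, well).
#' @export
plot_zcurve <- function(zcurve, z_threshold = -1.5) {
  ggplot2::ggplot(zcurve,
                  ggplot2::aes(x = .data$reduction, y = .data$z,
                               group = interaction(.data$plate_id, .data$well_id),
                               colour = .data$plate_id)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = z_threshold, linetype = "dashed") +
    ggplot2::scale_x_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = "simulated read reduction", y = "Z-score",
                  colour = "plate") +
    ggplot2::theme_minimal()
}

#' Compound-of-interest volcano-style scatter
#'
#' @param coi Output of [compounds_of_interest()].
#' @return A ggplot of inhibition against Z, passing observations
#'   highlighted.
#' @export
plot_coi <- function(coi) {
  ggplot2::ggplot(coi, ggplot2::aes(x = .data$z, y = .data$inhibition,
                                    colour = .data$passed)) +
    ggplot2::geom_point(alpha = 0.6, na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "#b2182b")) +
    ggplot2::labs(x = "Z-score", y = "inhibition vs DMSO",
                  colour = "passed") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.screen_result <- function(object, ...) {
  plot_coi(object$coi)
}
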