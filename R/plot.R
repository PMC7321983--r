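map_to_df <- function(m, value_name = "value") {
  d <- dim(m)
  tibble::tibble(
    row = rep(seq_len(d[1]), d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    !!value_name := as.vector(m)
  )
}

#' Plot an activation map
#'
#' @param object A `fus_activation_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.fus_activation_map <- function(object, ...) {
  df <- map_to_df(object$values, "pct_cbv")
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$pct_cbv)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "%CBV", na.value = "grey90") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("Activation map (%d trial%s)",
                                  object$n_trials,
                                  if (object$n_trials > 1) "s" else ""),
                  x = "lateral (px)", y = "depth (px)") +
    ggplot2::theme_minimal()
}

#' Plot a preference map
#'
#' @param object A `fus_preference_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.fus_preference_map <- function(object, ...) {
  df <- map_to_df(object$center, "center")
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$center)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(option = "turbo", na.value = "grey90",
                                  name = "preference") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "lateral (px)", y = "depth (px)") +
    ggplot2::theme_minimal()
}

#' Plot an OD map
#'
#' @param object A `fus_od_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.fus_od_map <- function(object, ...) {
  df <- map_to_df(object$od_index, "od_index")
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$od_index)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "blue", high = "red",
                                  na.value = "grey90", name = "OD index") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste0("OD map (", object$provenance, ")"),
                  x = "lateral (px)", y = "depth (px)") +
    ggplot2::theme_minimal()
}

#' Plot a reliability curve with its Naka-Rushton fit
#'
#' @param object A `fus_reliability` tibble.
#' @param fit Optional `fus_naka_rushton` fit to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.fus_reliability <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(.data$n_averaged,
                                    .data$proportion_correct)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "trials averaged",
                  y = "proportion of pixels correctly classified") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    nn <- seq(min(object$n_averaged), max(object$n_averaged),
              length.out = 200)
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(n_averaged = nn,
                            proportion_correct = predict(fit, nn)),
      colour = "black", linewidth = 1)
  }
  p
}

#' Plot a laminar OD profile
#'
#' @param object A `fus_layer_profile`.
#' @param extrema Optional [find_extrema()] result to mark.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.fus_layer_profile <- function(object, extrema = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$distance)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$od_raw),
                        alpha = 0.4, size = 0.7) +
    ggplot2::geom_line(ggplot2::aes(y = .data$od_fit)) +
    ggplot2::labs(x = "distance along layer (um)", y = "OD index") +
    ggplot2::theme_minimal()
  if (!is.null(extrema)) {
    if (nrow(extrema$maxima)) {
      p <- p + ggplot2::geom_point(
        data = extrema$maxima,
        ggplot2::aes(.data$distance, .data$value), colour = "red")
    }
    if (nrow(extrema$minima)) {
      p <- p + ggplot2::geom_point(
        data = extrema$minima,
        ggplot2::aes(.data$distance, .data$value), colour = "blue")
    }
  }
  p
}

#' Plot a spatial-frequency spectrum
#'
#' @param object A `fus_spectrum`.
#' @param band Band to shade (um^-1); default the classical OD band.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.fus_spectrum <- function(object, band = od_band(), ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$frequency,
                                       .data$magnitude)) +
    ggplot2::annotate("rect", xmin = band[1], xmax = band[2],
                      ymin = 0, ymax = 1, alpha = 0.15) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "spatial frequency (1/um)",
                  y = "normalized magnitude") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @importFrom rlang .data
#' @export
ggplot2::autoplot
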