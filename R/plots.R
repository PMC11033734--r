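#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a reconstructed or rasterized image
#'
#' @param object An [image_grid()].
#' @param ... Unused.
#' @return A ggplot raster of the image on `[-R, R]^2` (y upward).
#' @method autoplot image_grid
#' @export
autoplot.image_grid <- function(object, ...) {
  df <- expand.grid(y = object$xs, x = object$xs)
  df$value <- as.vector(object$values)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x", y = "y", fill = "u")
}

#' Plot detector-domain data
#'
#' @param object A `detector_data`.
#' @param ... Unused.
#' @return A ggplot raster, channels horizontal and time/radius vertical.
#' @method autoplot detector_data
#' @export
autoplot.detector_data <- function(object, ...) {
  df <- expand.grid(channel = seq_len(nrow(object$values)),
                    t = object$grid$times)
  df$value <- as.vector(object$values)
  ggplot2::ggplot(df, ggplot2::aes(.data$channel, .data$t,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "channel", y = if (object$kind == "circular_means")
      "radius" else "time", fill = object$kind)
}

#' Plot the improvement trace of a design search
#'
#' @param object A `design_result`.
#' @param ... Unused.
#' @return A ggplot step curve of the best injectivity number by iteration.
#' @method autoplot design_result
#' @export
autoplot.design_result <- function(object, ...) {
  tr <- object$improvement_trace
  if (nrow(tr) == 0) {
    tr <- tibble::tibble(iteration = c(0, object$iterations_run), sin = 0)
  } else {
    tr <- dplyr::bind_rows(
      tibble::tibble(iteration = 0, sin = 0), tr,
      tibble::tibble(iteration = object$iterations_run,
                     sin = max(tr$sin)))
  }
  ggplot2::ggplot(tr, ggplot2::aes(.data$iteration, .data$sin)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "iteration", y = "best s-sparse injectivity number")
}

#' Plot a compression sweep
#'
#' @param sweep A tibble from [compression_sweep()].
#' @return A ggplot of best injectivity number against measurements per
#'   group, non-singular designs highlighted.
#' @export
plot_compression_sweep <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(.data$m0, .data$best_sin,
                                      color = .data$nonsingular)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(ggplot2::aes(group = 1), color = "grey50") +
    ggplot2::labs(x = "measurements per group",
                  y = "best s-sparse injectivity number",
                  color = "non-singular")
}
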