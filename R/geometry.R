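#' Circular detector geometry
#'
#' Detectors sit on a circle of radius `R` at angles `Omega * (j - 1) / n`,
#' counterclockwise from angle 0, for `j = 1..n`. The imaged source is
#' assumed to be supported inside this circle. Sound speed is rescaled to 1
#' throughout, so times and lengths share units.
#'
#' @param R Detection-circle radius (default 1).
#' @param n Number of detectors (default 64, the instrument's array size).
#' @param Omega Angular coverage in radians, `0 < Omega <= 2*pi`
#'   (default full ring).
#' @return An object of class `sensor_geometry` with fields `R`, `n`,
#'   `Omega`, and an `n x 2` matrix `positions`.
#' @export
sensor_geometry <- function(R = 1, n = 64, Omega = 2 * pi) {
  stopifnot(R > 0, n >= 1, n == round(n), Omega > 0, Omega <= 2 * pi + 1e-12)
  ang <- Omega * (seq_len(n) - 1) / n
  structure(
    list(R = R, n = as.integer(n), Omega = Omega,
         angles = ang,
         positions = cbind(x = R * cos(ang), y = R * sin(ang))),
    class = "sensor_geometry"
  )
}

#' @export
print.sensor_geometry <- function(x, ...) {
  cat(sprintf("<sensor_geometry> R=%g, n=%d, Omega=%.4g rad\n",
              x$R, x$n, x$Omega))
  invisible(x)
}

#' Uniform time (or radius) grid
#'
#' Samples `t_l = 2 R (l - 1) / (q - 1)` for `l = 1..q`, covering `[0, 2R]`:
#' with unit sound speed and sources inside the detection circle, all signal
#' arrives by `t = 2R`. The same grid doubles as the radius grid of the
#' circular means.
#'
#' @param R Detection-circle radius.
#' @param q Number of samples (>= 2).
#' @return An object of class `time_grid` with fields `q`, `R`, `times`,
#'   `dt`.
#' @export
time_grid <- function(R = 1, q = 1024) {
  stopifnot(R > 0, q >= 2, q == round(q))
  t <- 2 * R * (seq_len(q) - 1) / (q - 1)
  structure(list(q = as.integer(q), R = R, times = t, dt = t[2] - t[1]),
            class = "time_grid")
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("<time_grid> q=%d on [0, %g], dt=%.4g\n", x$q, 2 * x$R, x$dt))
  invisible(x)
}

#' Square reconstruction grid
#'
#' Pixel centers of an `Nr x Nr` raster of the square `[-R, R]^2`, symmetric
#' about the origin. Rows index `y` (increasing upward), columns index `x`.
#'
#' @param R Half-width of the square (the detection-circle radius).
#' @param Nr Samples per axis (>= 2).
#' @param values Optional `Nr x Nr` matrix of pixel values (defaults to 0).
#' @return An object of class `image_grid` with fields `Nr`, `R`, `xs`
#'   (pixel-center coordinates, shared by both axes), `values`, and the
#'   pixel area `pixel_area`.
#' @export
image_grid <- function(R = 1, Nr = 128, values = NULL) {
  stopifnot(R > 0, Nr >= 2, Nr == round(Nr))
  h <- 2 * R / Nr
  xs <- -R + h * (seq_len(Nr) - 0.5)
  if (is.null(values)) values <- matrix(0, Nr, Nr)
  stopifnot(identical(dim(values), c(as.integer(Nr), as.integer(Nr))))
  structure(list(Nr = as.integer(Nr), R = R, xs = xs, values = values,
                 pixel_area = h^2),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid> %d x %d on [-%g, %g]^2, value range [%.4g, %.4g]\n",
              x$Nr, x$Nr, x$R, x$R, min(x$values), max(x$values)))
  invisible(x)
}

#' Detector count required by Shannon sampling
#'
#' For an `Nr x Nr` target raster of `[-R, R]^2`, stable full sampling of a
#' circular-geometry measurement requires `round(pi * Nr / 2)` equally spaced
#' detectors on the full ring. Arrays below this count (such as 64 detectors
#' against a 128-pixel raster, which would need 201) are spatially
#' undersampled; compressed sensing targets exactly this regime.
#'
#' @param Nr Raster size per axis (nonnegative integer).
#' @return The required detector count, `round(pi * Nr / 2)`.
#' @examples
#' nyquist_sensor_count(128)  # 201
#' @export
nyquist_sensor_count <- function(Nr) {
  stopifnot(length(Nr) == 1, Nr >= 0, Nr == round(Nr))
  as.integer(round(pi * Nr / 2))
}

#' Is a sensor count undersampled for a target resolution?
#'
#' @param n Available detector count.
#' @param Nr Target raster size per axis.
#' @return `TRUE` when `n` falls short of [nyquist_sensor_count()].
#' @export
is_undersampled <- function(n, Nr) n < nyquist_sensor_count(Nr)
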