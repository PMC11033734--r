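#' Disk phantom
#'
#' A phantom is a tibble of disks, one row per disk, with columns `x`, `y`
#' (center), `radius`, `amplitude`, `profile` (`"uniform"`, `"taper"` or
#' `"flat_means"`) and `kappa` (taper exponent, ignored otherwise). A
#' uniform disk has constant value `amplitude` inside its radius; a tapered
#' disk has the radially decaying profile
#' `amplitude * (1 - (rho/radius)^2)^kappa`, continuous at the rim; a
#' `"flat_means"` disk has the density
#' `amplitude * (1 - (rho/radius)^2)^(-1/2)`, whose integral along any
#' straight chord is the constant `pi * radius * amplitude` — so, for disks
#' small against the detection circle, its circular means are nearly
#' piecewise constant across sensors and radii: the detector-domain
#' signature is an indicator plateau with two jumps, the signal class that
#' total-variation recovery handles exactly. Every disk must lie strictly
#' inside the detection circle of radius `R` (the support condition of the
#' circular measurement geometry).
#'
#' @param x,y,radius,amplitude Numeric vectors (recycled to a common
#'   length).
#' @param profile Character, `"uniform"` or `"taper"`.
#' @param kappa Taper exponent (> 0); only used by `"taper"` disks.
#' @param R Detection-circle radius the phantom must fit inside.
#' @return A tibble of class `disk_phantom` with attribute `R`.
#' @examples
#' disk_phantom(x = c(0, 0.3), y = c(0, -0.2), radius = c(0.2, 0.1),
#'              amplitude = c(1, 0.5))
#' @export
disk_phantom <- function(x = numeric(0), y = numeric(0),
                         radius = numeric(0), amplitude = numeric(0),
                         profile = "uniform", kappa = 2, R = 1) {
  ph <- tibble::tibble(x = x, y = y, radius = radius, amplitude = amplitude,
                       profile = profile, kappa = kappa)
  if (nrow(ph)) {
    stopifnot(all(ph$radius > 0),
              all(ph$profile %in% c("uniform", "taper", "flat_means")),
              all(ph$kappa > 0))
    outside <- sqrt(ph$x^2 + ph$y^2) + ph$radius >= R
    if (any(outside)) {
      stop("disk(s) ", paste(which(outside), collapse = ", "),
           " not strictly inside the detection circle of radius ", R,
           call. = FALSE)
    }
  }
  structure(ph, class = c("disk_phantom", class(ph)), R = R)
}

#' Evaluate a phantom at points
#'
#' Superposition of all disk profiles at arbitrary coordinates.
#'
#' @param phantom A [disk_phantom()].
#' @param px,py Coordinate vectors of equal length.
#' @return Numeric vector of source values.
#' @export
phantom_values <- function(phantom, px, py) {
  stopifnot(inherits(phantom, "disk_phantom"), length(px) == length(py))
  u <- numeric(length(px))
  for (i in seq_len(nrow(phantom))) {
    d2 <- (px - phantom$x[i])^2 + (py - phantom$y[i])^2
    a2 <- phantom$radius[i]^2
    inside <- d2 < a2
    if (phantom$profile[i] == "uniform") {
      u[inside] <- u[inside] + phantom$amplitude[i]
    } else if (phantom$profile[i] == "taper") {
      u[inside] <- u[inside] +
        phantom$amplitude[i] * (1 - d2[inside] / a2)^phantom$kappa[i]
    } else {
      # integrable rim singularity; clamp for point evaluation/rasters
      u[inside] <- u[inside] +
        phantom$amplitude[i] / sqrt(pmax(1 - d2[inside] / a2, 1e-4))
    }
  }
  u
}

#' Rasterize a phantom onto an image grid
#'
#' @param phantom A [disk_phantom()].
#' @param grid An [image_grid()]; defaults to a 128-pixel raster of the
#'   phantom's own circle.
#' @return The `image_grid` with `values` filled in (row = y, col = x).
#' @export
rasterize_phantom <- function(phantom, grid = NULL) {
  stopifnot(inherits(phantom, "disk_phantom"))
  if (is.null(grid)) grid <- image_grid(R = attr(phantom, "R"), Nr = 128)
  pts <- expand.grid(y = grid$xs, x = grid$xs)  # row-major over y
  vals <- phantom_values(phantom, pts$x, pts$y)
  grid$values <- matrix(vals, grid$Nr, grid$Nr)
  grid
}
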