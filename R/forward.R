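#' Detector-domain data container
#'
#' A sensors-by-samples array together with its geometry and grid. `kind`
#' records which domain the values live in: `"pressure"` (time samples of
#' the acoustic pressure at each detector), `"circular_means"` (averages of
#' the source over circles centered at the detectors, indexed by radius), or
#' `"transformed"` (the time-integrated pressure, i.e. the Abel transform of
#' the means).
#'
#' @param values Numeric `n x q` matrix (rows = sensors).
#' @param kind One of `"pressure"`, `"circular_means"`, `"transformed"`,
#'   `"cs"`.
#' @param geometry A [sensor_geometry()] (row count must match `n`, except
#'   for `kind = "cs"`, where rows are measurement channels).
#' @param grid A [time_grid()] (column count must match `q`).
#' @return An object of class `detector_data`.
#' @export
detector_data <- function(values, kind, geometry, grid) {
  kind <- match.arg(kind, c("pressure", "circular_means", "transformed", "cs"))
  values <- as.matrix(values)
  stopifnot(inherits(geometry, "sensor_geometry"), inherits(grid, "time_grid"),
            ncol(values) == grid$q)
  if (kind != "cs" && nrow(values) != geometry$n) {
    stop("row count ", nrow(values), " does not match sensor count ",
         geometry$n, call. = FALSE)
  }
  structure(list(values = values, kind = kind, geometry = geometry,
                 grid = grid),
            class = "detector_data")
}

#' @export
print.detector_data <- function(x, ...) {
  cat(sprintf("<detector_data:%s> %d x %d, range [%.4g, %.4g]\n",
              x$kind, nrow(x$values), ncol(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

# Arc fraction of the circle |p - s| = r lying inside a disk of radius a
# whose center is at distance d from s; returns the mean of the disk
# indicator over the circle. Vectorized over r.
.uniform_disk_mean <- function(d, a, r) {
  out <- numeric(length(r))
  full <- r <= a - d          # circle entirely inside the disk (d < a)
  out[full] <- 1
  partial <- r > abs(d - a) & r < d + a
  if (any(partial)) {
    rp <- r[partial]
    cosa <- (d^2 + rp^2 - a^2) / (2 * d * rp)
    out[partial] <- acos(pmin(1, pmax(-1, cosa))) / pi
  }
  out
}

#' Circular means of a disk phantom
#'
#' Entry `(j, l)` is the average of the source over the circle of radius
#' `t_l` centered at detector `j`. Uniform disks use the closed-form arc
#' fraction; tapered disks are integrated by Gauss-Legendre quadrature over
#' the arc inside the disk. Radius 0 is the point value of the source at the
#' detector. Contributions of multiple disks add.
#'
#' @param phantom A [disk_phantom()].
#' @param geometry A [sensor_geometry()].
#' @param grid A [time_grid()] interpreted as radii.
#' @param quad_order Quadrature order for tapered disks (default 48).
#' @return A `detector_data` of kind `"circular_means"`.
#' @export
circular_means <- function(phantom, geometry, grid, quad_order = 48) {
  stopifnot(inherits(phantom, "disk_phantom"),
            inherits(geometry, "sensor_geometry"),
            inherits(grid, "time_grid"))
  n <- geometry$n
  r <- grid$times
  V <- matrix(0, n, grid$q)
  if (nrow(phantom) == 0) {
    return(detector_data(V, "circular_means", geometry, grid))
  }
  gl <- pracma::gaussLegendre(quad_order, 0, 1)
  gl2 <- pracma::gaussLegendre(2 * quad_order, 0, 1)  # edge-singular case
  for (i in seq_len(nrow(phantom))) {
    a <- phantom$radius[i]
    amp <- phantom$amplitude[i]
    dx <- geometry$positions[, 1] - phantom$x[i]
    dy <- geometry$positions[, 2] - phantom$y[i]
    dd <- sqrt(dx^2 + dy^2)   # sensor-to-center distances (all > a)
    for (j in seq_len(n)) {
      d <- dd[j]
      if (phantom$profile[i] == "uniform") {
        V[j, ] <- V[j, ] + amp * .uniform_disk_mean(d, a, r)
      } else if (phantom$profile[i] == "flat_means") {
        # density amp / sqrt(1 - rho^2/a^2): the theta integrand has an
        # integrable inverse-square-root singularity at the arc edge
        # theta_max; theta = theta_max (1 - v^2) removes it
        hit <- r > d - a & r < d + a
        if (any(hit)) {
          rh <- r[hit]
          cosmax <- pmin(1, pmax(-1, (d^2 + rh^2 - a^2) / (2 * d * rh)))
          thmax <- acos(cosmax)
          acc <- numeric(length(rh))
          for (k in seq_len(2 * quad_order)) {
            v <- gl2$x[k]
            th <- thmax * (1 - v^2)
            rho2 <- d^2 + rh^2 - 2 * d * rh * cos(th)
            f <- 1 / sqrt(pmax(1 - rho2 / a^2, 1e-14))
            acc <- acc + gl2$w[k] * 2 * v * thmax * f
          }
          V[j, hit] <- V[j, hit] + amp * acc / pi
        }
      } else {
        # mean over the circle: (1/pi) * int_0^thetamax f(rho(theta)) dtheta,
        # rho^2 = d^2 + r^2 - 2 d r cos(theta); integrand vanishes outside
        # theta < thetamax where rho = a
        hit <- r > d - a & r < d + a
        if (any(hit)) {
          rh <- r[hit]
          cosmax <- pmin(1, pmax(-1, (d^2 + rh^2 - a^2) / (2 * d * rh)))
          thmax <- acos(cosmax)
          acc <- numeric(length(rh))
          for (k in seq_len(quad_order)) {
            th <- thmax * gl$x[k]
            rho2 <- d^2 + rh^2 - 2 * d * rh * cos(th)
            f <- pmax(0, 1 - rho2 / a^2)^phantom$kappa[i]
            acc <- acc + gl$w[k] * thmax * f
          }
          V[j, hit] <- V[j, hit] + amp * acc / pi
        }
      }
    }
  }
  # radius 0: point evaluation at the sensor (zero here since disks are
  # strictly inside the ring, but keep it exact)
  V[, 1] <- phantom_values(phantom, geometry$positions[, 1],
                           geometry$positions[, 2])
  detector_data(V, "circular_means", geometry, grid)
}

#' Discrete Abel-transform matrix
#'
#' Lower-triangular matrix `L` with `(L m)(t) ~ int_0^t r m(r) /
#' sqrt(t^2 - r^2) dr` on a uniform grid, built by product integration:
#' `m` is interpolated linearly between grid nodes and the weakly singular
#' kernel `r / sqrt(t^2 - r^2)` is integrated against each linear piece in
#' closed form (antiderivatives `-sqrt(t^2 - r^2)` and
#' `(t^2 asin(r/t) - r sqrt(t^2 - r^2)) / 2`). The singular end panel is
#' thereby handled exactly, which keeps the diagonal well scaled and makes
#' the forward-substitution inverse stable. Cached per grid within a
#' session.
#'
#' @param grid A [time_grid()].
#' @return A dense lower-triangular `q x q` matrix.
#' @export
abel_matrix <- function(grid) {
  stopifnot(inherits(grid, "time_grid"))
  key <- sprintf("q%d_R%.12g", grid$q, grid$R)
  cached <- .abel_cache[[key]]
  if (!is.null(cached)) return(cached)
  q <- grid$q
  t <- grid$times
  dt <- grid$dt
  # node matrices over (row l = upper limit t_l, col i = grid node r_i),
  # clamped at r = t so entries above the diagonal are inert
  ratio <- outer(1 / pmax(t, dt * 1e-12), t)      # r_i / t_l
  ratio <- pmin(ratio, 1)
  root <- sweep(sqrt(1 - ratio^2), 1, t, `*`)     # sqrt(t^2 - r^2)
  S <- sweep(asin(ratio), 1, t^2 / 2, `*`) -
    sweep(ratio * root, 1, t, `*`) / 2            # int r^2/sqrt kernel
  # per-panel integrals I0, I1 on [r_i, r_{i+1}] for i = 1..q-1
  I0 <- root[, -q, drop = FALSE] - root[, -1, drop = FALSE]
  I1 <- S[, -1, drop = FALSE] - S[, -q, drop = FALSE]
  # linear-interpolation weights: panel i contributes
  #   (r_{i+1} I0 - I1)/dt to node i and (I1 - r_i I0)/dt to node i+1
  WL <- (sweep(I0, 2, t[-1], `*`) - I1) / dt
  WR <- (I1 - sweep(I0, 2, t[-q], `*`)) / dt
  L <- matrix(0, q, q)
  L[, -q] <- WL
  L[, -1] <- L[, -1] + WR
  # keep strictly lower-triangular + diagonal; clamping makes upper
  # entries zero already, but enforce exactly
  L[upper.tri(L)] <- 0
  L[1, ] <- 0
  assign(key, L, envir = .abel_cache)
  L
}

.abel_cache <- new.env(parent = emptyenv())

#' Abel transform of circular means
#'
#' Per sensor, `g(t) = int_0^t r m(r) / sqrt(t^2 - r^2) dr`, the
#' time-integrated pressure of the 2D wave solution; `g(0) = 0`.
#'
#' @param means A `detector_data` of kind `"circular_means"` on a uniform
#'   radius grid starting at 0.
#' @return A `detector_data` of kind `"transformed"`.
#' @export
abel_forward <- function(means) {
  stopifnot(inherits(means, "detector_data"))
  if (means$kind != "circular_means") {
    stop("abel_forward expects circular_means data", call. = FALSE)
  }
  L <- abel_matrix(means$grid)
  G <- means$values %*% t(L)
  detector_data(G, "transformed", means$geometry, means$grid)
}

#' Inverse Abel transform
#'
#' Solves the discretized lower-triangular system of [abel_forward()] by
#' forward substitution, so `abel_inverse(abel_forward(m))` reproduces `m`
#' up to discretization error. The value at radius 0 (where the transform
#' carries no information) is filled by quadratic extrapolation.
#'
#' @param g A `detector_data` of kind `"transformed"` with `g(0) = 0`.
#' @return A `detector_data` of kind `"circular_means"`.
#' @export
abel_inverse <- function(g) {
  stopifnot(inherits(g, "detector_data"))
  if (g$kind != "transformed") {
    stop("abel_inverse expects transformed data", call. = FALSE)
  }
  out <- .abel_inverse_matrix(g$values, g$grid)
  d <- g
  d$values <- out
  d$kind <- "circular_means"
  d
}

.abel_inverse_matrix <- function(values, grid) {
  L <- abel_matrix(grid)
  Lsub <- L[-1, -1, drop = FALSE]
  # the r = 0 node is not an unknown of the triangular system (row 1 of L is
  # zero); close it with the constant extrapolation m_1 = m_2, which folds
  # its column into the m_2 column and keeps the system lower triangular
  c1 <- L[-1, 1]
  Lsub[, 1] <- Lsub[, 1] + c1
  if (any(abs(diag(Lsub)) < 1e-14)) {
    stop("degenerate grid: singular diagonal in the Abel system",
         call. = FALSE)
  }
  M <- forwardsolve(Lsub, t(values[, -1, drop = FALSE]))
  out <- cbind(0, t(M))
  out[, 1] <- 2 * out[, 2] - out[, 3]
  out
}

# central differences in time; one-sided second order at the ends
.time_derivative <- function(values, dt) {
  q <- ncol(values)
  if (q < 3) stop("need at least 3 time samples", call. = FALSE)
  d <- values
  d[, 2:(q - 1)] <- (values[, 3:q] - values[, 1:(q - 2)]) / (2 * dt)
  d[, 1] <- (-3 * values[, 1] + 4 * values[, 2] - values[, 3]) / (2 * dt)
  d[, q] <- (3 * values[, q] - 4 * values[, q - 1] + values[, q - 2]) / (2 * dt)
  d
}

#' Pressure from circular means
#'
#' The acoustic pressure of the 2D wave equation driven by an impulsive
#' (time-derivative delta) source equals the time derivative of the Abel
#' transform of the circular means: `p = d/dt abel_forward(m)`. Central
#' differences on the uniform grid, one-sided at the ends.
#'
#' @param means A `detector_data` of kind `"circular_means"`.
#' @return A `detector_data` of kind `"pressure"`.
#' @export
pressure_from_means <- function(means) {
  g <- abel_forward(means)
  detector_data(.time_derivative(g$values, g$grid$dt), "pressure",
                means$geometry, means$grid)
}

#' Full forward model: phantom to pressure
#'
#' Composition of [circular_means()] and [pressure_from_means()]; linear in
#' the phantom amplitudes.
#'
#' @inheritParams circular_means
#' @return A `detector_data` of kind `"pressure"`.
#' @export
forward_pressure <- function(phantom, geometry, grid) {
  pressure_from_means(circular_means(phantom, geometry, grid))
}
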