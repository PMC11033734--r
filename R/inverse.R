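#' Temporal filter: pressure to circular means
#'
#' The two-step method's temporal transform: cumulative trapezoidal
#' integration of the pressure in time (recovering the Abel-transformed
#' means, with `g(0) = 0` enforced) followed by [abel_inverse()]. Acts per
#' channel in the time variable only, so it commutes exactly with any
#' sensor-mixing matrix.
#'
#' @param pressure A `detector_data` of kind `"pressure"` (or `"cs"` for
#'   compressed channels) on a uniform time grid.
#' @return A `detector_data` of kind `"circular_means"` (kind `"cs"` input
#'   keeps kind `"cs"`, since compressed channels are mixtures of
#'   per-sensor means).
#' @export
apply_phi <- function(pressure) {
  stopifnot(inherits(pressure, "detector_data"))
  if (!pressure$kind %in% c("pressure", "cs")) {
    stop("apply_phi expects pressure (or cs) data", call. = FALSE)
  }
  P <- pressure$values
  dt <- pressure$grid$dt
  # cumulative trapezoid with g(0) = 0
  avg <- (P[, -1, drop = FALSE] + P[, -ncol(P), drop = FALSE]) / 2 * dt
  G <- cbind(0, t(apply(avg, 1, cumsum)))
  M <- .abel_inverse_matrix(G, pressure$grid)
  out <- pressure
  out$values <- M
  out$kind <- if (pressure$kind == "cs") "cs" else "circular_means"
  for (a in c("matrix", "source_kind")) attr(out, a) <- attr(pressure, a)
  if (pressure$kind == "cs") attr(out, "source_kind") <- "circular_means"
  out
}

# q x q filter matrix for the exact circular-mean inversion: row l holds the
# product-integration weights of I(d_l) = int_0^{2R} w(r) log|r^2 - d_l^2| dr
# against grid samples of w (piecewise linear), using the split
# log|r^2-d^2| = log|r-d| + log(r+d) and the exact antiderivatives of
# u log|u| against linear pieces.
.log_kernel_matrix <- function(grid) {
  key <- sprintf("logk_q%d_R%.12g", grid$q, grid$R)
  cached <- .abel_cache[[key]]
  if (!is.null(cached)) return(cached)
  q <- grid$q
  r <- grid$times
  dt <- grid$dt
  A0 <- function(u) ifelse(u == 0, 0, u * log(abs(u)) - u)
  A1 <- function(u) ifelse(u == 0, 0, u^2 / 2 * log(abs(u)) - u^2 / 4)
  K <- matrix(0, q, q)
  d <- r
  # panel [r_i, r_{i+1}]; hat parts (alpha + beta r) for nodes i and i+1
  for (i in seq_len(q - 1)) {
    a <- r[i]; b <- r[i + 1]
    for (part in 1:2) {
      if (part == 1) { alpha <- b / dt; beta <- -1 / dt; node <- i }
      else           { alpha <- -a / dt; beta <- 1 / dt; node <- i + 1 }
      Im <- (alpha + beta * d) * (A0(b - d) - A0(a - d)) +
        beta * (A1(b - d) - A1(a - d))
      Ip <- (alpha - beta * d) * (A0(b + d) - A0(a + d)) +
        beta * (A1(b + d) - A1(a + d))
      K[, node] <- K[, node] + Im + Ip
    }
  }
  assign(key, K, envir = .abel_cache)
  K
}

# backproject per-sensor distance profiles FF (n x q, indexed by d = t_l)
# onto the image grid with linear interpolation in d; profiles are zero
# (or clamped) beyond the last sample
.backproject <- function(FF, geometry, grid, grid_out, clamp_beyond = TRUE) {
  Nr <- grid_out$Nr
  q <- grid$q
  dt <- grid$dt
  px <- rep(grid_out$xs, each = Nr)    # column-major: row = y index
  py <- rep(grid_out$xs, times = Nr)
  u <- numeric(Nr * Nr)
  for (j in seq_len(geometry$n)) {
    d <- sqrt((px - geometry$positions[j, 1])^2 +
                (py - geometry$positions[j, 2])^2)
    if (clamp_beyond) d <- pmin(d, 2 * grid$R)
    idx <- pmin(pmax(floor(d / dt) + 1L, 1L), q - 1L)
    frac <- pmin(pmax(d / dt - (idx - 1L), 0), 1)
    u <- u + (1 - frac) * FF[j, idx] + frac * FF[j, idx + 1L]
  }
  matrix(u, Nr, Nr)
}

# exact inversion of circular means on the full ring:
# u(x) = (1/(2 pi R)) * sum_j arc_j * I_j(|x - s_j|),
# I(d) = int_0^{2R} (d/dr (r d/dr m)) log|r^2 - d^2| dr
.means_reconstruct <- function(means, grid_out) {
  geom <- means$geometry
  tg <- means$grid
  dm <- .time_derivative(means$values, tg$dt)
  w <- .time_derivative(sweep(dm, 2, tg$times, `*`), tg$dt)
  K <- .log_kernel_matrix(tg)
  FF <- w %*% t(K)
  vals <- .backproject(FF, geom, tg, grid_out) / geom$n
  grid_out$values <- vals * (geom$Omega / (2 * pi))
  grid_out
}

#' Filtered backprojection reconstruction
#'
#' Inverts full-ring pressure data in two stages, both acting on the
#' detector-domain arrays: the temporal filter of [apply_phi()] (time
#' integration followed by Abel inversion, recovering the circular means)
#' and the exact filtered-backprojection inversion of the circular-mean
#' transform,
#' `u(x) = (1/(2 pi R)) * sum_j (2 pi R / n) * I_j(|x - s_j|)` with
#' `I(d) = int_0^{2R} (d/dr (r d/dr m))(r) log|r^2 - d^2| dr`.
#' The log-kernel integral is product-integrated exactly against a
#' piecewise-linear interpolant, so the reconstruction is quantitatively
#' accurate (not just adjoint-like backprojection). Quantitative use
#' assumes full-ring coverage (`Omega = 2*pi`).
#'
#' @param pressure A `detector_data` of kind `"pressure"`.
#' @param grid_out An [image_grid()]; must not extend beyond the detection
#'   square `[-R, R]^2`. Defaults to a 128-pixel raster.
#' @return The `image_grid` with reconstructed `values`.
#' @export
fbp <- function(pressure, grid_out = NULL) {
  stopifnot(inherits(pressure, "detector_data"))
  if (pressure$kind != "pressure") {
    stop("fbp expects pressure data", call. = FALSE)
  }
  geom <- pressure$geometry
  if (is.null(grid_out)) grid_out <- image_grid(R = geom$R, Nr = 128)
  if (grid_out$R > geom$R + 1e-12) {
    stop("image grid [-", grid_out$R, ", ", grid_out$R,
         "]^2 exceeds the detection square of radius ", geom$R,
         call. = FALSE)
  }
  .means_reconstruct(apply_phi(pressure), grid_out)
}

#' Filtered backprojection from circular means
#'
#' Second stage of the two-step method, taking (recovered) circular means
#' directly to an image through the exact log-kernel inversion — the same
#' operator [fbp()] applies after its temporal filter. Starting from the
#' means skips the derivative/integration round trip of the pressure path,
#' so `fbp_from_means(m)` and `fbp(pressure_from_means(m))` agree up to
#' (not to machine precision, but within) the temporal discretization
#' error of that round trip.
#'
#' @param means A `detector_data` of kind `"circular_means"`.
#' @inheritParams fbp
#' @return An [image_grid()].
#' @export
fbp_from_means <- function(means, grid_out = NULL) {
  stopifnot(inherits(means, "detector_data"),
            means$kind == "circular_means")
  geom <- means$geometry
  if (is.null(grid_out)) grid_out <- image_grid(R = geom$R, Nr = 128)
  if (grid_out$R > geom$R + 1e-12) {
    stop("image grid [-", grid_out$R, ", ", grid_out$R,
         "]^2 exceeds the detection square of radius ", geom$R,
         call. = FALSE)
  }
  .means_reconstruct(means, grid_out)
}

# q x q matrix for J(d_l) = int_{d_l}^{2R} h(t) / sqrt(t^2 - d_l^2) dt with
# piecewise-linear h, by product integration (antiderivatives
# log(t + sqrt(t^2-d^2)) and sqrt(t^2-d^2)); used by the adjoint.
.sqrt_kernel_matrix <- function(grid) {
  key <- sprintf("sqrtk_q%d_R%.12g", grid$q, grid$R)
  cached <- .abel_cache[[key]]
  if (!is.null(cached)) return(cached)
  q <- grid$q
  t <- grid$times
  dt <- grid$dt
  B <- matrix(0, q, q)
  d <- t
  for (i in seq_len(q - 1)) {
    a <- pmax(t[i], d); b <- pmax(t[i + 1], d)   # clamp panels below d
    ra <- sqrt(pmax(0, a^2 - d^2)); rb <- sqrt(pmax(0, b^2 - d^2))
    F0a <- log(a + ra); F0b <- log(b + rb)        # d > 0 rows only
    for (part in 1:2) {
      if (part == 1) { alpha <- t[i + 1] / dt; beta <- -1 / dt; node <- i }
      else           { alpha <- -t[i] / dt; beta <- 1 / dt; node <- i + 1 }
      B[, node] <- B[, node] + alpha * (F0b - F0a) + beta * (rb - ra)
    }
  }
  B[1, ] <- B[2, ]    # d = 0 row: log singularity; copy the d = dt row
  B[!is.finite(B)] <- 0
  assign(key, B, envir = .abel_cache)
  B
}

#' Adjoint of the forward operator
#'
#' The L2 adjoint of the phantom-to-pressure map (with data recorded on the
#' finite window `[0, 2R]`) with respect to the plain data inner product
#' `sum p1 p2 * dt * arc` and image inner product `sum u1 u2 * pixel_area`:
#' `(W* p)(x) = (1/(2 pi)) * sum_j arc_j * [ p_j(2R) / sqrt(4R^2 - d^2)
#' - J_j(d) ]` with `J(d) = int_d^{2R} (dp/dt)(t) / sqrt(t^2 - d^2) dt` and
#' `d = |x - s_j|`. The first term is the time-boundary contribution: in 2D
#' there is no Huygens principle, the pressure has a persistent tail, and
#' the record truncated at `t = 2R` ends on nonzero values.
#'
#' Unlike [fbp()] this is not an inversion; it is the operator whose
#' inner-product identity `<W u, p> = <u, W* p>` holds for arbitrary `p`,
#' which is what makes iterative schemes and consistency checks on the
#' forward model possible.
#'
#' @inheritParams fbp
#' @return An [image_grid()] holding `W* p`.
#' @export
forward_adjoint <- function(pressure, grid_out = NULL) {
  stopifnot(inherits(pressure, "detector_data"),
            pressure$kind == "pressure")
  geom <- pressure$geometry
  if (is.null(grid_out)) grid_out <- image_grid(R = geom$R, Nr = 128)
  tg <- pressure$grid
  dp <- .time_derivative(pressure$values, tg$dt)
  B <- .sqrt_kernel_matrix(tg)
  J <- dp %*% t(B)
  # time-boundary term; the inverse square root is clamped two samples
  # short of d = 2R (pixels that close to double range sit outside the
  # detection circle)
  denom <- sqrt(pmax((2 * tg$R)^2 - tg$times^2, (2 * tg$dt)^2))
  FF <- outer(pressure$values[, tg$q], 1 / denom) - J
  arc <- geom$Omega * geom$R / geom$n
  grid_out$values <- arc / (2 * pi) * .backproject(FF, geom, tg, grid_out)
  grid_out
}
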