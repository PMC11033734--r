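#' Exhaustive-support sparse decoder
#'
#' Decodes an s-sparse vector from `y = M x` by trying every size-`s`
#' support, solving the least-squares restriction, and returning the
#' reconstruction with the smallest residual (first minimum wins on ties).
#' When the matrix has positive s-sparse injectivity number, the true
#' s-sparse signal is the unique s-sparse solution of exact data and the
#' decoder recovers it exactly; with zero injectivity number distinct
#' sparse signals share measurements and decoding must fail on some
#' inputs. Exponential in `s`; a certification tool, not a practical
#' reconstruction method.
#'
#' @param y Measurement vector (length `nrow(M)`) or matrix of columns.
#' @param M Measurement matrix.
#' @param s Sparsity level.
#' @return Decoded vector (or matrix of columns) of length `ncol(M)`.
#' @export
decode_sparse <- function(y, M, s) {
  M <- unclass(as.matrix(M))
  y <- as.matrix(y)
  stopifnot(nrow(y) == nrow(M), s >= 1, s <= ncol(M))
  supports <- utils::combn(ncol(M), s)
  # precompute pseudo-inverses per support
  pinvs <- vector("list", ncol(supports))
  ok <- logical(ncol(supports))
  for (j in seq_len(ncol(supports))) {
    Ms <- M[, supports[, j], drop = FALSE]
    sv <- svd(Ms)
    pos <- sv$d > 1e-10 * max(sv$d, 1)
    ok[j] <- all(pos)
    pinvs[[j]] <- sv$v[, pos, drop = FALSE] %*%
      (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  }
  out <- matrix(0, ncol(M), ncol(y))
  for (cidx in seq_len(ncol(y))) {
    yc <- y[, cidx]
    best <- Inf; best_x <- numeric(ncol(M))
    for (j in seq_len(ncol(supports))) {
      xs <- pinvs[[j]] %*% yc
      res <- sum((M[, supports[, j], drop = FALSE] %*% xs - yc)^2)
      if (res < best - 1e-14) {
        best <- res
        best_x <- numeric(ncol(M))
        best_x[supports[, j]] <- xs
      }
    }
    out[, cidx] <- best_x
  }
  if (ncol(y) == 1) drop(out) else out
}

#' Recover full transformed detector data from compressed measurements
#'
#' First step of the two-step reconstruction: the temporal filter
#' [apply_phi()] is applied to the compressed channels (legitimate because
#' the measurement matrix mixes sensors only and therefore commutes with
#' any temporal operation), then each radius sample is recovered by
#' TV-regularized inversion of the measurement matrix across the sensor
#' ring — one [tv_solve()] with all radius samples as columns.
#'
#' @param Y A `detector_data` of kind `"cs"`. If its source kind is
#'   `"pressure"`, the temporal filter is applied first; data already in
#'   the transformed (means) domain are used as is.
#' @param A The measurement matrix (defaults to the one attached to `Y`).
#' @param reg_weight TV regularization weight.
#' @param D Optional difference operator override (see
#'   [ring_difference()]).
#' @param ... Solver settings passed to [tv_problem()].
#' @return A `detector_data` of kind `"circular_means"` with the full
#'   sensor count; the `tv_fit` is attached as attribute `fit`.
#' @export
recover_transformed <- function(Y, A = NULL, reg_weight = 1e-3, D = NULL,
                                ...) {
  stopifnot(inherits(Y, "detector_data"), Y$kind == "cs")
  if (is.null(A)) A <- attr(Y, "matrix")
  if (is.null(A)) stop("no measurement matrix available", call. = FALSE)
  src <- attr(Y, "source_kind")
  Yt <- if (identical(src, "pressure")) apply_phi(Y) else Y
  fit <- tv_solve(tv_problem(A, Yt$values, reg_weight, D = D, ...))
  H <- as.matrix(fit$h)
  out <- detector_data(H, "circular_means", Y$geometry, Y$grid)
  attr(out, "fit") <- fit
  out
}

#' Two-step image reconstruction from compressed data
#'
#' [recover_transformed()] followed by [fbp_from_means()]: recover the full
#' circular means from the compressed channels by per-radius TV
#' minimization, then invert the means by filtered backprojection.
#' Deterministic given inputs and settings.
#'
#' @inheritParams recover_transformed
#' @param grid_out An [image_grid()] for the reconstruction.
#' @return An [image_grid()]; the recovered means are attached as
#'   attribute `recovered_means`.
#' @export
two_step_reconstruct <- function(Y, A = NULL, reg_weight = 1e-3,
                                 grid_out = NULL, D = NULL, ...) {
  H <- recover_transformed(Y, A = A, reg_weight = reg_weight, D = D, ...)
  img <- fbp_from_means(H, grid_out)
  attr(img, "recovered_means") <- H
  img
}
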