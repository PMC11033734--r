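#' Apply a compressed-sensing matrix to detector data
#'
#' Per time (or radius) sample, `y = A p`: the matrix mixes sensors only, so
#' it acts identically on pressure, transformed, or circular-mean data and
#' commutes exactly with any temporal operation.
#'
#' @param A A `block_diagonal_matrix` (or any numeric matrix whose column
#'   count equals the sensor count).
#' @param P A `detector_data`.
#' @return A `detector_data` of kind `"cs"` with `nrow(A)` channels; the
#'   matrix is attached as attribute `matrix`.
#' @export
apply_cs <- function(A, P) {
  stopifnot(inherits(P, "detector_data"))
  A <- as.matrix(A)
  if (ncol(A) != nrow(P$values)) {
    stop("matrix has ", ncol(A), " columns but data has ", nrow(P$values),
         " sensor rows", call. = FALSE)
  }
  out <- detector_data(unclass(A) %*% P$values, "cs", P$geometry, P$grid)
  attr(out, "matrix") <- A
  attr(out, "source_kind") <- P$kind
  out
}

#' Relative l2 error
#'
#' `||x - x_ref|| / ||x_ref||` over all entries; the error measure used for
#' data-domain, recovery-domain and image-domain comparisons alike.
#'
#' @param x Estimate (vector, matrix, `detector_data` or `image_grid`).
#' @param x_ref Reference of the same shape; must be nonzero.
#' @return Nonnegative scalar.
#' @export
relative_l2_error <- function(x, x_ref) {
  get_vals <- function(z) {
    if (inherits(z, "detector_data")) z$values
    else if (inherits(z, "image_grid")) z$values
    else as.numeric(z)
  }
  x <- get_vals(x); x_ref <- get_vals(x_ref)
  nref <- sqrt(sum(x_ref^2))
  if (nref == 0) stop("reference is identically zero", call. = FALSE)
  sqrt(sum((x - x_ref)^2)) / nref
}
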