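#' s-sparse injectivity number
#'
#' The s-sparse injectivity number of a matrix `M` is the largest constant
#' `Theta >= 0` with `||M x1 - M x2|| >= Theta ||x1 - x2||` for all s-sparse
#' `x1, x2`. Because any difference of two s-sparse vectors is supported on at
#' most `2s` coordinates, it equals the minimum over all `2s`-column subsets
#' `S` of the smallest singular value of `M[, S]`. It is strictly positive
#' exactly when `M` is injective on s-sparse vectors, so a positive value
#' certifies exact recoverability of s-sparse signals from exact data.
#'
#' The value is on the singular-value (norm-ratio) scale. Quality figures for
#' such designs are sometimes quoted on the squared scale, i.e. the smallest
#' eigenvalue of the submatrix Gram matrices; [glance.design_result()]
#' reports both scales for a completed search.
#'
#' The subset enumeration (`choose(ncol(M), 2s)` smallest-eigenvalue problems)
#' runs in compiled code. Two cheap exact shortcuts skip it: a matrix with any
#' all-zero column, or with fewer than `2s` nonzero columns, has injectivity
#' number 0 by definition.
#'
#' @param M Numeric matrix.
#' @param s Sparsity level (positive integer); requires `2 * s <= ncol(M)`.
#' @param early_exit Optional nonnegative number: stop the enumeration as soon
#'   as the running minimum falls to or below this value and return that
#'   (smaller-or-equal) minimum. Used by [search_design()] to discard
#'   candidates that cannot beat an incumbent; the default `NULL` computes the
#'   exact value.
#' @return A nonnegative scalar.
#' @examples
#' sparse_injectivity(diag(8), s = 2)  # orthonormal columns: 1
#' @export
sparse_injectivity <- function(M, s, early_exit = NULL) {
  M <- unclass(as.matrix(M))
  storage.mode(M) <- "double"
  if (length(s) != 1 || s < 1 || s != round(s)) {
    stop("s must be a positive integer", call. = FALSE)
  }
  k <- 2L * as.integer(s)
  if (k > ncol(M)) {
    stop(sprintf("2s = %d exceeds the number of columns (%d)", k, ncol(M)),
         call. = FALSE)
  }
  cn <- colSums(abs(M))
  if (any(cn == 0) || sum(cn > 0) < k) return(0)
  .sin_enum_cpp(M, k, if (is.null(early_exit)) -1.0 else as.numeric(early_exit))
}

#' Normalized injectivity diagnostic
#'
#' The injectivity number divided by the spectral norm of `M`; useful when
#' comparing matrices of different overall scale.
#'
#' @inheritParams sparse_injectivity
#' @return `sparse_injectivity(M, s) / ||M||_2` (0 for a zero matrix).
#' @export
sparse_injectivity_normalized <- function(M, s) {
  M <- unclass(as.matrix(M))
  nrm <- if (all(M == 0)) 0 else max(svd(M, nu = 0, nv = 0)$d)
  if (nrm == 0) return(0)
  sparse_injectivity(M, s) / nrm
}

#' Restricted isometry constant by support enumeration
#'
#' The restricted isometry constant of order `s` is the smallest `delta` with
#' `(1 - delta) ||x||^2 <= ||M x||^2 <= (1 + delta) ||x||^2` for all s-sparse
#' `x`. It is computed exactly as the maximum, over all size-`s` column
#' supports, of `max(1 - lambda_min, lambda_max - 1)` of the Gram matrix of
#' the column submatrix. Enumeration is exponential in the column count, so
#' the matrix is limited to 24 columns; this is a small-matrix diagnostic,
#' not an estimator.
#'
#' @inheritParams sparse_injectivity
#' @param s Order of the property, `1 <= s <= ncol(M)`.
#' @return The constant `delta_s >= 0`.
#' @export
rip_delta <- function(M, s) {
  M <- unclass(as.matrix(M))
  if (length(s) != 1 || s < 1 || s != round(s) || s > ncol(M)) {
    stop("s must be an integer in 1..ncol(M)", call. = FALSE)
  }
  if (ncol(M) > 24) {
    stop("support enumeration limited to matrices with <= 24 columns; ",
         "reduce the column count or s", call. = FALSE)
  }
  G <- crossprod(M)
  supports <- utils::combn(ncol(M), s)
  delta <- 0
  for (j in seq_len(ncol(supports))) {
    S <- supports[, j]
    ev <- eigen(G[S, S, drop = FALSE], symmetric = TRUE,
                only.values = TRUE)$values
    delta <- max(delta, max(ev) - 1, 1 - min(ev))
  }
  delta
}

#' Best s-term approximation error
#'
#' The l1 distance from `x` to the nearest s-sparse vector: the sum of the
#' magnitudes of all but the `s` largest-magnitude entries. Vectors for which
#' this decays quickly in `s` are the compressible signals that sparse
#' recovery targets.
#'
#' @param x Numeric vector.
#' @param s Number of retained entries, `0 <= s <= length(x)`.
#' @return A nonnegative scalar; 0 when `x` is s-sparse.
#' @export
best_s_term_error <- function(x, s) {
  stopifnot(is.numeric(x), length(s) == 1, s >= 0, s <= length(x),
            s == round(s))
  if (s == 0) return(sum(abs(x)))
  a <- sort(abs(x), decreasing = TRUE)
  sum(a[seq_along(a) > s])
}
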