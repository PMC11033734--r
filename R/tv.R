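#' First-difference (gradient) operator on the sensor ring
#'
#' Cyclic difference matrix used as the sparsifying transform of the TV
#' recovery: row `i` is `h[i+1] - h[i]`, wrapping at the end. With
#' `groups > 1` the ring is split into that many independent cyclic blocks
#' (an ablation variant where each sensor group is treated as its own
#' closed loop).
#'
#' @param n Number of sensors.
#' @param groups Number of independent cyclic blocks (default 1: one closed
#'   ring).
#' @return An `n x n` difference matrix.
#' @export
ring_difference <- function(n, groups = 1) {
  stopifnot(n >= 2, groups >= 1, n %% groups == 0)
  size <- n / groups
  one <- diag(-1, size)
  one[cbind(seq_len(size), c(seq_len(size - 1) + 1, 1))] <- 1
  D <- matrix(0, n, n)
  for (g in seq_len(groups)) {
    i <- (g - 1) * size + seq_len(size)
    D[i, i] <- one
  }
  D
}

#' Total-variation regularized recovery problem
#'
#' Bundles the measurement matrix, data, regularization weight and solver
#' settings of the per-sample recovery
#' `min_h 1/2 ||A h - y||_2^2 + mu ||D h||_1`, where `D` is the ring
#' difference operator. The l1 term favors signals that are piecewise
#' constant across the sensor ring, which is the structure the temporal
#' (Abel) filter produces from piecewise-smooth sources.
#'
#' @param A Measurement matrix (`m x n`).
#' @param y Data: length-`m` vector, or `m x k` matrix to solve `k`
#'   independent problems sharing `A`.
#' @param reg_weight Positive regularization weight `mu`.
#' @param D Optional difference operator (defaults to the full cyclic ring).
#' @param max_iter Iteration cap (default 2000).
#' @param tol Relative-change stopping tolerance (default 1e-8).
#' @param rho ADMM penalty parameter (default `max(reg_weight, 0.1)`).
#' @return An object of class `tv_problem`.
#' @export
tv_problem <- function(A, y, reg_weight, D = NULL, max_iter = 2000,
                       tol = 1e-8, rho = NULL) {
  A <- unclass(as.matrix(A))
  y <- as.matrix(y)
  stopifnot(nrow(y) == nrow(A), reg_weight > 0, max_iter >= 1, tol > 0)
  if (!all(is.finite(A)) || !all(is.finite(y))) {
    stop("non-finite entries in A or y", call. = FALSE)
  }
  if (is.null(D)) D <- ring_difference(ncol(A))
  stopifnot(ncol(D) == ncol(A))
  if (is.null(rho)) rho <- max(reg_weight, 0.1)
  structure(list(A = A, y = y, reg_weight = reg_weight, D = D,
                 max_iter = as.integer(max_iter), tol = tol, rho = rho),
            class = "tv_problem")
}

.soft_threshold <- function(x, k) sign(x) * pmax(abs(x) - k, 0)

#' Solve a TV recovery problem
#'
#' ADMM with the l1 term split out (`z = D h`): the `h` update is a single
#' pre-factorized linear solve, the `z` update a soft threshold. All columns
#' of a matrix-valued `y` are solved simultaneously against the shared
#' factorization. The reported iterate is the best (lowest-objective) one
#' visited, so the objective trace is nonincreasing by construction, and the
#' solver stops once the relative change of the iterate falls below `tol`.
#'
#' @param problem A [tv_problem()], or a matrix `A` (with `y`, `reg_weight`,
#'   `...` passed on to [tv_problem()]).
#' @param ... Further arguments to [tv_problem()] when `problem` is a
#'   matrix.
#' @return An object of class `tv_fit`: list with `h` (same shape as `y`'s
#'   unknowns: `n x k` or length-`n` vector), `objective` (per column, at
#'   the returned iterate), `trace` (total objective per outer iteration,
#'   nonincreasing), `iterations`, `converged`.
#' @export
tv_solve <- function(problem, ...) {
  if (!inherits(problem, "tv_problem")) problem <- tv_problem(problem, ...)
  A <- problem$A; y <- problem$y; mu <- problem$reg_weight
  D <- problem$D; rho <- problem$rho
  n <- ncol(A); k <- ncol(y)
  vec_in <- attr(problem$y, "vector_input")

  AtA <- crossprod(A)
  DtD <- crossprod(D)
  M <- AtA + rho * DtD
  ch <- tryCatch(chol(M), error = function(e) chol(M + 1e-10 * diag(n)))
  Aty <- crossprod(A, y)

  H <- matrix(crossprod(A, y), n, k)   # deterministic init h = A^T y
  Z <- D %*% H
  U <- matrix(0, nrow(D), k)

  obj_of <- function(H) {
    r <- A %*% H - y
    colSums(r^2) / 2 + mu * colSums(abs(D %*% H))
  }
  best_obj <- obj_of(H)
  best_H <- H
  trace <- sum(best_obj)
  converged <- FALSE
  it <- 0
  for (it in seq_len(problem$max_iter)) {
    H_old <- H
    Z_old <- Z
    H <- backsolve(ch, backsolve(ch, Aty + rho * crossprod(D, Z - U),
                                 transpose = TRUE))
    DH <- D %*% H
    Z <- .soft_threshold(DH + U, mu / rho)
    U <- U + DH - Z
    o <- obj_of(H)
    improved <- o < best_obj
    if (any(improved)) {
      best_H[, improved] <- H[, improved]
      best_obj[improved] <- o[improved]
    }
    trace <- c(trace, sum(best_obj))
    scale <- max(sqrt(sum(H_old^2)), sqrt(sum(Z_old^2)), 1e-30)
    rel <- (sqrt(sum((H - H_old)^2)) + sqrt(sum((Z - Z_old)^2))) / scale
    if (rel < problem$tol) { converged <- TRUE; break }
  }
  h <- if (k == 1) drop(best_H) else best_H
  structure(list(h = h, objective = unname(best_obj), trace = trace,
                 iterations = it, converged = converged,
                 reg_weight = mu, rho = rho),
            class = "tv_fit")
}

#' @export
print.tv_fit <- function(x, ...) {
  cat(sprintf("<tv_fit> %d column(s), %d iterations%s, objective %.6g\n",
              if (is.matrix(x$h)) ncol(x$h) else 1L, x$iterations,
              if (x$converged) " (converged)" else "", sum(x$objective)))
  invisible(x)
}
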