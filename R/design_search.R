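#' Random-search design of a structured measurement matrix
#'
#' Repeatedly draws feasible matrices with [sample_feasible_matrix()] and
#' keeps the one with the strictly largest s-sparse injectivity number seen
#' so far (ties keep the earlier matrix). The search starts from the zero
#' matrix with injectivity number 0, so with `n_iter = 0` it returns that
#' initialization. Random selection within this structured class very often
#' yields a singular (zero-injectivity) matrix, which is why the search, not
#' a single draw, is the design tool.
#'
#' Candidates with an all-zero column or fewer than `2s` nonzero columns are
#' rejected without enumeration (their injectivity number is exactly 0), and
#' the enumeration of a surviving candidate aborts as soon as it can no
#' longer beat the incumbent; both shortcuts are exact, so the result is
#' identical to scoring every draw fully.
#'
#' @param structure A [cs_structure()].
#' @param s Sparsity level the design targets (default 2).
#' @param n_iter Number of random draws (>= 0).
#' @param seed Optional integer seed applied via [set.seed()]; `NULL` uses
#'   the current RNG state.
#' @return An object of class `design_result`: a list with `best_matrix`,
#'   `best_selection`, `best_sin`, `best_sin_normalized`, `iterations_run`,
#'   `improvement_trace` (tibble of iteration/SIN at each improvement),
#'   `structure`, `s`, `seed`.
#' @examples
#' res <- search_design(cs_structure(m0 = 12), s = 2, n_iter = 25, seed = 1)
#' res$best_sin
#' @export
search_design <- function(structure, s = 2, n_iter, seed = NULL) {
  stopifnot(inherits(structure, "cs_structure"),
            length(n_iter) == 1, n_iter >= 0, n_iter == round(n_iter))
  if (!is.null(seed)) set.seed(seed)

  best_sin <- 0
  best_sel <- matrix(0L, structure$m0, structure$blocks_per_group)
  best_mat <- make_cs_matrix(best_sel, structure)
  trace_it <- integer(0)
  trace_sin <- numeric(0)

  for (i in seq_len(n_iter)) {
    cand <- sample_feasible_matrix(structure)
    cand_sin <- sparse_injectivity(cand$matrix, s, early_exit = best_sin)
    if (cand_sin > best_sin) {
      best_sin <- cand_sin
      best_sel <- cand$selection
      best_mat <- cand$matrix
      trace_it <- c(trace_it, i)
      trace_sin <- c(trace_sin, cand_sin)
    }
  }

  structure(
    list(
      best_matrix = best_mat,
      best_selection = best_sel,
      best_sin = best_sin,
      best_sin_normalized = sparse_injectivity_normalized(best_mat, s),
      iterations_run = as.integer(n_iter),
      improvement_trace = tibble::tibble(iteration = trace_it,
                                         sin = trace_sin),
      structure = structure,
      s = as.integer(s),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
    ),
    class = "design_result"
  )
}

#' @export
print.design_result <- function(x, ...) {
  cat(sprintf(
    "<design_result> %d-SIN = %.4g after %d iterations (m0=%d, n0=%d)\n",
    x$s, x$best_sin, x$iterations_run, x$structure$m0, x$structure$n0
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Improvement trace of a design search
#'
#' @param x A `design_result`.
#' @param ... Unused.
#' @return A tibble with one row per strict improvement: `iteration`, `sin`.
#' @method tidy design_result
#' @export
tidy.design_result <- function(x, ...) x$improvement_trace

#' One-row summary of a design search
#'
#' @param x A `design_result`.
#' @param ... Unused.
#' @return A tibble with the structure parameters, target sparsity, best
#'   injectivity number (raw and spectral-norm normalized), iteration count
#'   and seed.
#' @method glance design_result
#' @export
glance.design_result <- function(x, ...) {
  tibble::tibble(
    block_size = x$structure$block_size,
    blocks_per_group = x$structure$blocks_per_group,
    n0 = x$structure$n0,
    m0 = x$structure$m0,
    s = x$s,
    best_sin = x$best_sin,
    best_sin_sq = x$best_sin^2,
    best_sin_normalized = x$best_sin_normalized,
    compression = x$structure$n0 / x$structure$m0,
    iterations = x$iterations_run,
    seed = x$seed
  )
}

#' Sweep the measurements-per-group count
#'
#' Runs [search_design()] for each `m0` in a range and tabulates the best
#' injectivity number found, the per-group compression factor `n0 / m0`, and
#' whether the design clears a non-singularity threshold. This maps the
#' compression frontier of a structured class: the smallest `m0` still
#' admitting a nonzero s-sparse injectivity number.
#'
#' @param m0_values Integer vector of measurements-per-group values to try.
#' @param block_size,blocks_per_group,num_groups Structure parameters passed
#'   to [cs_structure()].
#' @param s Sparsity level (default 2).
#' @param n_iter Search iterations per `m0`.
#' @param sin_threshold Designs with `best_sin` above this count as
#'   non-singular (default `1e-8`, safely above the round-off floor of the
#'   small-submatrix eigenvalue computations).
#' @param seed Optional base seed; `m0`-specific seeds are derived from it so
#'   runs are independent but reproducible.
#' @return A tibble with columns `m0`, `best_sin`, `compression`,
#'   `nonsingular`, `iterations`.
#' @export
compression_sweep <- function(m0_values, block_size = 4, blocks_per_group = 4,
                              num_groups = 4, s = 2, n_iter = 1000,
                              sin_threshold = 1e-8, seed = NULL) {
  purrr::map_dfr(as.integer(m0_values), function(m0) {
    st <- cs_structure(block_size, blocks_per_group, num_groups, m0)
    res <- search_design(st, s = s, n_iter = n_iter,
                         seed = if (is.null(seed)) NULL else seed + m0)
    tibble::tibble(
      m0 = m0,
      best_sin = res$best_sin,
      compression = st$n0 / m0,
      nonsingular = res$best_sin > sin_threshold,
      iterations = res$iterations_run
    )
  })
}

#' Random feasible matrix with non-vanishing injectivity number
#'
#' Baseline used when comparing an optimized design against an "unoptimized"
#' one: feasible matrices are resampled until the s-sparse injectivity number
#' exceeds `sin_threshold`, and the first such matrix is returned without any
#' further optimization. (A matrix with zero injectivity number cannot
#' recover the target class at all, so the fair baseline is the first random
#' matrix that is at least identifiable.)
#'
#' @inheritParams search_design
#' @param sin_threshold Acceptance threshold (default `1e-8`).
#' @param max_draws Bound on resampling attempts.
#' @return A `design_result` whose `iterations_run` is the number of draws
#'   used.
#' @export
sample_nonsingular_matrix <- function(structure, s = 2, sin_threshold = 1e-8,
                                      max_draws = 100000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  for (i in seq_len(max_draws)) {
    cand <- sample_feasible_matrix(structure)
    cand_sin <- sparse_injectivity(cand$matrix, s)
    if (cand_sin > sin_threshold) {
      return(structure(
        list(
          best_matrix = cand$matrix,
          best_selection = cand$selection,
          best_sin = cand_sin,
          best_sin_normalized =
            sparse_injectivity_normalized(cand$matrix, s),
          iterations_run = i,
          improvement_trace = tibble::tibble(iteration = i, sin = cand_sin),
          structure = structure,
          s = as.integer(s),
          seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
        ),
        class = "design_result"
      ))
    }
  }
  stop("no feasible matrix with injectivity number above the threshold ",
       "found in ", max_draws, " draws", call. = FALSE)
}
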