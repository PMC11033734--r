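#' Select a TV regularization weight on a held-out synthetic instance
#'
#' Generates a gradient-sparse detector signal (the signal class the
#' temporal filter produces), measures it with `A` (plus noise at the given
#' relative level), runs the TV recovery over a logarithmic grid of
#' weights, and returns the weight minimizing the recovery-domain relative
#' error. The held-out instance is independent of any experiment data, so
#' the selected weight is not tuned on the signals being evaluated.
#'
#' @param A Measurement matrix (block-diagonal over groups).
#' @param noise_level Relative l2 noise level of the intended use
#'   (default 0).
#' @param grid Candidate weights at unit signal scale
#'   (default `10^seq(-5, -1)`).
#' @param q Columns of the held-out instance (default 32).
#' @param seed Seed for the held-out instance and its noise.
#' @param match_data Optional `detector_data` whose root-mean-square value
#'   sets the amplitude scale of the held-out instance: the objective's
#'   optimal weight scales linearly with signal amplitude, so matching
#'   scales makes the selection transferable to the data at hand.
#' @param ... Solver settings passed through to [recover_transformed()].
#' @return The selected weight, with attribute `errors` (named vector of
#'   the grid errors).
#' @export
select_reg_weight <- function(A, noise_level = 0,
                              grid = 10^seq(-5, -1, by = 0.5),
                              q = 32, seed = 90210, match_data = NULL,
                              ...) {
  st <- attr(A, "structure")
  n <- ncol(A)
  n0 <- if (!is.null(st)) st$n0 else 16
  sig <- make_group_sparse_signals(n0 = n0, num_groups = n / n0, s = 2,
                                   q = q, mode = "gradient", seed = seed)
  scale <- 1
  if (!is.null(match_data)) {
    ref <- if (inherits(match_data, "detector_data")) match_data$values
    else match_data
    base <- unclass(as.matrix(A)) %*% sig$values
    scale <- sqrt(mean(ref^2)) / max(sqrt(mean(base^2)), 1e-300)
    sig$values <- sig$values * scale
    grid <- grid * scale
  }
  Y <- apply_cs(A, sig)
  if (noise_level > 0) Y <- add_noise(Y, noise_level, seed = seed + 1)$data
  errs <- vapply(grid, function(mu) {
    rec <- recover_transformed(Y, A = A, reg_weight = mu, ...)
    relative_l2_error(rec, sig)
  }, numeric(1))
  names(errs) <- signif(grid, 3)
  structure(grid[which.min(errs)], errors = errs)
}

#' Run the full compressed-sensing imaging experiment grid
#'
#' End-to-end driver mirroring the numerical study design: for each
#' measurement matrix (SIN-optimized versus first random feasible matrix
#' with non-vanishing SIN), each phantom class (near-sparse versus
#' piecewise), and each noise level, it simulates full detector data,
#' takes compressed measurements, reconstructs by the two-step method, and
#' reports three relative l2 errors per run: the realized data error
#' (noisy versus exact compressed data), the recovery-domain error
#' (recovered circular means versus the true means), and the image error
#' (two-step reconstruction versus the filtered-backprojection image from
#' full uncompressed data, which serves as the reference — the aim of
#' compressed sensing is to match the full-array image, not to beat it).
#'
#' @param m0 Measurements per group (default 12).
#' @param s Target sparsity (default 2).
#' @param design_iters Random-search iterations for the optimized matrix.
#' @param phantoms Phantom kinds to run (default both).
#' @param noise_levels Relative noise levels (default exact and 9%).
#' @param matrices Which matrices to run (default both).
#' @param n,q,Nr Sensors, time samples, image raster (defaults 64, 1024,
#'   128 — the instrument-scale configuration).
#' @param reg_weight TV weight; `NULL` selects per noise level via
#'   [select_reg_weight()].
#' @param seed Base seed; all randomness derives from it.
#' @param solver_settings List of extra arguments for the TV solver.
#' @return A tibble with one row per run: `matrix`, `phantom`, `noise`,
#'   `data_error`, `cs_error`, `fbp_error`, `reg_weight`, `sin`. Details
#'   (matrices, reference images, recovered data) are attached as
#'   attribute `details`.
#' @export
run_experiment <- function(m0 = 12, s = 2, design_iters = 200,
                           phantoms = c("sparse", "piecewise"),
                           noise_levels = c(0, 0.09),
                           matrices = c("optimized", "random"),
                           n = 64, q = 1024, Nr = 128,
                           reg_weight = NULL, seed = 1,
                           solver_settings = list()) {
  st <- cs_structure(m0 = m0)
  stopifnot(st$n == n)
  geom <- sensor_geometry(R = 1, n = n)
  tg <- time_grid(R = 1, q = q)
  ig <- image_grid(R = 1, Nr = Nr)

  designs <- list()
  if ("optimized" %in% matrices) {
    designs$optimized <- search_design(st, s = s, n_iter = design_iters,
                                       seed = seed)
  }
  if ("random" %in% matrices) {
    designs$random <- sample_nonsingular_matrix(st, s = s, seed = seed + 1)
  }

  rows <- list()
  details <- list(designs = designs)
  for (ph_kind in phantoms) {
    ph <- make_disk_phantom(ph_kind, seed = seed + 10, geometry = geom)
    cm <- circular_means(ph, geom, tg)
    pr <- pressure_from_means(cm)
    ref_img <- fbp(pr, ig)
    details[[paste0("phantom_", ph_kind)]] <-
      list(phantom = ph, reference = ref_img)
    for (mt in names(designs)) {
      A <- assemble_block_diagonal(designs[[mt]]$best_matrix)
      Y0 <- apply_cs(A, pr)
      for (lev in noise_levels) {
        if (lev > 0) {
          nz <- add_noise(Y0, lev, seed = seed + 100)
          Y <- nz$data
          data_err <- relative_l2_error(Y, Y0)
        } else {
          Y <- Y0
          data_err <- 0
        }
        Yt <- apply_phi(Y)
        mu <- reg_weight
        if (is.null(mu)) {
          mu <- as.numeric(select_reg_weight(A, noise_level = lev,
                                             seed = seed + 200,
                                             match_data = Yt))
        }
        rec <- do.call(recover_transformed,
                       c(list(Yt, A = A, reg_weight = mu), solver_settings))
        img <- fbp_from_means(rec, ig)
        rows[[length(rows) + 1]] <- tibble::tibble(
          matrix = mt, phantom = ph_kind, noise = lev,
          data_error = data_err,
          cs_error = relative_l2_error(rec, cm),
          fbp_error = relative_l2_error(img, ref_img),
          reg_weight = mu,
          sin = designs[[mt]]$best_sin
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "details") <- details
  out
}
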