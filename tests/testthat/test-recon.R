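test_that("apply_cs acts per sample and validates dimensions", {
  st <- cs_structure(m0 = 2, num_groups = 1)
  M <- make_cs_matrix(rbind(c(1, 0, 1, 2), c(4, 1, 4, 0)), st)
  A <- assemble_block_diagonal(list(M))
  geom <- sensor_geometry(R = 1, n = 16)
  tg <- time_grid(R = 1, q = 8)
  ones <- detector_data(matrix(1, 16, 8), "circular_means", geom, tg)
  Y <- apply_cs(A, ones)
  expect_equal(Y$values, matrix(c(3, 3), 2, 8))  # row sums of the example
  z <- apply_cs(matrix(0, 2, 16), ones)
  expect_equal(sum(abs(z$values)), 0)
  expect_error(apply_cs(matrix(0, 2, 7), ones), "columns")
})

test_that("relative_l2_error basics", {
  x <- c(1, 2, 3)
  expect_equal(relative_l2_error(x, x), 0)
  expect_equal(relative_l2_error(0 * x, x), 1)
  expect_equal(relative_l2_error(2 * x, x), 1)
  expect_error(relative_l2_error(x, 0 * x), "zero")
})

test_that("tv_solve limits: unregularized and fully fused", {
  y <- c(1, 1, 0, 0)
  f0 <- tv_solve(tv_problem(diag(4), y, reg_weight = 1e-9, max_iter = 500))
  expect_equal(f0$h, y, tolerance = 1e-5)
  # non-cyclic difference on 4 points, huge weight: flat at the data mean
  D <- rbind(c(-1, 1, 0, 0), c(0, -1, 1, 0), c(0, 0, -1, 1))
  f1 <- tv_solve(tv_problem(diag(4), y, reg_weight = 50, D = D,
                            max_iter = 2000))
  expect_equal(f1$h, rep(0.5, 4), tolerance = 1e-4)
  # exhaustive check over two-level piecewise-constant candidates confirms
  # the flat solution is the l2-optimal one under dominating TV
  cands <- expand.grid(a = seq(0, 1, 0.05), b = seq(0, 1, 0.05))
  objs <- apply(cands, 1, function(p) {
    h <- c(p[1], p[1], p[2], p[2])
    0.5 * sum((h - y)^2) + 50 * sum(abs(D %*% h))
  })
  best <- cands[which.min(objs), ]
  expect_equal(as.numeric(best), c(0.5, 0.5), tolerance = 0.051)
  expect_error(tv_problem(diag(4), c(1, NA, 0, 0), 1), "non-finite")
})

test_that("tv_solve matches a projected-subgradient oracle on a random instance", {
  set.seed(12)
  A <- matrix(rnorm(48), 6, 8)
  y <- rnorm(6)
  D <- ring_difference(8)
  mu <- 0.3
  fit <- tv_solve(tv_problem(A, y, mu, max_iter = 5000, tol = 1e-12))
  orc <- tv_subgradient_oracle(A, y, mu, D, n_iter = 40000)
  expect_equal(fit$objective, orc$objective, tolerance = 1e-4)
  expect_lte(fit$objective, orc$objective + 1e-6)  # at least as good
})

test_that("tv_solve objective trace is nonincreasing and scaling-consistent", {
  set.seed(3)
  A <- matrix(rnorm(60), 6, 10)
  y <- rnorm(6)
  fit <- tv_solve(tv_problem(A, y, 0.05, max_iter = 800))
  expect_true(all(diff(fit$trace) <= 1e-12))
  # scaling (y, mu) -> (c y, c mu) scales the minimizer by c
  c0 <- 3.7
  fit2 <- tv_solve(tv_problem(A, c0 * y, c0 * 0.05, max_iter = 3000,
                              tol = 1e-12))
  expect_equal(fit2$h, c0 * fit$h, tolerance = 1e-3)
})

test_that("exhaustive decoder certifies exact recovery iff SIN is positive", {
  st <- cs_structure(m0 = 12)
  des <- search_design(st, 2, 100, seed = 6)
  expect_gt(des$best_sin, 1e-6)
  M <- des$best_matrix
  set.seed(101)
  for (i in 1:25) {
    x <- numeric(16)
    x[sample(16, 2)] <- runif(2, 0.5, 1.5) * sample(c(-1, 1), 2, TRUE)
    expect_equal(decode_sparse(unclass(M) %*% x, M, 2), x,
                 tolerance = 1e-8)
  }
  # zero-SIN matrix: some 2-sparse vector is not identifiable
  set.seed(5)
  repeat {
    Mz <- sample_feasible_matrix(st)$matrix
    if (sparse_injectivity(Mz, 2) < 1e-8) break
  }
  fails <- 0
  set.seed(77)
  for (i in 1:60) {
    x <- numeric(16)
    x[sample(16, 2)] <- runif(2, 0.5, 1.5) * sample(c(-1, 1), 2, TRUE)
    xh <- decode_sparse(unclass(Mz) %*% x, Mz, 2)
    if (max(abs(xh - x)) > 1e-6) fails <- fails + 1
  }
  expect_gt(fails, 0)
})

test_that("recover_transformed achieves near-exact sparse recovery", {
  st <- cs_structure(m0 = 12)
  des <- search_design(st, 2, 150, seed = 1)
  A <- assemble_block_diagonal(des$best_matrix)
  sig <- make_group_sparse_signals(s = 2, q = 24, mode = "gradient",
                                   seed = 7)
  Y <- apply_cs(A, sig)
  rec <- recover_transformed(Y, A = A, reg_weight = 3e-4, max_iter = 8000)
  expect_lt(relative_l2_error(rec, sig), 1e-3)
  # zero data -> zero recovery
  z <- Y; z$values <- 0 * z$values
  rec0 <- recover_transformed(z, A = A, reg_weight = 1e-3, max_iter = 50)
  expect_equal(sum(abs(rec0$values)), 0)
})

test_that("two-step pipeline collapses to plain FBP without compression", {
  geom <- sensor_geometry(R = 1, n = 64)
  tg <- time_grid(R = 1, q = 256)
  ph <- make_disk_phantom("sparse", seed = 2, geometry = geom, grid = tg)
  pr <- forward_pressure(ph, geom, tg)
  ig <- image_grid(R = 1, Nr = 32)
  ref <- fbp(pr, ig)
  Y <- apply_cs(diag(64), pr)
  img <- two_step_reconstruct(Y, A = diag(64), reg_weight = 1e-10,
                              grid_out = ig, max_iter = 400)
  expect_lt(relative_l2_error(img, ref), 1e-3)
})

test_that("noise injection realizes the requested level exactly", {
  geom <- sensor_geometry(R = 1, n = 8)
  tg <- time_grid(R = 1, q = 32)
  d <- detector_data(matrix(rnorm(8 * 32, sd = 2), 8), "pressure", geom, tg)
  nz <- add_noise(d, 0.09, seed = 4)
  expect_equal(relative_l2_error(nz$data, d), 0.09, tolerance = 1e-12)
  expect_equal(nz$realized_error, 0.09)
  # different seeds, same realized level, different noise
  nz2 <- add_noise(d, 0.09, seed = 5)
  expect_equal(relative_l2_error(nz2$data, d), 0.09, tolerance = 1e-12)
  expect_gt(max(abs(nz2$data$values - nz$data$values)), 0)
  expect_identical(add_noise(d, 0)$data, d)
  zz <- d; zz$values <- 0 * zz$values
  expect_error(add_noise(zz, 0.1), "zero data")
})
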