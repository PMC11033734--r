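test_that("sparse_injectivity on canonical matrices", {
  expect_equal(sparse_injectivity(diag(16), s = 2), 1.0)
  expect_equal(sparse_injectivity(diag(8), s = 4), 1.0)
  M <- diag(8); M[, 3] <- 0              # a zero column kills injectivity
  expect_equal(sparse_injectivity(M, s = 1), 0)
  # the printed 2x16 example matrix has zero columns, hence SIN 0
  st <- cs_structure(m0 = 2)
  Mex <- make_cs_matrix(rbind(c(1, 0, 1, 2), c(4, 1, 4, 0)), st)
  expect_equal(sparse_injectivity(Mex, 2), 0)
  expect_error(sparse_injectivity(diag(4), s = 3), "exceeds")
})

test_that("sparse_injectivity agrees with the enumeration and sampling oracles", {
  st <- cs_structure(m0 = 12)
  set.seed(11)
  n_checked <- 0
  while (n_checked < 8) {
    M <- sample_feasible_matrix(st)$matrix
    v <- sparse_injectivity(M, 2)
    expect_equal(v, sin_oracle(M, 2), tolerance = 1e-10)
    if (v > 1e-6) {
      # random 2-sparse pairs only upper-bound the infimum
      expect_gte(sin_sampling_bound(M, 2, 3000), v - 1e-10)
    }
    n_checked <- n_checked + 1
  }
})

test_that("SIN monotonicity, bounds and permutation invariance", {
  st <- cs_structure(m0 = 12)
  set.seed(21)
  for (i in 1:6) {
    M <- sample_feasible_matrix(st)$matrix
    s1 <- sparse_injectivity(M, 1)
    s2 <- sparse_injectivity(M, 2)
    expect_lte(s2, s1 + 1e-12)           # larger support set, smaller min
    expect_gte(s2, 0)
    expect_lte(s2, max(svd(unclass(M))$d) + 1e-12)
    pr <- sample(nrow(M)); pc <- sample(ncol(M))
    expect_equal(sparse_injectivity(unclass(M)[pr, pc], 2), s2,
                 tolerance = 1e-10)
  }
})

test_that("positive SIN is equivalent to full rank of every 2s-column subset", {
  st <- cs_structure(m0 = 12)
  set.seed(33)
  found_pos <- FALSE; found_zero <- FALSE
  for (i in 1:60) {
    M <- sample_feasible_matrix(st)$matrix
    v <- sparse_injectivity(M, 2)
    subs <- utils::combn(16, 4)
    minrank <- min(apply(subs, 2, function(S) qr(unclass(M)[, S])$rank))
    if (v > 1e-6) { expect_equal(minrank, 4); found_pos <- TRUE }
    else { expect_lt(minrank, 4); found_zero <- TRUE }
    if (found_pos && found_zero && i > 40) break
  }
  expect_true(found_zero)  # random draws do hit singular matrices
})

test_that("normalized SIN divides by the spectral norm", {
  st <- cs_structure(m0 = 12)
  res <- search_design(st, 2, 60, seed = 5)
  M <- res$best_matrix
  expect_equal(sparse_injectivity_normalized(M, 2),
               sparse_injectivity(M, 2) / max(svd(unclass(M))$d))
  expect_equal(sparse_injectivity_normalized(matrix(0, 2, 4), 1), 0)
})

test_that("rip_delta on canonical and closed-form cases", {
  expect_equal(rip_delta(diag(6), 3), 0)
  expect_equal(rip_delta(matrix(0, 4, 5), 1), 1)
  # 2x2 with columns (1,0) and (eps, sqrt(1-eps^2)): Gram eigenvalues 1 +- eps
  eps <- 0.3
  M <- cbind(c(1, 0), c(eps, sqrt(1 - eps^2)))
  expect_equal(rip_delta(M, 2), eps, tolerance = 1e-12)
  expect_error(rip_delta(matrix(0, 2, 30), 2), "24 columns")
  # permutation invariance
  set.seed(2)
  A <- matrix(rnorm(12 * 8), 12, 8) / sqrt(12)
  expect_equal(rip_delta(A[, sample(8)], 2), rip_delta(A, 2),
               tolerance = 1e-12)
})

test_that("best_s_term_error drops the largest magnitudes", {
  x <- c(3, -1, 0.5)
  expect_equal(best_s_term_error(x, 1), 1.5)
  expect_equal(best_s_term_error(x, 3), 0)
  expect_equal(best_s_term_error(x, 0), sum(abs(x)))
  set.seed(9)
  z <- rnorm(20)
  errs <- vapply(0:20, function(s) best_s_term_error(z, s), numeric(1))
  expect_true(all(diff(errs) <= 1e-12))  # nonincreasing in s
})
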