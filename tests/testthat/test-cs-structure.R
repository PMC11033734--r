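test_that("cs_structure derives sizes and validates counts", {
  st <- cs_structure(m0 = 12)
  expect_equal(st$n0, 16L)
  expect_equal(st$n, 64L)
  expect_equal(st$m, 48L)
  st2 <- cs_structure(block_size = 2, blocks_per_group = 8, num_groups = 4,
                      m0 = 10)
  expect_equal(st2$n0, 16L)
  expect_error(cs_structure(m0 = 0), "positive integers")
  expect_error(cs_structure(m0 = 17), "cannot exceed")
  expect_error(cs_structure(block_size = 2.5, m0 = 2), "positive integers")
})

test_that("make_cs_matrix reproduces the two-row switched-array example", {
  st <- cs_structure(m0 = 2)
  sel <- rbind(c(1, 0, 1, 2), c(4, 1, 4, 0))
  M <- make_cs_matrix(sel, st)
  expect_equal(
    unclass(M),
    rbind(c(1,0,0,0, 0,0,0,0, 1,0,0,0, 0,1,0,0),
          c(0,0,0,1, 1,0,0,0, 0,0,0,1, 0,0,0,0)),
    ignore_attr = TRUE
  )
  expect_true(is_feasible(M, st))
})

test_that("make_cs_matrix degenerate selections and errors", {
  st <- cs_structure(m0 = 3)
  all_off <- matrix(0L, 3, 4)
  expect_equal(sum(make_cs_matrix(all_off, st)), 0)
  all_one <- matrix(1L, 3, 4)
  M <- make_cs_matrix(all_one, st)
  expect_equal(unname(rowSums(M)), rep(4, 3))   # one per block
  bad <- matrix(0L, 3, 4); bad[2, 3] <- 7L
  expect_error(make_cs_matrix(bad, st), "row 2, block 3")
  expect_error(make_cs_matrix(matrix(0L, 2, 4), st), "3 x 4")
})

test_that("is_feasible enforces the at-most-one-per-block constraint", {
  st <- cs_structure(m0 = 2)
  M <- matrix(0, 2, 16)
  expect_true(is_feasible(M, st))        # "at most one" permits zero
  M[1, c(1, 3)] <- 1                     # two in one block
  expect_false(is_feasible(M, st))
  M2 <- matrix(0, 2, 16); M2[1, 1] <- 2  # non-binary
  expect_false(is_feasible(M2, st))
  expect_error(is_feasible(matrix(0, 3, 16), st), "2 x 16")
})

test_that("sample_feasible_matrix is uniform over cells and reproducible", {
  st <- cs_structure(m0 = 12)
  set.seed(1); a <- sample_feasible_matrix(st)
  set.seed(1); b <- sample_feasible_matrix(st)
  expect_identical(a$selection, b$selection)
  # per-cell "off" frequency ~ 1/5 under uniform choice over 5 states
  set.seed(42)
  cells <- replicate(2000, sample_feasible_matrix(st)$selection)
  off_freq <- mean(cells == 0)
  expect_lt(abs(off_freq - 0.2), 0.01)
  # feasibility closure over draws
  set.seed(7)
  for (i in 1:25) {
    expect_true(is_feasible(sample_feasible_matrix(st)$matrix, st))
  }
})

test_that("assemble_block_diagonal shapes, zeros and replication", {
  st <- cs_structure(m0 = 12)
  set.seed(3)
  gs <- replicate(4, sample_feasible_matrix(st)$matrix, simplify = FALSE)
  A <- assemble_block_diagonal(gs)
  expect_equal(dim(A), c(48L, 64L))
  expect_equal(sum(A), sum(vapply(gs, sum, numeric(1))))
  for (g in 1:4) {
    expect_equal(A[(g - 1) * 12 + 1:12, (g - 1) * 16 + 1:16],
                 unclass(gs[[g]]), ignore_attr = TRUE)
  }
  off <- A
  for (g in 1:4) off[(g - 1) * 12 + 1:12, (g - 1) * 16 + 1:16] <- 0
  expect_equal(sum(abs(off)), 0)
  # single group: identity packaging
  st1 <- cs_structure(num_groups = 1, m0 = 5)
  set.seed(4); g1 <- sample_feasible_matrix(st1)$matrix
  expect_equal(unclass(assemble_block_diagonal(list(g1))), unclass(g1),
               ignore_attr = TRUE)
  # replicated single matrix across groups
  A4 <- assemble_block_diagonal(gs[[1]])
  expect_equal(A4[13:24, 17:32], unclass(gs[[1]]), ignore_attr = TRUE)
})
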