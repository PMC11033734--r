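test_that("geometry, grids and the sampling rule", {
  geom <- sensor_geometry(R = 2, n = 8, Omega = 2 * pi)
  expect_equal(geom$positions[1, ], c(x = 2, y = 0))
  expect_equal(geom$positions[3, ], c(x = 0, y = 2), tolerance = 1e-12)
  tg <- time_grid(R = 2, q = 5)
  expect_equal(tg$times, c(0, 1, 2, 3, 4))
  expect_equal(nyquist_sensor_count(128), 201L)
  expect_equal(nyquist_sensor_count(0), 0L)
  expect_true(is_undersampled(64, 128))
  expect_false(is_undersampled(201, 128))
  expect_error(sensor_geometry(R = -1), "R > 0")
  expect_error(disk_phantom(x = 0.9, y = 0, radius = 0.3, amplitude = 1),
               "not strictly inside")
})

test_that("circular means of uniform disks match the closed form and oracle", {
  # partial overlap: d = 2, a = 1, r = 2 -> arccos(7/8)/pi
  expect_equal(cspat:::.uniform_disk_mean(2, 1, 2), acos(7 / 8) / pi,
               tolerance = 1e-12)
  # full containment and empty cases
  expect_equal(cspat:::.uniform_disk_mean(0.2, 0.5, 0.1), 1)
  expect_equal(cspat:::.uniform_disk_mean(2, 0.5, 0.5), 0)
  geom <- sensor_geometry(R = 1, n = 4)
  tg <- time_grid(R = 1, q = 128)
  ph <- disk_phantom(x = 0.2, y = -0.1, radius = 0.3, amplitude = 0.8)
  cm <- circular_means(ph, geom, tg)
  for (l in c(40, 60, 90)) {
    expect_equal(cm$values[1, l],
                 circle_mean_oracle(ph, geom$positions[1, ], tg$times[l],
                                    n_theta = 50000),
                 tolerance = 1e-3)
  }
  # empty phantom -> zeros
  cm0 <- circular_means(disk_phantom(R = 1), geom, tg)
  expect_equal(sum(abs(cm0$values)), 0)
})

test_that("circular means of taper and flat_means disks match dense quadrature", {
  geom <- sensor_geometry(R = 1, n = 3)
  tg <- time_grid(R = 1, q = 128)
  for (prof in c("taper", "flat_means")) {
    ph <- disk_phantom(x = -0.25, y = 0.15, radius = 0.2, amplitude = 1.1,
                       profile = prof, kappa = 3)
    cm <- circular_means(ph, geom, tg)
    busiest <- which.max(abs(cm$values[2, ]))
    # near tangency the point-sampled oracle is biased by the rim clamp of
    # phantom_values, so the comparison is loosest there
    for (l in c(busiest, busiest + 4L)) {
      expect_equal(cm$values[2, l],
                   circle_mean_oracle(ph, geom$positions[2, ], tg$times[l],
                                      n_theta = 100000),
                   tolerance = 1e-2)
    }
  }
})

test_that("Abel transform reproduces analytic pairs", {
  geom <- sensor_geometry(R = 1, n = 2)
  tg <- time_grid(R = 1, q = 512)
  m1 <- detector_data(matrix(1, 2, 512), "circular_means", geom, tg)
  g1 <- abel_forward(m1)
  expect_equal(g1$values[1, ], tg$times, tolerance = 1e-10)   # g(t) = t
  p1 <- pressure_from_means(m1)
  expect_equal(p1$values[2, ], rep(1, 512), tolerance = 1e-8) # p = 1
  b <- 0.5
  ind <- matrix(as.numeric(tg$times <= b), 2, 512, byrow = TRUE)
  gi <- abel_forward(detector_data(ind, "circular_means", geom, tg))
  ref <- ifelse(tg$times <= b, tg$times,
                tg$times - sqrt(pmax(0, tg$times^2 - b^2)))
  expect_lt(max(abs(gi$values[1, ] - ref)), 0.02)  # kink smearing only
  # zero maps to zero, scaling is linear
  z <- abel_forward(detector_data(matrix(0, 2, 512), "circular_means",
                                  geom, tg))
  expect_equal(sum(abs(z$values)), 0)
  g2 <- abel_forward(detector_data(3 * ind, "circular_means", geom, tg))
  expect_equal(g2$values, 3 * gi$values, tolerance = 1e-12)
})

test_that("Abel round trip error is small and decreases with q", {
  geom <- sensor_geometry(R = 1, n = 2)
  errs <- vapply(c(256, 512, 1024), function(q) {
    tg <- time_grid(R = 1, q = q)
    t <- tg$times
    m <- rbind(t * exp(-3 * t^2) + 0.3 * sin(pi * t / 2)^2,
               sin(pi * t / 2)^2 * exp(-t))
    md <- detector_data(m, "circular_means", geom, tg)
    rt <- abel_inverse(abel_forward(md))
    relative_l2_error(rt$values, m)
  }, numeric(1))
  expect_lt(errs[2], 0.01)              # <= 1% from q = 512
  expect_lt(errs[3], 0.01)
  expect_true(all(diff(errs) < 0))      # monotone decrease
  # inverse of the analytic pair g(t) = t
  tg <- time_grid(R = 1, q = 512)
  g <- detector_data(matrix(tg$times, 2, 512, byrow = TRUE), "transformed",
                     geom, tg)
  m <- abel_inverse(g)
  expect_equal(m$values[1, -(1:3)], rep(1, 509), tolerance = 1e-6)
  g0 <- abel_inverse(detector_data(matrix(0, 2, 512), "transformed",
                                   geom, tg))
  expect_equal(sum(abs(g0$values)), 0)
})

test_that("forward model is linear and respects finite propagation", {
  geom <- sensor_geometry(R = 1, n = 16)
  tg <- time_grid(R = 1, q = 512)
  ph1 <- disk_phantom(x = 0.3, y = 0, radius = 0.15, amplitude = 1)
  ph2 <- disk_phantom(x = -0.2, y = 0.2, radius = 0.2, amplitude = 0.6)
  both <- disk_phantom(x = c(0.3, -0.2), y = c(0, 0.2),
                       radius = c(0.15, 0.2), amplitude = c(1, 0.6))
  p1 <- forward_pressure(ph1, geom, tg)
  p2 <- forward_pressure(ph2, geom, tg)
  pb <- forward_pressure(both, geom, tg)
  expect_equal(pb$values, p1$values + p2$values, tolerance = 1e-10)
  expect_equal(sum(abs(forward_pressure(disk_phantom(R = 1), geom,
                                        tg)$values)), 0)
  # arrival window: sensor 1 sees disk 1 only within [d - a, d + a]
  # (plus the stencil width and the 2D tail after integration)
  d <- sqrt((1 - 0.3)^2); a <- 0.15
  before <- tg$times < d - a - 3 * tg$dt
  expect_lt(max(abs(p1$values[1, before])), 1e-8)
})

test_that("temporal filter inverts the forward model per sensor", {
  geom <- sensor_geometry(R = 1, n = 16)
  tg <- time_grid(R = 1, q = 1024)
  ph <- disk_phantom(x = 0.1, y = -0.2, radius = 0.3, amplitude = 1)
  cm <- circular_means(ph, geom, tg)
  rec <- apply_phi(pressure_from_means(cm))
  expect_lt(relative_l2_error(rec, cm), 0.02)
  z <- apply_phi(detector_data(matrix(0, 16, 1024), "pressure", geom, tg))
  expect_equal(sum(abs(z$values)), 0)
})

test_that("temporal filter commutes exactly with sensor mixing", {
  geom <- sensor_geometry(R = 1, n = 64)
  tg <- time_grid(R = 1, q = 256)
  ph <- disk_phantom(x = 0.2, y = 0.1, radius = 0.25, amplitude = 1)
  P <- forward_pressure(ph, geom, tg)
  st <- cs_structure(m0 = 12)
  set.seed(5)
  A <- assemble_block_diagonal(sample_feasible_matrix(st)$matrix)
  lhs <- apply_phi(apply_cs(A, P))$values
  rhs <- unclass(A) %*% apply_phi(P)$values
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("fbp reconstructs a disk and validates its inputs", {
  geom <- sensor_geometry(R = 1, n = 128)
  tg <- time_grid(R = 1, q = 512)
  ph <- disk_phantom(x = 0.1, y = -0.2, radius = 0.25, amplitude = 1)
  pr <- forward_pressure(ph, geom, tg)
  ig <- image_grid(R = 1, Nr = 64)
  img <- fbp(pr, ig)
  truth <- rasterize_phantom(ph, ig)
  inside <- outer(ig$xs, ig$xs, function(y, x) sqrt(x^2 + y^2) < 1)
  err <- sqrt(sum((img$values - truth$values)[inside]^2) /
                sum(truth$values[inside]^2))
  expect_lt(err, 0.2)
  z <- fbp(detector_data(matrix(0, 128, 512), "pressure", geom, tg), ig)
  expect_equal(sum(abs(z$values)), 0)
  expect_error(fbp(pr, image_grid(R = 2, Nr = 16)), "exceeds")
  expect_error(fbp(apply_phi(pr)), "expects pressure")
})

test_that("means path and pressure path agree within round-trip error", {
  geom <- sensor_geometry(R = 1, n = 64)
  tg <- time_grid(R = 1, q = 256)
  ph <- disk_phantom(x = -0.15, y = 0.2, radius = 0.2, amplitude = 1)
  cm <- circular_means(ph, geom, tg)
  ig <- image_grid(R = 1, Nr = 32)
  img1 <- fbp_from_means(cm, ig)
  img2 <- fbp(pressure_from_means(cm), ig)
  # the pressure path adds one derivative/integration round trip
  expect_lt(relative_l2_error(img2, img1), 0.05)
  z <- fbp_from_means(detector_data(matrix(0, 64, 256), "circular_means",
                                    geom, tg), ig)
  expect_equal(sum(abs(z$values)), 0)
})

test_that("forward and adjoint satisfy the inner-product identity", {
  geom <- sensor_geometry(R = 1, n = 64)
  tg <- time_grid(R = 1, q = 512)
  ig <- image_grid(R = 1, Nr = 64)
  dt <- tg$dt; arc <- 2 * pi * geom$R / geom$n
  set.seed(17)
  for (i in 1:3) {
    u1 <- random_taper_phantom(300 + i)
    u2 <- random_taper_phantom(400 + i)
    P2 <- forward_pressure(u2, geom, tg)
    lhs <- sum(forward_pressure(u1, geom, tg)$values * P2$values) * dt * arc
    rhs <- sum(rasterize_phantom(u1, ig)$values *
                 forward_adjoint(P2, ig)$values) * ig$pixel_area
    expect_equal(lhs / rhs, 1, tolerance = 0.02)
  }
})
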