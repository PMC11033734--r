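# independent oracles and shared fixtures

# SIN by direct SVD enumeration over column subsets (independent of the
# compiled path)
sin_oracle <- function(M, s) {
  M <- unclass(as.matrix(M))
  subs <- utils::combn(ncol(M), 2 * s)
  min(apply(subs, 2, function(S) min(svd(M[, S, drop = FALSE])$d)))
}

# upper bound on the SIN from random sparse difference directions
sin_sampling_bound <- function(M, s, n_draws = 2000) {
  M <- unclass(as.matrix(M))
  n <- ncol(M)
  vals <- replicate(n_draws, {
    x <- numeric(n)
    S <- sample.int(n, 2 * s)
    x[S] <- stats::rnorm(2 * s)
    sqrt(sum((M %*% x)^2) / sum(x^2))
  })
  min(vals)
}

# projected-subgradient oracle for the TV objective
# 1/2 ||A h - y||^2 + mu ||D h||_1 run to high precision
tv_subgradient_oracle <- function(A, y, mu, D, n_iter = 60000) {
  h <- crossprod(A, y)
  best <- Inf
  best_h <- h
  L <- max(svd(A)$d)^2 + mu * max(svd(D)$d)
  for (k in seq_len(n_iter)) {
    g <- crossprod(A, A %*% h - y) + mu * crossprod(D, sign(D %*% h))
    h <- h - (1 / (L * sqrt(k))) * g
    o <- 0.5 * sum((A %*% h - y)^2) + mu * sum(abs(D %*% h))
    if (o < best) { best <- o; best_h <- h }
  }
  list(h = best_h, objective = best)
}

tv_objective <- function(A, y, mu, D, h) {
  0.5 * sum((A %*% h - y)^2) + mu * sum(abs(D %*% h))
}

random_taper_phantom <- function(seed, R = 1) {
  set.seed(seed)
  k <- sample(2:4, 1)
  th <- stats::runif(k, 0, 2 * pi)
  rr <- stats::runif(k, 0, 0.5 * R)
  disk_phantom(x = rr * cos(th), y = rr * sin(th),
               radius = stats::runif(k, 0.08, 0.3) * R,
               amplitude = stats::runif(k, 0.5, 1.5),
               profile = "taper", kappa = sample(2:4, k, TRUE), R = R)
}

# mean of a disk phantom over one circle by dense angular sampling
circle_mean_oracle <- function(phantom, center, r, n_theta = 200000) {
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-1]
  mean(phantom_values(phantom, center[1] + r * cos(th),
                      center[2] + r * sin(th)))
}
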