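test_that("wls_cg at convergence matches the dense pseudo-inverse solution", {
  set.seed(3)
  d <- c(8, 8, 8)
  n <- prod(d)
  kern <- make_dipole_kernel(d, 1)
  w <- array(runif(n, 0.5, 1.5), d)
  chi_true <- array(rnorm(n, sd = 0.05), d)
  delta <- forward_field(chi_true, kern)
  # explicit dense normal equations, solved independently
  Aop <- function(v) forward_field(array(v, d), kern)
  A <- dense_operator(Aop, n)
  Nmat <- A %*% (as.vector(w)^2 * A) # A diag(w^2) A, A symmetric
  b <- A %*% (as.vector(w)^2 * as.vector(delta))
  x_dense <- MASS::ginv(Nmat) %*% b
  x_cg <- wls_cg(delta, w, kern, n_iter = 2000)
  expect_lt(sqrt(sum((as.vector(x_cg) - x_dense)^2)) /
              sqrt(sum(x_dense^2)), 1e-6)
})

test_that("wls_cg runs a fixed iteration count with non-increasing residual", {
  set.seed(4)
  d <- c(12, 12, 12)
  kern <- make_dipole_kernel(d, 1)
  delta <- forward_field(array(rnorm(prod(d), sd = 0.1), d), kern)
  w <- array(1, d)
  x <- wls_cg(delta, w, kern, n_iter = 25, track = TRUE)
  res <- attr(x, "residuals")
  expect_length(res, 25L)
  expect_true(all(diff(res) <= 1e-12))
  # zero field maps to zero for any iteration count (zero initialization)
  expect_equal(max(abs(wls_cg(array(0, d), w, kern, 5))), 0)
  expect_error(wls_cg(delta, array(0, d), kern, 5), "degenerate")
})

test_that("tkd_invert equals brute-force per-coefficient division", {
  set.seed(5)
  d <- c(16, 16, 16)
  delta <- array(rnorm(prod(d), sd = 0.02), d)
  thr <- 0.18
  # independent oracle: rebuild the kernel from raw frequency indices and
  # divide coefficient by coefficient
  f <- ((0:15 + 8) %% 16 - 8) / 16
  g <- expand.grid(kx = f, ky = f, kz = f)
  k2 <- g$kx^2 + g$ky^2 + g$kz^2
  dk <- ifelse(k2 == 0, 0, 1 / 3 - g$kz^2 / k2)
  dt <- ifelse(abs(dk) > thr, dk, ifelse(dk < 0, -thr, thr))
  Y <- as.vector(fft(delta)) / dt
  Y[1] <- 0
  oracle <- Re(fft(array(Y, d), inverse = TRUE)) / prod(d)
  got <- tkd_invert(delta, make_dipole_kernel(d, 1), thr)
  expect_lt(max(abs(got - oracle)) / max(abs(oracle)), 1e-12)
  # where |d| > threshold the inversion is exact
  chi_true <- array(rnorm(prod(d), sd = 0.05), d)
  kern <- make_dipole_kernel(d, 1)
  rec <- tkd_invert(forward_field(chi_true, kern), kern, thr)
  keep <- abs(unclass(kern)) > thr
  expect_equal(fft(rec)[keep], fft(chi_true)[keep], tolerance = 1e-8)
  # zero mode discards the band instead of clipping
  z <- tkd_invert(delta, kern, thr, mode = "zero")
  expect_equal(max(Mod(fft(z)[!keep])), 0, tolerance = 1e-8)
})

test_that("spatial gradients satisfy ramp, boundary and adjoint identities", {
  d <- c(8, 8, 8)
  expect_equal(spatial_gradient(array(3.2, d), 1)[1:7, , ],
               array(0, c(7, 8, 8)))
  ramp <- array(rep(2 * (1:8), each = 1), d) # slope 2 along x
  gx <- spatial_gradient(ramp, 1)
  expect_equal(gx[1:7, , ], array(2, c(7, 8, 8)))
  expect_equal(gx[8, , ], -ramp[8, , ]) # zero-padded boundary
  set.seed(6)
  for (ax in 1:3) {
    x <- array(rnorm(prod(d)), d)
    y <- array(rnorm(prod(d)), d)
    expect_equal(sum(spatial_gradient(x, ax) * y),
                 sum(x * spatial_gradient_adjoint(y, ax)),
                 tolerance = 1e-12)
  }
})

test_that("edge masks threshold gradients and repair isolated zeros", {
  d <- c(10, 10, 10)
  bm <- array(TRUE, d)
  expect_warning(em0 <- build_edge_masks(array(1, d), bm), "constant")
  expect_equal(em0$mx, array(1, d))
  # a sparse spike far above alpha_s: zeros exactly at its x-edges in mx
  x <- array(0, d)
  x[5, 5, 5] <- 1 # sd_pop ~ 0.032, alpha ~ 0.13, edge gradient 1
  em <- build_edge_masks(x, bm, rule = "sd4")
  expect_equal(em$mx[4, 5, 5], 0)
  expect_equal(em$mx[5, 5, 5], 0)
  expect_equal(sum(em$mx == 0), 2)
  expect_equal(sum(em$my == 0), 2)
  # the in-vivo rule yields a positive threshold and the same zeros
  em2 <- build_edge_masks(x, bm, rule = "mean_abs_grad")
  expect_gt(em2$alpha, 0)
  expect_equal(em2$mx[4, 5, 5], 0)
  # an artificially isolated zero flips back to one
  m <- array(1, d)
  m[4, 4, 4] <- 0
  expect_equal(mudick:::repair_isolated_zeros(m), array(1, d))
  m2 <- array(1, d)
  m2[4:5, 4, 4] <- 0 # 6-connected pair survives
  expect_equal(mudick:::repair_isolated_zeros(m2), m2)
})

test_that("masked-L1 solve matches an independent accelerated proximal oracle", {
  set.seed(8)
  d <- c(6, 6, 6)
  n <- prod(d)
  kern <- make_dipole_kernel(d, 1)
  m_nma <- make_magic_angle_mask(kern, 0.1)
  chi_l <- array(rnorm(n, sd = 0.05), d)
  edges <- list(
    mx = array(rbinom(n, 1, 0.9), d),
    my = array(rbinom(n, 1, 0.9), d),
    mz = array(rbinom(n, 1, 0.9), d)
  )
  lambda <- 0.02
  eps <- 1e-3
  cfg <- recon_config(max_iter = 5000, grad_tol = 1e-11, l1_eps = eps)
  got <- solve_masked_l1(chi_l, m_nma, c(edges, list(alpha = 1)), lambda, cfg)
  # dense oracle on the same smoothed objective
  Dm <- as.vector(m_nma) * dense_operator(function(v) fft(array(v, d)), n,
                                          complex = TRUE)
  Gs <- lapply(1:3, function(ax) dense_gradient(d, ax))
  ms <- lapply(edges, as.vector)
  x_or <- fista_l1_dense(Dm, Dm %*% as.vector(chi_l), cw = 1 / n, Gs, ms,
                         lambda, eps, x0 = as.vector(chi_l),
                         n_iter = 20000)
  expect_lt(max(abs(as.vector(got) - x_or)), 1e-4)
})

test_that("masked-L1 solve reduces to the pre-estimate in degenerate cases", {
  set.seed(9)
  d <- c(12, 12, 12)
  chi_l <- array(rnorm(prod(d), sd = 0.05), d)
  ones <- array(1, d)
  zeros <- array(0, d)
  cfg <- recon_config(max_iter = 300, grad_tol = 1e-9)
  # full data support, negligible penalty: init is already the optimum
  out1 <- solve_masked_l1(chi_l, ones, list(mx = ones, my = ones, mz = ones,
                                            alpha = 1), 1e-12, cfg)
  expect_equal(as.vector(out1), as.vector(chi_l), tolerance = 1e-6)
  # all penalties masked out: chi_l untouched on the full data support
  out2 <- solve_masked_l1(chi_l, ones, list(mx = zeros, my = zeros,
                                            mz = zeros, alpha = 1), 0.5, cfg)
  expect_equal(as.vector(out2), as.vector(chi_l), tolerance = 1e-6)
})

test_that("MEDI-style baseline matches its dense oracle and smooths no-edge data", {
  set.seed(10)
  d <- c(6, 6, 6)
  n <- prod(d)
  kern <- make_dipole_kernel(d, 1)
  chi_true <- array(0, d)
  chi_true[3:4, 3:4, 3:4] <- 0.1
  delta <- forward_field(chi_true, kern) + array(rnorm(n, sd = 0.002), d)
  w <- array(1, d)
  mag <- array(1, d) # flat magnitude: all edges penalized
  lambda <- 3e-3
  eps <- 1e-3
  cfg <- recon_config(max_iter = 5000, grad_tol = 1e-11, l1_eps = eps)
  got <- suppressWarnings(
    medi_baseline(delta, w, mag, lambda, cfg, kern)
  )
  Dm <- dense_operator(function(v) forward_field(array(v, d), kern), n)
  Gs <- lapply(1:3, function(ax) dense_gradient(d, ax))
  ones <- list(rep(1, n), rep(1, n), rep(1, n))
  x_or <- fista_l1_dense(Dm, as.vector(delta), cw = 2, Gs, ones,
                         lambda, eps, x0 = rep(0, n), n_iter = 20000)
  expect_lt(max(abs(as.vector(got) - x_or)), 1e-4)
})

test_that("high-frequency combination is an exact convex k-space blend", {
  set.seed(11)
  d <- c(12, 12, 12)
  a <- array(rnorm(prod(d)), d)
  b <- array(rnorm(prod(d)), d)
  mh <- make_highfreq_weight(d, 1, 0.25, 5)
  expect_equal(combine_highfreq(a, b, array(0, d)), a, tolerance = 1e-12)
  expect_equal(combine_highfreq(a, b, array(1, d)), b, tolerance = 1e-12)
  expect_equal(combine_highfreq(a, a, mh), a, tolerance = 1e-12)
  # linear in both arguments
  c2 <- array(rnorm(prod(d)), d)
  expect_equal(combine_highfreq(a + c2, b, mh),
               combine_highfreq(a, b, mh) + combine_highfreq(c2, 0 * c2, mh),
               tolerance = 1e-10)
})

test_that("phase-variation weights grade local phase coherence", {
  d <- c(12, 12, 12)
  expect_equal(vol_data(phase_weight_image(array(0.7, d))), array(1, d),
               tolerance = 1e-6)
  # 0/pi checkerboard: neighbourhood SD of exp(i phi) is maximal
  idx <- as.matrix(expand.grid(1:12, 1:12, 1:12))
  chk <- array((-1)^rowSums(idx), d) # +1/-1
  phs <- (chk < 0) * pi
  w <- vol_data(phase_weight_image(array(phs, d)))
  expect_lt(max(w[2:11, 2:11, 2:11]), 0.05)
  # i.i.d. uniform phase: interior weights match a direct Monte-Carlo
  # estimate of 1 - SD(exp(i U)) over 27 samples
  set.seed(12)
  u <- array(runif(24^3, -pi, pi), c(24, 24, 24))
  wu <- vol_data(phase_weight_image(u))
  mc <- replicate(4000, {
    z <- exp(1i * runif(27, -pi, pi))
    v <- sqrt(mean(Mod(z - mean(z))^2))
    max(0, 1 - v)
  })
  expect_lt(abs(mean(wu[2:23, 2:23, 2:23]) - mean(mc)), 0.02)
})
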