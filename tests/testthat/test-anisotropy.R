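test_that("gaussian smoothing preserves constants and total mass", {
  g <- image_grid(20, 20, 1)
  const <- image2d(g, matrix(3.5, 20, 20))
  expect_equal(gaussian_smooth(const, 2)$values, const$values)
  set.seed(2)
  img <- image2d(g, matrix(runif(400), 20, 20))
  expect_equal(sum(gaussian_smooth(img, 1.7)$values), sum(img$values),
               tolerance = 1e-10)
  expect_identical(gaussian_smooth(img, 0)$values, img$values)
  expect_error(gaussian_smooth(img, -1), "non-negative")
})

test_that("smoothing a delta reproduces the sampled Gaussian kernel", {
  g <- image_grid(33, 33, 1)
  d <- matrix(0, 33, 33); d[17, 17] <- 1
  sm <- gaussian_smooth(image2d(g, d), 1.5)$values
  ref <- outer(1:33, 1:33,
               function(i, j) exp(-((i - 17)^2 + (j - 17)^2) / (2 * 1.5^2)))
  ref <- ref / sum(ref)
  expect_equal(sm[17, 17], ref[17, 17], tolerance = 1e-3)
})

test_that("structure tensor of analytic ramps matches closed forms", {
  g <- image_grid(21, 21, 1)
  # u = x: unit gradient along x only
  ramp_x <- image2d(g, matrix(rep(1:21, each = 21), 21, 21))
  J <- structure_tensor(ramp_x, sigma = 0, rho = 0)
  inner <- 5:17
  expect_equal(J$jxx[inner, inner], matrix(1, 13, 13))
  expect_equal(J$jyy[inner, inner], matrix(0, 13, 13))
  expect_equal(J$jxy[inner, inner], matrix(0, 13, 13))
  # u = x + y: equal components
  ramp_xy <- image2d(g, outer(1:21, 1:21, "+"))
  J2 <- structure_tensor(ramp_xy, 0, 0)
  expect_equal(J2$jxx[inner, inner], J2$jyy[inner, inner])
  expect_equal(J2$jxx[inner, inner], J2$jxy[inner, inner])
  # constant image: all zero
  J0 <- structure_tensor(image2d(g, 5), 1, 1)
  expect_equal(J0$jxx + abs(J0$jxy) + J0$jyy, matrix(0, 21, 21))
})

test_that("structure tensor is PSD and rotates consistently", {
  g <- image_grid(24, 24, 1)
  for (s in 1:10) {
    set.seed(s)
    J <- structure_tensor(image2d(g, matrix(runif(576), 24, 24)), 1, 2)
    eps <- 1e-12 * max(J$jxx + J$jyy)
    expect_true(all(J$jxx >= -eps), label = sprintf("jxx >= 0 (seed %d)", s))
    expect_true(all(J$jyy >= -eps))
    expect_true(all(J$jxx * J$jyy - J$jxy^2 >= -eps * (J$jxx + J$jyy + eps)))
  }
  set.seed(1)
  v <- matrix(runif(576), 24, 24)
  J <- structure_tensor(image2d(g, v), 1, 2)
  # rotating the image by 90 degrees swaps jxx and jyy
  v_rot <- t(v)[, 24:1]  # counter-clockwise rotation
  Jr <- structure_tensor(image2d(g, v_rot), 1, 2)
  expect_equal(sort(as.vector(Jr$jxx)), sort(as.vector(J$jyy)), tolerance = 1e-12)
  expect_equal(sort(as.vector(Jr$jyy)), sort(as.vector(J$jxx)), tolerance = 1e-12)
})

test_that("2x2 eigen-decomposition matches closed forms and conventions", {
  mk <- function(a, b, d) list(jxx = matrix(a), jxy = matrix(b), jyy = matrix(d))
  E <- eig_decompose(mk(2, 1, 2))
  expect_equal(c(E$mu1, E$mu2), c(3, 1))
  expect_equal(c(E$v1x, E$v1y), c(1, 1) / sqrt(2))
  E2 <- eig_decompose(mk(5, 0, 2))
  expect_equal(c(E2$mu1, E2$mu2), c(5, 2))
  expect_equal(c(E2$v1x, E2$v1y), c(1, 0))
  E0 <- eig_decompose(mk(0, 0, 0))
  expect_equal(c(E0$mu1, E0$mu2), c(0, 0))
  expect_equal(c(E0$v1x, E0$v1y), c(1, 0))  # tie-break convention
  expect_error(eig_decompose(list(jxx = matrix(1), jxy = matrix(1),
                                  jyx = matrix(2), jyy = matrix(1))),
               "symmetric")
  # random symmetric matrices against base eigen()
  set.seed(3)
  for (i in 1:20) {
    a <- rnorm(1)^2; d <- rnorm(1)^2; b <- rnorm(1)
    E <- eig_decompose(mk(a, b, d))
    ref <- eigen(matrix(c(a, b, b, d), 2, 2), symmetric = TRUE)
    expect_equal(as.numeric(c(E$mu1, E$mu2)), ref$values, tolerance = 1e-12)
    expect_equal(as.numeric(abs(E$v1x * ref$vectors[1, 1] +
                                E$v1y * ref$vectors[2, 1])), 1,
                 tolerance = 1e-10)
  }
})

test_that("edge-stopping function obeys its branch structure and limits", {
  expect_equal(edge_stopping(-1, 0.5), 1)
  expect_equal(edge_stopping(0, 0.5), 1)
  expect_equal(edge_stopping(1, 1), 1 - exp(-3.31488), tolerance = 1e-12)
  expect_equal(edge_stopping(100, 1), 3.31488e-8, tolerance = 1e-3)
  expect_error(edge_stopping(1, 0), "positive")
  expect_error(edge_stopping(1, -2), "positive")
  # non-increasing on (0, inf) (saturates at exactly 1 for tiny s in double
  # precision), strictly decreasing where representable; continuous at 0+
  s <- seq(1e-3, 10, length.out = 500)
  cv <- edge_stopping(s, 0.3)
  expect_true(all(diff(cv) <= 0))
  s_mid <- seq(0.7 * 0.3, 30 * 0.3, length.out = 200)
  expect_true(all(diff(edge_stopping(s_mid, 0.3)) < 0))
  expect_equal(edge_stopping(1e-6, 0.3), 1, tolerance = 1e-12)
})

test_that("the flux-extremum condition recovers the printed constant", {
  C <- flux_extremum_constant()
  expect_equal(C, 3.31488, tolerance = 1e-4 / 3.31488)
  expect_equal(1 - exp(-C) * (1 + 8 * C), 0, tolerance = 1e-10)
})

test_that("anisotropy tensor is identity on flat images and edge-adapted", {
  g <- image_grid(32, 32, 1)
  A <- build_anisotropy_tensor(image2d(g, 7), k = 0.5)
  expect_equal(A$axx, matrix(1, 32, 32))
  expect_equal(A$axy, matrix(0, 32, 32))
  expect_equal(A$ayy, matrix(1, 32, 32))
  # vertical step edge: penalty shrunk across (x), untouched along (y)
  step <- image2d(g, matrix(rep(c(0, 1), each = 16 * 32), 32, 32))
  A <- build_anisotropy_tensor(step, sigma = 1, rho = 1, k = 0.5)
  E <- eig_decompose(structure_tensor(step, 1, 1))
  mid <- cbind(8:24, 16)
  expect_true(all(abs(E$v1x[mid]) > 0.99))          # gradient along x
  cvals <- edge_stopping(E$mu1 / E$mu1_avg, 0.5)
  expect_equal(A$axx[mid], cvals[mid], tolerance = 1e-12)
  expect_equal(A$ayy[mid], rep(1, nrow(mid)), tolerance = 1e-10)
  # symmetric, det(A) = c everywhere
  det_A <- A$axx * A$ayy - A$axy^2
  expect_equal(det_A, edge_stopping(E$mu1 / E$mu1_avg, 0.5), tolerance = 1e-10)
  expect_identical(A$axy, A$ayx)
  expect_error(build_anisotropy_tensor(step, k = 0), "0, 1")
  expect_error(build_anisotropy_tensor(step, k = 1.5), "0, 1")
})

test_that("TV seminorm matches hand evaluations and is homogeneous", {
  expect_equal(tv_seminorm(matrix(1, 5, 5)), 0)
  expect_equal(tv_seminorm(matrix(c(0, 0, 0, 1), 2, 2)), sqrt(2))
  set.seed(4)
  u <- matrix(rnorm(100), 10, 10)
  expect_equal(tv_seminorm(-2.5 * u), 2.5 * tv_seminorm(u))
})

test_that("A2TV seminorm reduces to TV for identity and scales with c", {
  g <- image_grid(16, 16, 1)
  set.seed(5)
  u <- matrix(rnorm(256), 16, 16)
  I <- identity_anisotropy(g)
  expect_identical(a2tv_seminorm(u, I), tv_seminorm(u))
  zeroA <- anisotropy_field(matrix(0, 16, 16), matrix(0, 16, 16),
                            matrix(0, 16, 16))
  expect_equal(a2tv_seminorm(u, zeroA), 0)
  # vertical-edge image with the across-edge direction shrunk by c
  step <- matrix(rep(c(0, 1), each = 8 * 16), 16, 16)
  cA <- anisotropy_field(matrix(0.3, 16, 16), matrix(0, 16, 16),
                         matrix(1, 16, 16))
  expect_equal(a2tv_seminorm(step, cA), 0.3 * tv_seminorm(step))
  expect_error(a2tv_seminorm(matrix(0, 8, 8), I), "match")
})

test_that("valid anisotropy never increases the seminorm above plain TV", {
  g <- image_grid(20, 20, 1)
  for (s in 1:6) {
    set.seed(s)
    u <- matrix(rnorm(400), 20, 20)
    u0 <- image2d(g, matrix(runif(400), 20, 20))
    A <- build_anisotropy_tensor(u0, sigma = 1, rho = 1, k = 0.3)
    expect_lte(a2tv_seminorm(u, A), tv_seminorm(u) + 1e-10)
  }
})
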