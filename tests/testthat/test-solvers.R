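test_that("LSQR solves identity and dense systems to the normal equations", {
  g <- image_grid(4, 4, 1)
  M <- identity_model_matrix(g)
  p <- devectorize_sinogram(rnorm(16), M$geometry, M$time)
  res <- reconstruct_lsqr(M, p, n_iter = 20)
  expect_equal(vectorize_image(res$image), vectorize_sinogram(p),
               tolerance = 1e-10)
  # random overdetermined dense system vs the Moore-Penrose solution
  set.seed(12)
  A <- matrix(rnorm(40 * 25), 40, 25); b <- rnorm(40)
  x_ref <- solve(crossprod(A), crossprod(A, b))
  r <- oatv:::lsqr_core(Matrix::Matrix(A), b, 60)
  expect_lt(sqrt(sum((r$x - x_ref)^2)) / sqrt(sum(x_ref^2)), 1e-8)
})

test_that("LSQR reconstructs the noiseless 64x64 fixture accurately", {
  fx <- fixture_64()
  res <- reconstruct_lsqr(fx$M, fx$sino, n_iter = 50)
  expect_lt(rel_l2_error(fx$phantom, res$image), 0.05)
})

test_that("Tikhonov matches its closed form and limits", {
  set.seed(13)
  A <- matrix(rnorm(30 * 20), 30, 20); b <- rnorm(30)
  lam <- 0.7
  x_ref <- solve(crossprod(A) + lam * diag(20), crossprod(A, b))
  r <- oatv:::lsqr_core(Matrix::Matrix(A), b, 60, damp = sqrt(lam))
  expect_lt(sqrt(sum((r$x - x_ref)^2)) / sqrt(sum(x_ref^2)), 1e-8)
  # lam = 0 equals LSQR; huge lam crushes the solution
  fx <- tiny_system()
  p <- forward_project(fx$M, image2d(fx$grid, matrix(runif(256), 16, 16)))
  expect_equal(reconstruct_tikhonov(fx$M, p, 0, 30)$image$values,
               reconstruct_lsqr(fx$M, p, 30)$image$values)
  Mn <- normalize_model_matrix(fx$M)
  Mn$matrix <- Mn$matrix / 160  # unit-norm scale
  pn <- forward_project(Mn, image2d(fx$grid, matrix(runif(256), 16, 16)))
  crush <- reconstruct_tikhonov(Mn, pn, 1e9, 30)
  expect_lt(sqrt(sum(crush$image$values^2)),
            1e-6 * sqrt(sum(pn$values^2)))
})

test_that("unregularized TV-L1 reduces to least squares", {
  # well-posed system: identity operator, noisy disk data
  g <- image_grid(8, 8, 1)
  M <- identity_model_matrix(g)
  p <- add_projection_noise(
    forward_project(M, generate_disk_phantom(g, radius = 2.5, amplitude = 1)),
    0.1, 3)
  ls <- reconstruct_lsqr(M, p, n_iter = 50)
  cp <- reconstruct_tv_l1(M, p, mu = 0, alpha = 0, n_iter = 4000)
  expect_lt(rel_l2_error(ls$image, cp$image), 1e-3)
})

test_that("strong TV over-regularization collapses texture (cartoon limit)", {
  fx <- small_system_unit()
  ls <- reconstruct_lsqr(fx$M, fx$sino, n_iter = 100)
  over <- reconstruct_tv_l1(fx$M, fx$sino, mu = 0, alpha = 1e4, n_iter = 3000)
  expect_lte(tv_seminorm(over$image), 0.01 * tv_seminorm(ls$image))
})

test_that("the A2TV data term dominates for large lambda (LSQR limit)", {
  # tiny well-posed system: identity operator, the LS solution is the data
  g <- image_grid(8, 8, 1)
  M <- identity_model_matrix(g)
  p <- add_projection_noise(
    forward_project(M, generate_disk_phantom(g, radius = 2.5, amplitude = 1)),
    0.1, 3)
  ls <- reconstruct_lsqr(M, p, n_iter = 50)
  cp <- chambolle_pock_a2tv(M, p, identity_anisotropy(g),
                            lam = 1e6, n_iter = 10000)
  expect_lt(rel_l2_error(ls$image, cp$image), 0.01)
})

test_that("Chambolle-Pock reaches the small-instance convex optimum", {
  fx <- small_system()
  A <- fx$M$matrix; pv <- vectorize_sinogram(fx$sino)
  mu <- 0.05; alpha <- 0.2
  x_or <- oracle_tvl1(A, pv, 8, 8, mu, alpha)
  res <- reconstruct_tv_l1(fx$M, fx$sino, mu, alpha, n_iter = 20000)
  f_cp <- obj_tvl1(A, pv, 8, 8, mu, alpha, as.numeric(res$image$values))
  f_or <- obj_tvl1(A, pv, 8, 8, mu, alpha, x_or)
  expect_lt(abs(f_cp - f_or), 1e-3 * f_or)
  # fixed-tensor A2TV against the same oracle family
  u0 <- reconstruct_lsqr(fx$M, fx$sino, 30)$image
  Af <- build_anisotropy_tensor(u0, 1, 1, 0.5)
  lam <- 5
  x_or2 <- oracle_a2tv(A, pv, 8, 8, Af, lam)
  res2 <- chambolle_pock_a2tv(fx$M, fx$sino, Af, lam, n_iter = 20000)
  f_cp2 <- obj_a2tv(A, pv, 8, 8, Af, lam, as.numeric(res2$image$values))
  f_or2 <- obj_a2tv(A, pv, 8, 8, Af, lam, x_or2)
  expect_lt(abs(f_cp2 - f_or2), 1e-3 * f_or2)
  # and the solver's objective cannot exceed the LSQR point's objective
  f_ls <- obj_a2tv(A, pv, 8, 8, Af, lam,
                   as.numeric(reconstruct_lsqr(fx$M, fx$sino, 300)$image$values))
  expect_lte(f_cp2, f_ls + 1e-8 * f_ls)
})

test_that("ROF denoising of a disk matches the continuous closed form", {
  g <- image_grid(64, 64, 1)
  disk <- generate_disk_phantom(g, radius = 16, amplitude = 1)
  M <- identity_model_matrix(g)
  res <- chambolle_pock_a2tv(M, forward_project(M, disk),
                             identity_anisotropy(g), lam = 0.5, n_iter = 2000)
  co <- grid_coords(g)
  d <- sqrt(outer((co$y - mean(range(co$y)))^2,
                  (co$x - mean(range(co$x)))^2, "+"))
  drop <- mean(1 - res$image$values[d <= 8])
  expect_equal(drop, 2 / (0.5 * 16), tolerance = 0.10)
})

test_that("isotropic-limit A2TV equals plain TV reconstruction", {
  # low-contrast target: heavy smoothing keeps the structure-tensor
  # contrast near its average, so c ~ 1 everywhere at k = 1 and the
  # adaptive tensor stays near the identity
  fx <- small_system_unit()
  smooth <- gaussian_smooth(fx$phantom, 2)
  sino <- forward_project(fx$M, smooth)
  cfg <- solver_config("a2tv", lam = 5, k = 1, sigma = 3, rho = 3,
                       n_iter = 8000, n_outer = 2)
  adaptive <- reconstruct_a2tv(fx$M, sino, cfg)
  iso <- chambolle_pock_a2tv(fx$M, sino, identity_anisotropy(fx$grid),
                             lam = 5, n_iter = 4000)
  expect_lt(rel_l2_error(iso$image, adaptive$image), 0.05)
})

test_that("A2TV recovers the phantom from clean data at large lambda", {
  fx <- fixture_64()
  cfg <- solver_config("a2tv", lam = 50, k = 0.5, n_iter = 400, n_outer = 2)
  res <- reconstruct_a2tv(fx$M, fx$sino, cfg)
  expect_lt(rel_l2_error(fx$phantom, res$image), 0.05)
  # deterministic pipeline: identical config, identical output
  res2 <- reconstruct_a2tv(fx$M, fx$sino, cfg)
  expect_identical(res$image$values, res2$image$values)
})

test_that("the outer tensor alternation settles within a few rounds", {
  fx <- fixture_64()
  cfg <- solver_config("a2tv", lam = 5, k = 0.3, n_iter = 1600, n_outer = 8,
                       tol = 1e-3)
  res <- reconstruct_a2tv(fx$M, fx$sino, cfg)
  expect_true(res$converged)
  expect_lte(res$n_outer_done, 8)
})

test_that("stronger regularization never increases the TV of the solution", {
  fx <- small_system()
  tv_tvl1 <- sapply(c(0.05, 0.5, 5), function(al)
    tv_seminorm(reconstruct_tv_l1(fx$M, fx$sino, mu = 0.01, alpha = al,
                                  n_iter = 3000)$image))
  expect_true(all(diff(tv_tvl1) <= 1e-6 * tv_tvl1[-3] + 1e-9))
  tv_a2tv <- sapply(c(50, 5, 0.5), function(lam)
    tv_seminorm(chambolle_pock_a2tv(fx$M, fx$sino,
                                    identity_anisotropy(fx$grid), lam,
                                    n_iter = 3000)$image))
  expect_true(all(diff(tv_a2tv) <= 1e-6 * tv_a2tv[-3] + 1e-9))
})

test_that("power iteration matches dense SVD and grows monotonically", {
  K <- 3 * diag(7)
  est <- power_iteration_norm(function(x) K %*% x,
                              function(y) crossprod(K, y), 7, 20)
  expect_equal(est, 3, tolerance = 1e-10)
  set.seed(14)
  K <- matrix(rnorm(20 * 12), 20, 12)
  est <- power_iteration_norm(function(x) K %*% x,
                              function(y) crossprod(K, y), 12, 200)
  expect_equal(est, max(svd(K)$d), tolerance = 0.01)
  # Rayleigh estimates are non-decreasing across iteration counts
  ests <- sapply(c(2, 5, 10, 30), function(n)
    power_iteration_norm(function(x) K %*% x,
                         function(y) crossprod(K, y), 12, n, seed = 2))
  expect_true(all(diff(ests) >= -1e-12))
})

test_that("solver configuration rejects invalid parameters", {
  expect_error(solver_config("a2tv", k = 0), "0, 1")
  expect_error(solver_config("nope"), "arg")
  expect_error(solver_config("tvl1", mu = -1), "mu")
  fx <- small_system()
  expect_error(chambolle_pock_a2tv(fx$M, fx$sino,
                                   identity_anisotropy(fx$grid), lam = 0),
               "positive")
  bad <- sinogram(detection_geometry(20, 270, 3), fx$M$time, 0)
  expect_error(reconstruct_lsqr(fx$M, bad), "match")
})
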