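# Independent oracles: a Huber-smoothed version of the nonsmooth objectives
# minimized by L-BFGS-B -- a different algorithm family from the primal-dual
# solvers under test. Objective values are always compared on the true
# (nonsmooth) functionals.

huber_sum <- function(z, eps) sum(ifelse(abs(z) <= eps, z^2 / (2 * eps),
                                         abs(z) - eps / 2))
huber_grad <- function(z, eps) pmin(pmax(z / eps, -1), 1)

# min ||A x - p||^2 + mu ||dwt2 x||_1 + alpha TV(x), smoothed
oracle_tvl1 <- function(A, pv, ny, nx, mu, alpha, eps = 1e-7, maxit = 3000) {
  fn <- function(x) {
    v <- matrix(x, ny, nx); r <- as.numeric(A %*% x) - pv
    gb <- oatv:::grad_backward(v); n <- sqrt(gb$gx^2 + gb$gy^2)
    sum(r^2) + mu * huber_sum(dwt2(v), eps) + alpha * huber_sum(n, eps)
  }
  gr <- function(x) {
    v <- matrix(x, ny, nx); r <- as.numeric(A %*% x) - pv
    gb <- oatv:::grad_backward(v)
    n <- sqrt(gb$gx^2 + gb$gy^2)
    sc <- ifelse(n <= eps, 1 / eps, 1 / n)
    gtv <- oatv:::grad_backward_adjoint(gb$gx * sc, gb$gy * sc)
    2 * as.numeric(Matrix::crossprod(A, r)) +
      mu * as.numeric(idwt2(huber_grad(dwt2(v), eps))) +
      alpha * as.numeric(gtv)
  }
  o <- stats::optim(rep(0, ny * nx), fn, gr, method = "L-BFGS-B",
                    control = list(maxit = maxit, factr = 1e1))
  o$par
}

# min a2tv_seminorm(x, Af) + lam/2 ||A x - p||^2, smoothed
oracle_a2tv <- function(A, pv, ny, nx, Af, lam, eps = 1e-7, maxit = 3000) {
  fn <- function(x) {
    v <- matrix(x, ny, nx); r <- as.numeric(A %*% x) - pv
    gb <- oatv:::grad_backward(v)
    q <- oatv:::apply_anisotropy(Af, gb$gx, gb$gy)
    huber_sum(sqrt(q$qx^2 + q$qy^2), eps) + lam / 2 * sum(r^2)
  }
  gr <- function(x) {
    v <- matrix(x, ny, nx); r <- as.numeric(A %*% x) - pv
    gb <- oatv:::grad_backward(v)
    q <- oatv:::apply_anisotropy(Af, gb$gx, gb$gy)
    n <- sqrt(q$qx^2 + q$qy^2)
    sc <- ifelse(n <= eps, 1 / eps, 1 / n)
    aq <- oatv:::apply_anisotropy(Af, q$qx * sc, q$qy * sc)
    as.numeric(oatv:::grad_backward_adjoint(aq$qx, aq$qy)) +
      lam * as.numeric(Matrix::crossprod(A, r))
  }
  o <- stats::optim(rep(0, ny * nx), fn, gr, method = "L-BFGS-B",
                    control = list(maxit = maxit, factr = 1e1))
  o$par
}

# true nonsmooth objectives
obj_tvl1 <- function(A, pv, ny, nx, mu, alpha, x) {
  v <- matrix(x, ny, nx); r <- as.numeric(A %*% x) - pv
  sum(r^2) + (if (mu > 0) mu * sum(abs(dwt2(v))) else 0) + alpha * tv_seminorm(v)
}
obj_a2tv <- function(A, pv, ny, nx, Af, lam, x) {
  v <- matrix(x, ny, nx); r <- as.numeric(A %*% x) - pv
  a2tv_seminorm(v, Af) + lam / 2 * sum(r^2)
}
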