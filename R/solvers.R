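# Inversion algorithms: LSQR (plain and damped/Tikhonov), TV-L1 and A2TV
# by Chambolle-Pock primal-dual iteration, and the outer loop alternating
# A2TV solves with anisotropy-tensor updates.

#' Solver configuration
#'
#' @param method one of `"lsqr"`, `"tikhonov"`, `"tvl1"`, `"a2tv"`.
#' @param lam fidelity weight: Tikhonov penalty weight, or the weight of
#'   the data term in the A2TV objective `J(u) + lam/2 ||Mu - p||^2`
#'   (smaller `lam` = stronger regularization).
#' @param mu L1 (wavelet-sparsity) weight of the TV-L1 objective.
#' @param alpha TV weight of the TV-L1 objective.
#' @param k anisotropy parameter in `(0, 1]` (a2tv only); lower = more
#'   anisotropic.
#' @param sigma,rho structure-tensor smoothing scales in pixels.
#' @param n_iter total number of inner (primal-dual or Krylov) iterations.
#' @param n_outer number of anisotropy-tensor updates (a2tv only); the
#'   inner budget is split evenly across outer rounds.
#' @param tol relative-change early-stopping tolerance (0 disables).
#' @param seed RNG seed used by the operator-norm power iteration.
#' @return list of class `solver_config`.
#' @export
solver_config <- function(method = c("lsqr", "tikhonov", "tvl1", "a2tv"),
                          lam = 1, mu = 0, alpha = 0, k = 0.5, sigma = 1.5,
                          rho = 3, n_iter = 200L, n_outer = 5L, tol = 0,
                          seed = 1L) {
  method <- match.arg(method)
  stopifnot(lam >= 0, mu >= 0, alpha >= 0, n_iter >= 1, n_outer >= 1, tol >= 0)
  if (method == "a2tv" && (k <= 0 || k > 1)) stop("k must be in (0, 1]")
  structure(list(method = method, lam = lam, mu = mu, alpha = alpha, k = k,
                 sigma = sigma, rho = rho, n_iter = as.integer(n_iter),
                 n_outer = as.integer(n_outer), tol = tol,
                 seed = as.integer(seed)),
            class = "solver_config")
}

recon_result <- function(image, objective_trace, n_outer_done = 1L,
                         converged = FALSE, config = NULL) {
  structure(list(image = image, objective_trace = objective_trace,
                 n_outer_done = n_outer_done, converged = converged,
                 config = config),
            class = "recon_result")
}

#' @export
print.recon_result <- function(x, ...) {
  obj <- x$objective_trace
  cat(sprintf("<recon_result> %d x %d image, %d objective samples%s%s\n",
              x$image$grid$ny, x$image$grid$nx, length(obj),
              if (length(obj)) sprintf(", final objective %.6g", obj[length(obj)]) else "",
              if (isTRUE(x$converged)) ", converged" else ""))
  invisible(x)
}

#' Operator 2-norm by power iteration
#'
#' Estimates `||K||_2` of a linear operator given as an apply/adjoint pair
#' by power iteration on `K^T K` from a random start. The Rayleigh
#' estimate is non-decreasing over iterations and matches the largest
#' singular value within about 1% on well-separated spectra.
#'
#' @param apply_fn function computing `K x`.
#' @param adjoint_fn function computing `K^T y`.
#' @param n length of the primal vector `x`.
#' @param n_iter number of power iterations (default 50).
#' @param seed RNG seed for the start vector.
#' @return scalar estimate of the spectral norm.
#' @export
power_iteration_norm <- function(apply_fn, adjoint_fn, n, n_iter = 50L,
                                 seed = 1L) {
  x <- with_local_seed(seed, stats::rnorm(n))
  x <- x / sqrt(sum(x^2))
  est <- 0
  for (i in seq_len(n_iter)) {
    y <- adjoint_fn(apply_fn(x))
    nrm <- sqrt(sum(y^2))
    if (nrm == 0) return(0)
    est <- nrm          # Rayleigh quotient of K^T K at unit x
    x <- y / nrm
  }
  sqrt(est)
}

# Golub-Kahan bidiagonalization least squares (LSQR) with optional damping:
# minimizes ||b - A x||^2 + damp^2 ||x||^2. Returns x and the per-iteration
# damped residual norms (phibar, the LSQR estimate of the augmented
# residual), which serve as the objective trace.
lsqr_core <- function(A, b, n_iter, damp = 0) {
  n <- ncol(A)
  x <- numeric(n)
  beta <- sqrt(sum(b^2))
  if (beta == 0) return(list(x = x, rnorm = numeric(0)))
  u <- b / beta
  v <- as.numeric(Matrix::crossprod(A, u))
  alpha <- sqrt(sum(v^2))
  if (alpha == 0) return(list(x = x, rnorm = numeric(0)))
  v <- v / alpha
  w <- v
  phibar <- beta; rhobar <- alpha
  rnorm <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    u <- as.numeric(A %*% v) - alpha * u
    beta <- sqrt(sum(u^2))
    if (beta > 0) u <- u / beta
    v <- as.numeric(Matrix::crossprod(A, u)) - beta * v
    alpha <- sqrt(sum(v^2))
    if (alpha > 0) v <- v / alpha
    # eliminate damping, then the lower bidiagonal entry
    rhobar1 <- sqrt(rhobar^2 + damp^2)
    c1 <- rhobar / rhobar1; s1 <- damp / rhobar1
    phibar <- c1 * phibar
    rho <- sqrt(rhobar1^2 + beta^2)
    cs <- rhobar1 / rho; sn <- beta / rho
    theta <- sn * alpha
    rhobar <- -cs * alpha
    phi <- cs * phibar
    phibar <- sn * phibar
    x <- x + (phi / rho) * w
    w <- v - (theta / rho) * w
    rnorm[it] <- phibar
    if (alpha == 0 || beta == 0) {  # exact Krylov solution reached
      rnorm <- rnorm[seq_len(it)]
      break
    }
  }
  list(x = x, rnorm = rnorm)
}

#' Regularization-free least-squares reconstruction (LSQR)
#'
#' Iteratively solves `argmin ||p - M u||_2^2`; with enough iterations on
#' a well-conditioned system this converges to the Moore-Penrose solution.
#'
#' @param M a [build_model_matrix()] result.
#' @param p a [sinogram()].
#' @param n_iter number of LSQR iterations (default 50).
#' @return a `recon_result`; the objective trace holds the LSQR residual
#'   norm per iteration.
#' @export
reconstruct_lsqr <- function(M, p, n_iter = 50L) {
  check_solver_inputs(M, p)
  r <- lsqr_core(M$matrix, vectorize_sinogram(p), n_iter)
  recon_result(devectorize(r$x, M$grid), r$rnorm^2,
               config = solver_config("lsqr", n_iter = n_iter))
}

#' Tikhonov-regularized reconstruction
#'
#' Solves `argmin ||p - M u||_2^2 + lam ||u||_2^2` (identity weighting
#' matrix) via damped LSQR on the augmented system `[M; sqrt(lam) I]`.
#'
#' @inheritParams reconstruct_lsqr
#' @param lam non-negative penalty weight; `lam = 0` reduces to
#'   [reconstruct_lsqr()].
#' @export
reconstruct_tikhonov <- function(M, p, lam, n_iter = 50L) {
  check_solver_inputs(M, p)
  if (lam < 0) stop("lam must be non-negative")
  r <- lsqr_core(M$matrix, vectorize_sinogram(p), n_iter, damp = sqrt(lam))
  recon_result(devectorize(r$x, M$grid), r$rnorm^2,
               config = solver_config("tikhonov", lam = lam, n_iter = n_iter))
}

check_solver_inputs <- function(M, p) {
  stopifnot(inherits(M, "model_matrix"), inherits(p, "sinogram"))
  if (length(vectorize_sinogram(p)) != nrow(M$matrix))
    stop(sprintf("sinogram length %d does not match matrix rows %d",
                 length(vectorize_sinogram(p)), nrow(M$matrix)))
  invisible(TRUE)
}

#' TV-L1 regularized reconstruction
#'
#' Chambolle-Pock primal-dual solution of
#' `argmin ||p - M u||_2^2 + mu ||Phi u||_1 + alpha ||u||_TV`
#' with `Phi` the orthonormal periodic Daubechies-4 wavelet transform
#' ([dwt2()]). All three terms are dualized over the stacked operator
#' `[grad; Phi; M]`; step sizes obey `sigma tau ||K||^2 < 1` with the norm
#' from [power_iteration_norm()].
#'
#' @inheritParams reconstruct_lsqr
#' @param mu wavelet-sparsity weight (>= 0; 0 disables the wavelet term,
#'   lifting the dyadic-grid requirement).
#' @param alpha TV weight (>= 0).
#' @param n_iter primal-dual iterations (default 200).
#' @param tol early stop when the relative change of `u` between objective
#'   checks falls below `tol` (0 disables).
#' @param seed seed for the operator-norm power iteration.
#' @return a `recon_result` with the objective sampled every 10 iterations.
#' @export
reconstruct_tv_l1 <- function(M, p, mu, alpha, n_iter = 200L, tol = 0,
                              seed = 1L) {
  check_solver_inputs(M, p)
  if (mu < 0 || alpha < 0) stop("mu and alpha must be non-negative")
  grid <- M$grid; ny <- grid$ny; nx <- grid$nx
  if (mu > 0) { check_dyadic(ny); check_dyadic(nx) }
  A <- M$matrix
  pv <- vectorize_sinogram(p)
  to_mat <- function(x) matrix(x, ny, nx)
  Kt_norm_apply <- function(x) {
    v <- to_mat(x)
    g <- grad_backward(v)
    out <- grad_backward_adjoint(g$gx, g$gy)
    if (mu > 0) out <- out + idwt2(dwt2(v))
    as.numeric(out) + as.numeric(Matrix::crossprod(A, A %*% x))
  }
  # Kt_norm_apply is K^T K, so the power iteration returns ||K|| directly
  L <- max(power_iteration_norm(Kt_norm_apply, identity, ny * nx,
                                n_iter = 30L, seed = seed),
           .Machine$double.eps)
  sg <- 0.99 / L; tau <- 0.99 / L
  u <- matrix(0, ny, nx); ubar <- u
  q1x <- u; q1y <- u
  q2 <- if (mu > 0) u else NULL
  q3 <- numeric(length(pv))
  objective <- function(v) {
    r <- as.numeric(A %*% as.numeric(v)) - pv
    sum(r^2) + (if (mu > 0) mu * sum(abs(dwt2(v))) else 0) +
      (if (alpha > 0) alpha * tv_seminorm(v) else 0)
  }
  trace <- numeric(0)
  u_prev_check <- u
  converged <- FALSE
  for (it in seq_len(n_iter)) {
    g <- grad_backward(ubar)
    q1x <- q1x + sg * g$gx; q1y <- q1y + sg * g$gy
    nrm <- pmax(1, sqrt(q1x^2 + q1y^2) / max(alpha, .Machine$double.xmin))
    q1x <- q1x / nrm; q1y <- q1y / nrm
    if (alpha == 0) { q1x[] <- 0; q1y[] <- 0 }
    if (mu > 0) q2 <- pmin(pmax(q2 + sg * dwt2(ubar), -mu), mu)
    q3 <- (q3 + sg * (as.numeric(A %*% as.numeric(ubar)) - pv)) / (1 + sg / 2)
    kt <- grad_backward_adjoint(q1x, q1y)
    if (mu > 0) kt <- kt + idwt2(q2)
    kt <- kt + to_mat(as.numeric(Matrix::crossprod(A, q3)))
    u_new <- u - tau * kt
    ubar <- 2 * u_new - u
    u <- u_new
    if (it %% 10L == 0L || it == n_iter) {
      trace <- c(trace, objective(u))
      if (tol > 0) {
        rel <- sqrt(sum((u - u_prev_check)^2)) / max(sqrt(sum(u^2)), 1e-300)
        u_prev_check <- u
        if (rel < tol) { converged <- TRUE; break }
      }
    }
  }
  recon_result(image2d(grid, u), trace, converged = converged,
               config = solver_config("tvl1", mu = mu, alpha = alpha,
                                      n_iter = n_iter, tol = tol, seed = seed))
}

#' Chambolle-Pock solver for the A2TV problem with a fixed tensor
#'
#' Minimizes the convex functional
#' `J_A2TV(u) + lam/2 ||M u - p||_2^2` for a fixed anisotropy field `A`,
#' by primal-dual iteration on the stacked operator `K = [A grad; M]` with
#' the dual of the pointwise 2,1-norm (unit-disk projection) and of the
#' quadratic fidelity. Step sizes `sigma = tau = 0.99 / ||K||`.
#'
#' @inheritParams reconstruct_lsqr
#' @param A an [anisotropy_field()] on the matrix grid.
#' @param lam positive fidelity weight.
#' @param n_iter primal-dual iterations.
#' @param tol relative-change early stop (0 disables).
#' @param seed seed for the power iteration.
#' @return a `recon_result` with the objective sampled every 10 iterations.
#' @export
chambolle_pock_a2tv <- function(M, p, A, lam, n_iter = 200L, tol = 0,
                                seed = 1L) {
  check_solver_inputs(M, p)
  stopifnot(inherits(A, "anisotropy_field"))
  if (lam <= 0) stop("lam must be positive")
  grid <- M$grid; ny <- grid$ny; nx <- grid$nx
  if (!all(dim(A$axx) == c(ny, nx)))
    stop("anisotropy field does not match the matrix grid")
  Am <- M$matrix
  pv <- vectorize_sinogram(p)
  to_mat <- function(x) matrix(x, ny, nx)
  KtK <- function(x) {
    v <- to_mat(x)
    g <- grad_backward(v)
    q <- apply_anisotropy(A, g$gx, g$gy)
    q <- apply_anisotropy(A, q$qx, q$qy)
    as.numeric(grad_backward_adjoint(q$qx, q$qy)) +
      as.numeric(Matrix::crossprod(Am, Am %*% x))
  }
  L <- max(power_iteration_norm(KtK, identity, ny * nx,
                                n_iter = 30L, seed = seed),
           .Machine$double.eps)
  sg <- 0.99 / L; tau <- 0.99 / L
  u <- matrix(0, ny, nx); ubar <- u
  q1x <- u; q1y <- u
  q2 <- numeric(length(pv))
  trace <- numeric(0)
  u_prev_check <- u
  converged <- FALSE
  for (it in seq_len(n_iter)) {
    g <- grad_backward(ubar)
    ag <- apply_anisotropy(A, g$gx, g$gy)
    q1x <- q1x + sg * ag$qx; q1y <- q1y + sg * ag$qy
    nrm <- pmax(1, sqrt(q1x^2 + q1y^2))
    q1x <- q1x / nrm; q1y <- q1y / nrm
    q2 <- (q2 + sg * (as.numeric(Am %*% as.numeric(ubar)) - pv)) / (1 + sg / lam)
    aq <- apply_anisotropy(A, q1x, q1y)
    kt <- grad_backward_adjoint(aq$qx, aq$qy) +
      to_mat(as.numeric(Matrix::crossprod(Am, q2)))
    u_new <- u - tau * kt
    ubar <- 2 * u_new - u
    u <- u_new
    if (it %% 10L == 0L || it == n_iter) {
      r <- as.numeric(Am %*% as.numeric(u)) - pv
      trace <- c(trace, a2tv_seminorm(u, A) + lam / 2 * sum(r^2))
      if (tol > 0) {
        rel <- sqrt(sum((u - u_prev_check)^2)) / max(sqrt(sum(u^2)), 1e-300)
        u_prev_check <- u
        if (rel < tol) { converged <- TRUE; break }
      }
    }
  }
  recon_result(image2d(grid, u), trace, converged = converged,
               config = solver_config("a2tv", lam = lam, n_iter = n_iter,
                                      tol = tol, seed = seed))
}

#' A2TV reconstruction with alternating tensor updates
#'
#' Outer loop of the adaptive anisotropic TV inversion: the tensor starts
#' as the identity (isotropic TV), the convex problem is solved with
#' [chambolle_pock_a2tv()], the tensor is rebuilt from the solution with
#' [build_anisotropy_tensor()], and the two steps alternate until the
#' relative change of the image falls below `config$tol` or `n_outer`
#' rounds complete. The inner iteration budget `n_iter` is split evenly
#' across the outer rounds. The adaptive problem is not jointly convex, so
#' convergence of the alternation is heuristic — but robust in practice.
#'
#' @inheritParams reconstruct_lsqr
#' @param config a [solver_config()] with `method = "a2tv"`; uses `lam`,
#'   `k`, `sigma`, `rho`, `n_iter`, `n_outer`, `tol`, `seed`.
#' @return a `recon_result`; the objective trace concatenates the inner
#'   traces (each outer round changes the functional, so small upward
#'   jumps at round boundaries are expected).
#' @export
reconstruct_a2tv <- function(M, p, config = solver_config("a2tv")) {
  check_solver_inputs(M, p)
  stopifnot(inherits(config, "solver_config"))
  if (config$k <= 0 || config$k > 1) stop("k must be in (0, 1]")
  inner <- max(1L, config$n_iter %/% config$n_outer)
  A <- identity_anisotropy(M$grid)
  u_prev <- NULL
  trace <- numeric(0)
  converged <- FALSE
  done <- 0L
  for (j in seq_len(config$n_outer)) {
    res <- chambolle_pock_a2tv(M, p, A, config$lam, n_iter = inner,
                               tol = 0, seed = config$seed)
    trace <- c(trace, res$objective_trace)
    done <- j
    u <- res$image
    if (!is.null(u_prev) && config$tol > 0) {
      rel <- sqrt(sum((u$values - u_prev$values)^2)) /
        max(sqrt(sum(u_prev$values^2)), 1e-300)
      if (rel < config$tol) { converged <- TRUE; u_prev <- u; break }
    }
    u_prev <- u
    if (j < config$n_outer)
      A <- build_anisotropy_tensor(u, sigma = config$sigma, rho = config$rho,
                                   k = config$k)
  }
  recon_result(u_prev, trace, n_outer_done = done, converged = converged,
               config = config)
}
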