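# Adaptive anisotropic TV machinery: discrete TV, structure tensor,
# per-pixel 2x2 eigen-decomposition, Weickert-type edge-stopping function,
# and the adaptive tensor A(x) that weights the gradient in the A2TV
# functional J(u) = sum ||A(x) grad u(x)||_2.

#' Gaussian smoothing with reflective boundary
#'
#' Separable Gaussian convolution (kernel truncated at 4 standard
#' deviations, renormalized) with symmetric (edge-reflect) padding, which
#' preserves the total image sum exactly. `std = 0` returns the image
#' unchanged.
#'
#' @param img an [image2d()].
#' @param std kernel standard deviation in pixels, non-negative.
#' @return the smoothed [image2d()].
#' @export
gaussian_smooth <- function(img, std) {
  stopifnot(inherits(img, "image2d"))
  if (std < 0) stop("std must be non-negative")
  if (std == 0) return(img)
  r <- max(1L, ceiling(4 * std))
  k <- exp(-(-r:r)^2 / (2 * std^2))
  k <- k / sum(k)
  image2d(img$grid, conv_sep_reflect(img$values, k, r))
}

# separable convolution with symmetric (repeat-edge reflect) padding
conv_sep_reflect <- function(v, k, r) {
  # triangle-wave fold of arbitrary indices into [1, n] (symmetric
  # padding); handles kernels wider than the image
  reflect_idx <- function(n) {
    idx <- (1L - r):(n + r)
    m <- (idx - 1L) %% (2L * n)
    ifelse(m < n, m + 1L, 2L * n - m)
  }
  ny <- nrow(v); nx <- ncol(v)
  ri <- reflect_idx(ny)
  out <- matrix(0, ny, nx)
  pv <- v[ri, , drop = FALSE]
  for (o in seq_along(k)) out <- out + k[o] * pv[o:(o + ny - 1L), , drop = FALSE]
  ci <- reflect_idx(nx)
  pv <- out[, ci, drop = FALSE]
  out <- matrix(0, ny, nx)
  for (o in seq_along(k)) out <- out + k[o] * pv[, o:(o + nx - 1L), drop = FALSE]
  out
}

# backward-difference gradient (the TV stencil): out-of-range neighbor
# differences are zero, i.e. the first row/column of each component is 0
grad_backward <- function(v) {
  ny <- nrow(v); nx <- ncol(v)
  gx <- matrix(0, ny, nx); gy <- matrix(0, ny, nx)
  gx[, 2:nx] <- v[, 2:nx, drop = FALSE] - v[, 1:(nx - 1L), drop = FALSE]
  gy[2:ny, ] <- v[2:ny, , drop = FALSE] - v[1:(ny - 1L), , drop = FALSE]
  list(gx = gx, gy = gy)
}

# exact adjoint of grad_backward: <grad u, q> = <u, grad_adjoint(q)>
grad_backward_adjoint <- function(qx, qy) {
  ny <- nrow(qx); nx <- ncol(qx)
  qx[, 1L] <- 0; qy[1L, ] <- 0
  out <- qx + qy
  out[, 1:(nx - 1L)] <- out[, 1:(nx - 1L), drop = FALSE] - qx[, 2:nx, drop = FALSE]
  out[1:(ny - 1L), ] <- out[1:(ny - 1L), , drop = FALSE] - qy[2:ny, , drop = FALSE]
  out
}

# central-difference gradient with replicate boundary (structure tensor)
grad_central <- function(v) {
  ny <- nrow(v); nx <- ncol(v)
  jl <- c(1L, 1:(nx - 1L)); jr <- c(2:nx, nx)
  il <- c(1L, 1:(ny - 1L)); ir <- c(2:ny, ny)
  list(gx = (v[, jr, drop = FALSE] - v[, jl, drop = FALSE]) / 2,
       gy = (v[ir, , drop = FALSE] - v[il, , drop = FALSE]) / 2)
}

#' Structure tensor of an image
#'
#' Smooths the image with a Gaussian of std `sigma`, forms the outer
#' product of its central-difference gradient, and smooths each tensor
#' component with a Gaussian of std `rho`. The result is a symmetric
#' positive-semidefinite 2x2 tensor per pixel whose leading eigenvector
#' gives the local gradient (across-edge) direction and whose eigenvalues
#' measure local contrast.
#'
#' @param u0 an [image2d()] (the current reconstruction estimate).
#' @param sigma pre-smoothing std in pixels (noise scale).
#' @param rho post-smoothing std in pixels (integration scale).
#' @return object of class `structure_tensor_field` with components
#'   `jxx`, `jxy`, `jyy` and the smoothing scales.
#' @export
structure_tensor <- function(u0, sigma = 1.5, rho = 3) {
  stopifnot(inherits(u0, "image2d"))
  if (sigma < 0 || rho < 0) stop("sigma and rho must be non-negative")
  us <- gaussian_smooth(u0, sigma)
  g <- grad_central(us$values)
  sm <- function(m) {
    if (rho == 0) return(m)
    r <- max(1L, ceiling(4 * rho))
    k <- exp(-(-r:r)^2 / (2 * rho^2)); k <- k / sum(k)
    conv_sep_reflect(m, k, r)
  }
  structure(list(jxx = sm(g$gx^2), jxy = sm(g$gx * g$gy), jyy = sm(g$gy^2),
                 sigma = sigma, rho = rho, grid = u0$grid),
            class = "structure_tensor_field")
}

#' Per-pixel eigen-decomposition of a structure tensor field
#'
#' Closed-form symmetric 2x2 eigen-decomposition. Eigenvalues are sorted
#' `mu1 >= mu2`; `v1` is the unit eigenvector of `mu1` with its first
#' nonzero component made positive. Near-isotropic pixels (eigenvalue gap
#' below `1e-12 * (mu1 + mu2 + eps)`) get the conventional `v1 = (1, 0)`.
#'
#' @param J a [structure_tensor()] result (or any list with symmetric
#'   components `jxx`, `jxy`, `jyy`; a differing `jyx` is rejected).
#' @return object of class `eigen_field` with `mu1`, `mu2`, `v1x`, `v1y`
#'   and the scalar `mu1_avg = mean(mu1)`.
#' @export
eig_decompose <- function(J) {
  if (!is.null(J$jyx) && !isTRUE(all.equal(J$jyx, J$jxy)))
    stop("structure tensor must be symmetric (jyx must equal jxy)")
  jxx <- J$jxx; jxy <- J$jxy; jyy <- J$jyy
  tr <- jxx + jyy
  disc <- sqrt(pmax((jxx - jyy)^2 + 4 * jxy^2, 0))
  mu1 <- (tr + disc) / 2
  mu2 <- (tr - disc) / 2
  # eigenvector of mu1: pick the numerically larger of the two candidate
  # forms (jxy, mu1 - jxx) and (mu1 - jyy, jxy)
  ax <- jxy; ay <- mu1 - jxx
  bx <- mu1 - jyy; by <- jxy
  use_b <- (bx^2 + by^2) > (ax^2 + ay^2)
  vx <- ifelse(use_b, bx, ax); vy <- ifelse(use_b, by, ay)
  nrm <- sqrt(vx^2 + vy^2)
  iso <- (mu1 - mu2) <= 1e-12 * (mu1 + mu2 + .Machine$double.eps) | nrm == 0
  nrm[iso] <- 1
  vx <- vx / nrm; vy <- vy / nrm
  vx[iso] <- 1; vy[iso] <- 0
  # sign convention: first nonzero component positive
  flip <- vx < 0 | (vx == 0 & vy < 0)
  vx[flip] <- -vx[flip]; vy[flip] <- -vy[flip]
  structure(list(mu1 = mu1, mu2 = mu2, v1x = vx, v1y = vy,
                 mu1_avg = mean(mu1)),
            class = "eigen_field")
}

# constant recommended for the exponential edge-stopping function
weickert_cm <- 3.31488

#' Constant of the exponential edge-stopping function
#'
#' Solves the flux-extremum condition `1 - exp(-C) (1 + 8C) = 0` for
#' `C > 0` by root bracketing. With exponent `m = 4` acting on the
#' quadratic contrast, this construction yields the recommended constant
#' `c_m = 3.31488` used by [edge_stopping()].
#'
#' @param lower,upper bracketing interval (default `(0.1, 20)`).
#' @param tol root tolerance.
#' @return the positive root `C`.
#' @export
flux_extremum_constant <- function(lower = 0.1, upper = 20, tol = 1e-12) {
  stats::uniroot(function(C) 1 - exp(-C) * (1 + 8 * C),
                 c(lower, upper), tol = tol)$root
}

#' Edge-stopping function
#'
#' Weickert-type diffusivity mapping a normalized quadratic contrast `s`
#' to a regularization weight in `(0, 1]`:
#' `c(s; k) = 1` for `s <= 0` and `1 - exp(-c_m (s/k)^(-m))` for `s > 0`.
#' It is continuous at `0+`, strictly decreasing on `(0, Inf)`, close to 1
#' where `s << k` (contrast well below the anisotropy threshold) and close
#' to 0 where `s >> k` (dominant edges).
#'
#' @param s contrast value(s), any sign; vectorized.
#' @param k anisotropy threshold, positive.
#' @param cm,m constants of the exponential form (defaults 3.31488 and 4).
#' @return value(s) in `(0, 1]`.
#' @export
edge_stopping <- function(s, k, cm = weickert_cm, m = 4) {
  if (k <= 0) stop("k must be positive")
  out <- rep(1, length(s))
  pos <- s > 0
  out[pos] <- 1 - exp(-cm * (s[pos] / k)^(-m))
  dim(out) <- dim(s)
  out
}

#' Per-pixel anisotropy tensor field
#'
#' Container for a symmetric 2x2 tensor per pixel. Use
#' [build_anisotropy_tensor()] to construct it from an image; this raw
#' constructor only checks shapes.
#'
#' @param axx,axy,ayy tensor components (`ny x nx` matrices).
#' @param k anisotropy parameter the field was built with (or `NA`).
#' @param grid the [image_grid()] the field lives on (or `NULL`).
#' @return object of class `anisotropy_field`; `ayx` mirrors `axy`.
#' @export
anisotropy_field <- function(axx, axy, ayy, k = NA_real_, grid = NULL) {
  stopifnot(all(dim(axx) == dim(axy)), all(dim(axx) == dim(ayy)))
  structure(list(axx = axx, axy = axy, ayx = axy, ayy = ayy, k = k,
                 grid = grid),
            class = "anisotropy_field")
}

#' Identity anisotropy field on a grid
#' @param grid an [image_grid()].
#' @return an [anisotropy_field()] equal to the identity at every pixel,
#'   for which the A2TV seminorm reduces exactly to isotropic TV.
#' @export
identity_anisotropy <- function(grid) {
  one <- matrix(1, grid$ny, grid$nx); zero <- matrix(0, grid$ny, grid$nx)
  anisotropy_field(one, zero, one, k = 1, grid = grid)
}

#' Build the adaptive anisotropy tensor from an image estimate
#'
#' Per pixel, `A = V diag(c(mu1 / mu1_avg; k), 1) V^T` where `(mu1, v1)`
#' is the leading eigenpair of the structure tensor of `u0` and `c` is the
#' [edge_stopping()] function: the penalty across a detected edge is
#' shrunk by `c < 1` while the penalty along it stays 1. On a constant
#' image (`mu1_avg = 0`) the field is the identity everywhere, recovering
#' isotropic TV.
#'
#' @param u0 an [image2d()] estimate of the reconstruction.
#' @param sigma,rho structure-tensor smoothing scales in pixels.
#' @param k anisotropy parameter in `(0, 1]`; lower values mean stronger
#'   anisotropy (more pixels treated as edges).
#' @param cm,m edge-stopping constants.
#' @return an [anisotropy_field()]; per pixel `A` is symmetric with
#'   eigenvalues `{c, 1}` in `(0, 1]` and `det(A) = c`.
#' @export
build_anisotropy_tensor <- function(u0, sigma = 1.5, rho = 3, k = 0.5,
                                    cm = weickert_cm, m = 4) {
  stopifnot(inherits(u0, "image2d"))
  if (k <= 0 || k > 1) stop("k must be in (0, 1]")
  E <- eig_decompose(structure_tensor(u0, sigma, rho))
  if (E$mu1_avg <= 0) return(identity_anisotropy(u0$grid))
  cvals <- edge_stopping(E$mu1 / E$mu1_avg, k, cm = cm, m = m)
  # A = I + (c - 1) v1 v1^T  (v2 orthogonal to v1 keeps eigenvalue 1)
  d <- cvals - 1
  anisotropy_field(1 + d * E$v1x^2, d * E$v1x * E$v1y, 1 + d * E$v1y^2,
                   k = k, grid = u0$grid)
}

# apply the tensor to a gradient field
apply_anisotropy <- function(A, gx, gy) {
  list(qx = A$axx * gx + A$axy * gy, qy = A$axy * gx + A$ayy * gy)
}

#' Isotropic discrete total-variation seminorm
#'
#' `TV(u) = sum_p sqrt(dx(p)^2 + dy(p)^2)` with backward differences and
#' out-of-range neighbor differences treated as zero.
#'
#' @param u an [image2d()] or a numeric matrix.
#' @return non-negative scalar.
#' @export
tv_seminorm <- function(u) {
  v <- if (inherits(u, "image2d")) u$values else as.matrix(u)
  g <- grad_backward(v)
  sum(sqrt(g$gx^2 + g$gy^2))
}

#' Adaptive anisotropic TV seminorm
#'
#' `sum_p ||A(p) g(p)||_2` with the same backward-difference gradient `g`
#' as [tv_seminorm()]; with an identity field the two agree exactly.
#'
#' @param u an [image2d()] or numeric matrix.
#' @param A an [anisotropy_field()] on the same grid.
#' @return non-negative scalar.
#' @export
a2tv_seminorm <- function(u, A) {
  v <- if (inherits(u, "image2d")) u$values else as.matrix(u)
  stopifnot(inherits(A, "anisotropy_field"))
  if (!all(dim(v) == dim(A$axx)))
    stop("anisotropy field does not match the image grid")
  g <- grad_backward(v)
  q <- apply_anisotropy(A, g$gx, g$gy)
  sum(sqrt(q$qx^2 + q$qy^2))
}
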