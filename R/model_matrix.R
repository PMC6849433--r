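#' Circular arc integral of a bilinearly interpolated image
#'
#' Computes `(1/radius) * \int u dl` over the circle of radius `radius`
#' about `center`, with the image extended by zero outside the convex hull
#' of its pixel centers. This is the inner (spherical-mean) integral of the
#' optoacoustic forward solution, before the time derivative, and serves as
#' the matrix-free oracle for the system matrix: both use the identical
#' uniform angular quadrature with arc-length step `pixel_size /
#' samples_per_pixel` on the global lattice `theta_i = 2 pi i / n_theta`.
#'
#' @param img an [image2d()].
#' @param center circle center (mm, 2-vector).
#' @param radius circle radius (mm), positive.
#' @param samples_per_pixel quadrature density: number of arc samples per
#'   pixel side length (default 16).
#' @param n_theta optional explicit number of angular nodes, overriding the
#'   density rule; the matrix builder passes one shared lattice for all
#'   radii of a detector so that nodes move smoothly with the radius.
#' @return scalar value of the normalized arc integral.
#' @export
arc_integral <- function(img, center, radius, samples_per_pixel = 16,
                         n_theta = NULL) {
  stopifnot(inherits(img, "image2d"))
  if (radius <= 0) stop("radius must be positive")
  g <- img$grid
  ps <- g$pixel_size
  if (is.null(n_theta))
    n_theta <- max(8, ceiling(2 * pi * radius * samples_per_pixel / ps))
  th <- 2 * pi * (seq_len(n_theta) - 1L) / n_theta
  px <- center[1] + radius * cos(th)
  py <- center[2] + radius * sin(th)
  gx <- (px - g$origin[1]) / ps
  gy <- (py - g$origin[2]) / ps
  ok <- gx >= 0 & gx <= g$nx - 1 & gy >= 0 & gy <= g$ny - 1
  if (!any(ok)) return(0)
  gx <- gx[ok]; gy <- gy[ok]
  ix <- pmin(floor(gx), g$nx - 2); iy <- pmin(floor(gy), g$ny - 2)
  fx <- gx - ix; fy <- gy - iy
  v <- img$values
  i1 <- iy + 1L; j1 <- ix + 1L  # 1-based matrix indices
  val <- v[cbind(i1, j1)] * (1 - fx) * (1 - fy) +
         v[cbind(i1 + 1L, j1)] * (1 - fx) * fy +
         v[cbind(i1, j1 + 1L)] * fx * (1 - fy) +
         v[cbind(i1 + 1L, j1 + 1L)] * fx * fy
  (2 * pi / n_theta) * sum(val)
}

# Second-order time-derivative stencil, nt x nt sparse: central differences
# in the interior, one-sided second-order stencils at the block ends.
time_derivative_stencil <- function(nt, dt) {
  i <- c(rep(2:(nt - 1L), 2L), 1L, 1L, 1L, nt, nt, nt)
  j <- c(1:(nt - 2L), 3:nt, 1L, 2L, 3L, nt - 2L, nt - 1L, nt)
  v <- c(rep(-1, nt - 2L), rep(1, nt - 2L), -3, 4, -1, 1, -4, 3) / (2 * dt)
  Matrix::sparseMatrix(i = i, j = j, x = v, dims = c(nt, nt))
}

#' Build the sparse optoacoustic model matrix
#'
#' Constructs the discrete forward operator `M` mapping a column-vectorized
#' image to the detector-major vectorized sinogram, `p = M u`. For each
#' detector `d` and sample time `t_j`, the pre-derivative row holds
#' bilinear-interpolation weights of the circle `|r - r_d| = c t_j`, scaled
#' by `1 / (c t_j)` (the spherical-spreading factor, constant on the arc);
#' the rows are then composed with a second-order time-derivative stencil
#' within each detector's time block. The Grueneisen/fluence amplitude is an
#' arbitrary global constant of 1 — reconstructions are in arbitrary units.
#'
#' @param grid an [image_grid()].
#' @param geometry a [detection_geometry()] whose arc encloses the grid.
#' @param time a [time_axis()]; defaults to [default_time_axis()].
#' @param samples_per_pixel arc quadrature density (default 16).
#' @return An object of class `model_matrix`: fields `matrix` (a
#'   `dgCMatrix` of size `(n_detectors*nt) x (nx*ny)`), provenance `grid`,
#'   `geometry`, `time`, `samples_per_pixel`, and the applied normalization
#'   factor `scale` (1 until [normalize_model_matrix()] is used).
#' @export
build_model_matrix <- function(grid, geometry, time = NULL, samples_per_pixel = 16) {
  stopifnot(inherits(grid, "image_grid"), inherits(geometry, "detection_geometry"))
  check_geometry_encloses(geometry, grid)
  if (is.null(time)) time <- default_time_axis(grid, geometry)
  radii_mm <- time$c * times(time) * 1e3
  n_theta <- arc_lattice_size(max(radii_mm), grid$pixel_size, samples_per_pixel)
  trip <- cpp_arc_matrix(grid$nx, grid$ny, grid$origin[1], grid$origin[2],
                         grid$pixel_size, geometry$det_x, geometry$det_y,
                         radii_mm, n_theta)
  n_rows <- geometry$n_detectors * time$nt
  arc <- Matrix::sparseMatrix(i = trip$i + 1L, j = trip$j + 1L, x = trip$v,
                              dims = c(n_rows, grid$nx * grid$ny))
  Dt <- time_derivative_stencil(time$nt, time$dt)
  M <- kronecker(Matrix::Diagonal(geometry$n_detectors), Dt) %*% arc
  structure(list(matrix = methods::as(M, "CsparseMatrix"), grid = grid,
                 geometry = geometry, time = time,
                 samples_per_pixel = as.integer(samples_per_pixel), scale = 1),
            class = "model_matrix")
}

#' @export
print.model_matrix <- function(x, ...) {
  cat(sprintf("<model_matrix> %d x %d, %.3g%% nonzero, scale %.4g\n",
              nrow(x$matrix), ncol(x$matrix),
              100 * Matrix::nnzero(x$matrix) / prod(dim(x$matrix)), x$scale))
  invisible(x)
}

grids_equal <- function(a, b) {
  a$nx == b$nx && a$ny == b$ny &&
    isTRUE(all.equal(a$pixel_size, b$pixel_size)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

#' Forward projection: simulate a sinogram from an image
#'
#' @param M a [build_model_matrix()] result.
#' @param img an [image2d()] on the matrix's grid.
#' @return a [sinogram()] with `values = M %*% vectorize_image(img)`
#'   devectorized detector-major.
#' @export
forward_project <- function(M, img) {
  stopifnot(inherits(M, "model_matrix"), inherits(img, "image2d"))
  if (!grids_equal(M$grid, img$grid))
    stop("image grid does not match the model matrix grid")
  p <- as.numeric(M$matrix %*% vectorize_image(img))
  devectorize_sinogram(p, M$geometry, M$time)
}

#' Adjoint projection (transpose operator)
#'
#' Applies `t(M)` to a vectorized sinogram, the adjoint needed by every
#' iterative solver; satisfies `<M u, p> = <u, t(M) p>` to rounding error.
#'
#' @param M a [build_model_matrix()] result.
#' @param sino a [sinogram()] with matching geometry and time axis.
#' @return an [image2d()] holding the backprojection.
#' @export
adjoint_project <- function(M, sino) {
  stopifnot(inherits(M, "model_matrix"), inherits(sino, "sinogram"))
  if (sino$geometry$n_detectors != M$geometry$n_detectors ||
      sino$time$nt != M$time$nt)
    stop("sinogram dimensions do not match the model matrix")
  u <- as.numeric(Matrix::crossprod(M$matrix, vectorize_sinogram(sino)))
  devectorize(u, M$grid)
}

#' Normalize the model matrix for scale-free regularization parameters
#'
#' Divides `M` by `eta = sqrt(norm(M, "I") * norm(M, "1")) / 160`, so that
#' after normalization `sqrt(norm * norm) = 160` — an upper bound on the
#' spectral norm pinned to a fixed value, making regularization weights
#' independent of the matrix construction details.
#'
#' @param M a [build_model_matrix()] result with at least one nonzero.
#' @return the normalized `model_matrix`; the applied factor accumulates in
#'   the `scale` field. Applying the function twice is idempotent.
#' @export
normalize_model_matrix <- function(M) {
  stopifnot(inherits(M, "model_matrix"))
  n_inf <- max(Matrix::rowSums(abs(M$matrix)))
  n_one <- max(Matrix::colSums(abs(M$matrix)))
  if (n_inf == 0 || n_one == 0) stop("cannot normalize an all-zero matrix")
  eta <- sqrt(n_inf * n_one) / 160
  M$matrix <- M$matrix / eta
  M$scale <- M$scale * eta
  M
}

# shared angular lattice: one node count for all radii of a time axis,
# dense enough for the largest arc
arc_lattice_size <- function(r_max, pixel_size, samples_per_pixel) {
  max(8, ceiling(2 * pi * r_max * samples_per_pixel / pixel_size))
}

# Matrix-free forward signal for one detector: arc integrals at every sample
# time (on the same shared angular lattice as the matrix builder) followed
# by the same time-derivative stencil. Oracle for tests.
forward_signal_matrix_free <- function(img, detector_xy, time,
                                       samples_per_pixel = 16) {
  r <- time$c * times(time) * 1e3
  n_theta <- arc_lattice_size(max(r), img$grid$pixel_size, samples_per_pixel)
  g <- vapply(r, function(ri) {
    if (ri <= 0) 0
    else arc_integral(img, detector_xy, ri, n_theta = n_theta)
  }, numeric(1))
  as.numeric(time_derivative_stencil(time$nt, time$dt) %*% g)
}

#' Wrap an identity forward operator on a grid
#'
#' Builds a `model_matrix` whose matrix is the identity on the vectorized
#' image (a denoising "acquisition"), useful for running the solvers in
#' their image-denoising limit.
#'
#' @param grid an [image_grid()].
#' @return a `model_matrix` with a synthetic single-detector geometry whose
#'   time axis has one sample per pixel.
#' @export
identity_model_matrix <- function(grid) {
  n <- grid$nx * grid$ny
  geom <- detection_geometry(radius = grid_bounding_radius(grid) * 2 + 1,
                             coverage_deg = 360, n_detectors = 1L,
                             center = c(mean(range(grid_coords(grid)$x)),
                                        mean(range(grid_coords(grid)$y))))
  ta <- time_axis(0, 1e-9, n)
  structure(list(matrix = Matrix::Diagonal(n), grid = grid, geometry = geom,
                 time = ta, samples_per_pixel = NA_integer_, scale = 1),
            class = "model_matrix")
}
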