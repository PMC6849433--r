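# Synthetic phantoms emulating the imaging targets the regularizer is aimed
# at: interwoven, branching, non-convex vessel-like structures (the kind of
# morphology dominating optoacoustic images of vasculature), plus analytic
# disks for solver limit checks.

#' Parameters of the random-walk vessel phantom generator
#'
#' Vessels are grown as bounded random-walk centerlines with per-step
#' heading noise, occasional branching, and Gaussian cross-section
#' profiles; crossings and curved, non-convex shapes arise by construction.
#'
#' @param n_seeds number of root vessels (default 8).
#' @param branch_prob per-step probability that a walker spawns a branch
#'   (default 0.02).
#' @param step_len centerline step length in pixels (default 1.5).
#' @param width_range half-width (Gaussian sigma) range of vessels in
#'   pixels (default `c(1, 3)`).
#' @param curvature_sigma std of the per-step heading increment in radians
#'   (default 0.12); larger values give more tortuous vessels.
#' @param amplitude_range peak intensity range of a vessel (default
#'   `c(0.5, 1)`).
#' @param seed RNG seed; the phantom is deterministic given the seed.
#' @return a list of class `vessel_phantom_params`.
#' @export
vessel_phantom_params <- function(n_seeds = 6, branch_prob = 0.02,
                                  step_len = 1.5, width_range = c(0.8, 2),
                                  curvature_sigma = 0.12,
                                  amplitude_range = c(0.5, 1), seed = 1L) {
  stopifnot(n_seeds >= 0, branch_prob >= 0, branch_prob <= 1, step_len > 0,
            all(width_range > 0), curvature_sigma >= 0,
            all(is.finite(c(n_seeds, branch_prob, step_len, width_range,
                            curvature_sigma, amplitude_range))))
  structure(list(n_seeds = as.integer(n_seeds), branch_prob = branch_prob,
                 step_len = step_len, width_range = sort(width_range),
                 curvature_sigma = curvature_sigma,
                 amplitude_range = sort(amplitude_range),
                 seed = as.integer(seed)),
            class = "vessel_phantom_params")
}

# run code with a private RNG stream, restoring the caller's state
with_local_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

# stamp a Gaussian cross-section profile around a centerline point,
# combining with pmax so crossing vessels keep their individual intensity
stamp_gaussian <- function(values, cx, cy, sigma, amp) {
  r <- ceiling(3 * sigma)
  ny <- nrow(values); nx <- ncol(values)
  jx <- max(1L, floor(cx) - r):min(nx, ceiling(cx) + r)
  iy <- max(1L, floor(cy) - r):min(ny, ceiling(cy) + r)
  if (!length(jx) || !length(iy)) return(values)
  d2 <- outer((iy - cy)^2, (jx - cx)^2, "+")
  values[iy, jx] <- pmax(values[iy, jx], amp * exp(-d2 / (2 * sigma^2)))
  values
}

#' Generate a vessel-like phantom image
#'
#' @param grid an [image_grid()].
#' @param params a [vessel_phantom_params()].
#' @return an [image2d()] with values in `[0, 1]`.
#' @export
generate_vessel_phantom <- function(grid, params = vessel_phantom_params()) {
  stopifnot(inherits(grid, "image_grid"), inherits(params, "vessel_phantom_params"))
  nx <- grid$nx; ny <- grid$ny
  values <- matrix(0, ny, nx)
  if (params$n_seeds == 0L) return(image2d(grid, values))
  max_steps <- ceiling(0.8 * (nx + ny) / params$step_len)
  with_local_seed(params$seed, {
    # walkers: list of (x, y, heading, sigma, amp, steps_left)
    walkers <- lapply(seq_len(params$n_seeds), function(i) {
      list(x = runif(1, 0.1 * nx, 0.9 * nx), y = runif(1, 0.1 * ny, 0.9 * ny),
           h = runif(1, 0, 2 * pi),
           sigma = runif(1, params$width_range[1], params$width_range[2]),
           amp = runif(1, params$amplitude_range[1], params$amplitude_range[2]),
           left = max_steps)
    })
    while (length(walkers)) {
      w <- walkers[[1]]; walkers <- walkers[-1]
      while (w$left > 0 &&
             w$x >= -2 && w$x <= nx + 2 && w$y >= -2 && w$y <= ny + 2) {
        values <- stamp_gaussian(values, w$x, w$y, w$sigma, w$amp)
        w$h <- w$h + stats::rnorm(1, 0, params$curvature_sigma)
        w$x <- w$x + params$step_len * cos(w$h)
        w$y <- w$y + params$step_len * sin(w$h)
        w$left <- w$left - 1L
        if (stats::runif(1) < params$branch_prob && length(walkers) < 64) {
          b <- w
          b$h <- w$h + sample(c(-1, 1), 1) * stats::runif(1, 0.4, 1.1)
          b$sigma <- max(params$width_range[1], w$sigma * stats::runif(1, 0.6, 0.9))
          b$left <- ceiling(w$left / 2)
          walkers <- c(walkers, list(b))
        }
      }
    }
  })
  image2d(grid, pmin(values, 1))
}

#' Generate an antialiased disk phantom
#'
#' A uniform disk with a boundary antialiased by the pixel-area fraction
#' (approximated from the signed distance to the circle), the analytic test
#' object for the denoising limit of the TV solvers.
#'
#' @param grid an [image_grid()].
#' @param center disk center (mm); defaults to the grid center.
#' @param radius disk radius (mm), positive.
#' @param amplitude disk intensity.
#' @return an [image2d()].
#' @export
generate_disk_phantom <- function(grid, center = NULL, radius, amplitude = 1) {
  stopifnot(inherits(grid, "image_grid"), radius > 0)
  co <- grid_coords(grid)
  if (is.null(center)) center <- c(mean(range(co$x)), mean(range(co$y)))
  if (center[1] - radius < min(co$x) || center[1] + radius > max(co$x) ||
      center[2] - radius < min(co$y) || center[2] + radius > max(co$y))
    stop("disk must lie inside the grid")
  d <- sqrt(outer((co$y - center[2])^2, (co$x - center[1])^2, "+"))
  frac <- pmin(pmax((radius - d) / grid$pixel_size + 0.5, 0), 1)
  image2d(grid, amplitude * frac)
}

#' Add Gaussian projection noise to a sinogram
#'
#' Adds i.i.d. zero-mean Gaussian noise with standard deviation
#' `level * max(abs(p))` — the level is referenced to the sinogram's peak
#' pressure, so `level = 0.6` reproduces heavy detector noise at 60% of the
#' peak signal.
#'
#' @param sino a [sinogram()].
#' @param level noise std as a fraction of `max(abs(p))`, non-negative.
#' @param seed RNG seed; noise is deterministic given the seed.
#' @return a [sinogram()] with the noise added.
#' @export
add_projection_noise <- function(sino, level, seed = 1L) {
  stopifnot(inherits(sino, "sinogram"))
  if (level < 0) stop("noise level must be non-negative")
  if (level == 0) return(sino)
  sd <- level * max(abs(sino$values))
  noise <- with_local_seed(seed,
    matrix(stats::rnorm(length(sino$values), 0, sd),
           nrow(sino$values), ncol(sino$values)))
  sino$values <- sino$values + noise
  sino
}

#' Keep a uniformly spaced subset of detectors
#'
#' Sparse-view subsampling: keeps `n_keep` detectors uniformly spaced over
#' the original index range starting at the first detector (stride
#' `n_detectors / n_keep` when that is an integer), emulating a
#' lower-density detector array.
#'
#' @param x a [sinogram()] or a [detection_geometry()].
#' @param n_keep number of detectors to keep (at most `n_detectors`).
#' @return object of the same class with `n_keep` detectors and angles
#'   updated consistently.
#' @export
subsample_projections <- function(x, n_keep) {
  n <- if (inherits(x, "sinogram")) x$geometry$n_detectors else x$n_detectors
  n_keep <- as.integer(n_keep)
  if (n_keep > n) stop(sprintf("cannot keep %d of %d detectors", n_keep, n))
  if (n_keep < 1L) stop("n_keep must be >= 1")
  idx <- 1L + floor((seq_len(n_keep) - 1L) * n / n_keep)
  if (inherits(x, "sinogram")) {
    geom <- subsample_projections(x$geometry, n_keep)
    sinogram(geom, x$time, x$values[idx, , drop = FALSE])
  } else if (inherits(x, "detection_geometry")) {
    x$n_detectors <- n_keep
    if (n_keep > 1L)
      x$coverage_deg <- (x$angles[idx[n_keep]] - x$angles[idx[1]]) * 180 / pi
    x$angles <- x$angles[idx]
    x$det_x <- x$det_x[idx]
    x$det_y <- x$det_y[idx]
    x
  } else stop("x must be a sinogram or detection_geometry")
}
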