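#' Arc detection geometry
#'
#' Point-like ultrasound detectors evenly spaced on a circular arc around the
#' imaged object, the geometry of conventional optoacoustic tomography
#' systems (e.g. a 270-degree arc of radius 4 cm). Detector `i` sits at
#' `center + radius * (cos(angle_i), sin(angle_i))`.
#'
#' @param radius arc radius in mm; must leave every grid pixel strictly
#'   inside the arc when the geometry is paired with a grid.
#' @param coverage_deg angular coverage in degrees, in (0, 360].
#' @param n_detectors number of detectors (>= 1).
#' @param center arc center (mm); defaults to the origin.
#' @param start_deg angle of the first detector in degrees; defaults to
#'   `-coverage_deg / 2` so the arc is symmetric about the positive x axis.
#' @return An object of class `detection_geometry` with derived `angles`
#'   (radians) and detector positions `det_x`, `det_y` (mm).
#' @export
detection_geometry <- function(radius, coverage_deg = 270, n_detectors = 256,
                               center = c(0, 0), start_deg = -coverage_deg / 2) {
  if (radius <= 0) stop("radius must be positive")
  if (coverage_deg <= 0 || coverage_deg > 360) stop("coverage_deg must be in (0, 360]")
  n_detectors <- as.integer(n_detectors)
  if (n_detectors < 1L) stop("n_detectors must be >= 1")
  if (n_detectors == 1L) {
    angles <- start_deg * pi / 180
  } else {
    angles <- (start_deg + seq(0, coverage_deg, length.out = n_detectors)) * pi / 180
  }
  structure(list(radius = radius, coverage_deg = coverage_deg,
                 n_detectors = n_detectors, center = as.numeric(center),
                 angles = angles,
                 det_x = center[1] + radius * cos(angles),
                 det_y = center[2] + radius * sin(angles)),
            class = "detection_geometry")
}

#' @export
print.detection_geometry <- function(x, ...) {
  cat(sprintf("<detection_geometry> %d detectors on %.4g deg arc, radius %.4g mm\n",
              x$n_detectors, x$coverage_deg, x$radius))
  invisible(x)
}

check_geometry_encloses <- function(geometry, grid) {
  if (geometry$radius <= grid_bounding_radius(grid, geometry$center))
    stop("detectors must lie outside the image support: increase the arc radius")
  invisible(TRUE)
}

#' Uniform time sampling of the detector signals
#'
#' @param t0 time of the first sample (s).
#' @param dt sample interval (s), positive.
#' @param nt number of samples (>= 3).
#' @param c speed of sound (m/s), default 1500.
#' @return An object of class `time_axis`; `times(ta)` gives the sample times.
#' @export
time_axis <- function(t0, dt, nt, c = 1500) {
  if (dt <= 0) stop("dt must be positive")
  nt <- as.integer(nt)
  if (nt < 3L) stop("nt must be >= 3")
  if (c <= 0) stop("speed of sound must be positive")
  structure(list(t0 = t0, dt = dt, nt = nt, c = c), class = "time_axis")
}

#' @export
print.time_axis <- function(x, ...) {
  cat(sprintf("<time_axis> %d samples, t0 = %.4g us, dt = %.4g ns, c = %g m/s\n",
              x$nt, x$t0 * 1e6, x$dt * 1e9, x$c))
  invisible(x)
}

#' Sample times of a time axis (s)
#' @param ta a [time_axis()].
#' @export
times <- function(ta) ta$t0 + (seq_len(ta$nt) - 1L) * ta$dt

#' Default time axis for a grid/geometry pair
#'
#' Samples at the spatial Nyquist rate of the grid, `dt = pixel_size / (2c)`,
#' over a window covering the full detector-to-grid distance range padded by
#' two samples on each side, so every detector's signal is compactly
#' supported strictly inside the window.
#'
#' @param grid an [image_grid()].
#' @param geometry a [detection_geometry()].
#' @param c speed of sound (m/s).
#' @return a [time_axis()].
#' @export
default_time_axis <- function(grid, geometry, c = 1500) {
  check_geometry_encloses(geometry, grid)
  co <- grid_coords(grid)
  corners <- expand.grid(x = range(co$x), y = range(co$y))
  d <- outer(geometry$det_x, corners$x, "-")^2 + outer(geometry$det_y, corners$y, "-")^2
  # detector-to-support distances: nearest point of the grid rectangle
  dx <- pmax(min(co$x) - geometry$det_x, geometry$det_x - max(co$x), 0)
  dy <- pmax(min(co$y) - geometry$det_y, geometry$det_y - max(co$y), 0)
  d_min <- min(sqrt(dx^2 + dy^2)) * 1e-3          # mm -> m
  d_max <- max(sqrt(d)) * 1e-3
  dt <- grid$pixel_size * 1e-3 / (2 * c)
  t0 <- d_min / c - 2 * dt
  nt <- ceiling((d_max / c + 2 * dt - t0) / dt) + 1
  time_axis(t0, dt, nt, c)
}

#' Sinogram: time-domain pressure signals for each detector
#'
#' @param geometry a [detection_geometry()].
#' @param time a [time_axis()].
#' @param values numeric matrix `n_detectors` x `nt` (arbitrary pressure
#'   units); a scalar is recycled.
#' @return An object of class `sinogram`.
#' @export
sinogram <- function(geometry, time, values = 0) {
  stopifnot(inherits(geometry, "detection_geometry"), inherits(time, "time_axis"))
  if (length(values) == 1L) values <- matrix(values, geometry$n_detectors, time$nt)
  values <- as.matrix(values)
  if (nrow(values) != geometry$n_detectors || ncol(values) != time$nt)
    stop(sprintf("sinogram values must be %d x %d (detectors x time), got %d x %d",
                 geometry$n_detectors, time$nt, nrow(values), ncol(values)))
  if (!all(is.finite(values))) stop("sinogram values must be finite")
  structure(list(geometry = geometry, time = time, values = values),
            class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("<sinogram> %d detectors x %d samples, max |p| = %.4g\n",
              x$geometry$n_detectors, x$time$nt, max(abs(x$values))))
  invisible(x)
}

#' Vectorize a sinogram detector-major (time fastest within each detector)
#' @param sino a [sinogram()].
#' @return numeric vector of length `n_detectors * nt`.
#' @export
vectorize_sinogram <- function(sino) {
  stopifnot(inherits(sino, "sinogram"))
  as.vector(t(sino$values))
}

#' Rebuild a sinogram from its detector-major vectorization
#' @param vec numeric vector of length `n_detectors * nt`.
#' @param geometry,time provenance of the sinogram rows.
#' @export
devectorize_sinogram <- function(vec, geometry, time) {
  n <- geometry$n_detectors * time$nt
  if (length(vec) != n)
    stop(sprintf("expected vector of length %d, got %d", n, length(vec)))
  sinogram(geometry, time, t(matrix(vec, time$nt, geometry$n_detectors)))
}
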