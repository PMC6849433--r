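#' Regular 2D reconstruction grid
#'
#' Defines the square-pixel grid on which the optoacoustic image (the local
#' energy deposition) is reconstructed. Physical coordinates are in mm; the
#' pixel `(1, 1)` of the value matrix sits at `origin`, x grows with the
#' column index and y grows (upward) with the row index.
#'
#' @param nx,ny pixel counts along x and y (each at least 2).
#' @param pixel_size side length of a pixel in mm (one scalar: square pixels).
#' @param origin physical coordinate (mm) of the center of pixel `(1, 1)`.
#'   Defaults to centering the grid on the physical origin.
#' @return An object of class `image_grid`.
#' @examples
#' g <- image_grid(64, 64, 0.1)
#' @export
image_grid <- function(nx, ny, pixel_size, origin = NULL) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx < 2L || ny < 2L) stop("grid must be at least 2x2 pixels")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("pixel_size must be a single positive number (mm)")
  if (is.null(origin))
    origin <- c(-(nx - 1L) / 2 * pixel_size, -(ny - 1L) / 2 * pixel_size)
  if (length(origin) != 2L || !all(is.finite(origin)))
    stop("origin must be a finite 2-vector (mm)")
  structure(list(nx = nx, ny = ny, pixel_size = pixel_size,
                 origin = as.numeric(origin)),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid> %d x %d pixels, %.4g mm/pixel, origin (%.4g, %.4g) mm\n",
              x$nx, x$ny, x$pixel_size, x$origin[1], x$origin[2]))
  invisible(x)
}

#' Physical x/y coordinates of the pixel centers (mm)
#' @param grid an [image_grid()].
#' @return list with numeric vectors `x` (length nx) and `y` (length ny).
#' @export
grid_coords <- function(grid) {
  list(x = grid$origin[1] + (seq_len(grid$nx) - 1L) * grid$pixel_size,
       y = grid$origin[2] + (seq_len(grid$ny) - 1L) * grid$pixel_size)
}

#' Radius of the smallest circle about `center` containing all pixel centers
#' @param grid an [image_grid()].
#' @param center 2-vector (mm); defaults to the grid's physical center.
#' @return distance in mm.
#' @export
grid_bounding_radius <- function(grid, center = NULL) {
  co <- grid_coords(grid)
  if (is.null(center)) center <- c(mean(range(co$x)), mean(range(co$y)))
  corners <- expand.grid(x = range(co$x), y = range(co$y))
  max(sqrt((corners$x - center[1])^2 + (corners$y - center[2])^2))
}

#' 2D image on a reconstruction grid
#'
#' @param grid an [image_grid()].
#' @param values numeric matrix of size `ny` x `nx` (row = y, column = x),
#'   finite everywhere. A single scalar is recycled.
#' @return An object of class `image2d`.
#' @export
image2d <- function(grid, values = 0) {
  stopifnot(inherits(grid, "image_grid"))
  if (length(values) == 1L) values <- matrix(values, grid$ny, grid$nx)
  values <- as.matrix(values)
  if (nrow(values) != grid$ny || ncol(values) != grid$nx)
    stop(sprintf("values must be %d x %d (ny x nx), got %d x %d",
                 grid$ny, grid$nx, nrow(values), ncol(values)))
  if (!all(is.finite(values))) stop("image values must be finite")
  structure(list(grid = grid, values = values), class = "image2d")
}

#' @export
print.image2d <- function(x, ...) {
  cat(sprintf("<image2d> %d x %d, range [%.4g, %.4g]\n",
              x$grid$ny, x$grid$nx, min(x$values), max(x$values)))
  invisible(x)
}

#' Vectorize an image column-wise
#'
#' The image vector is divided into sub-vectors, one per image column, with
#' the y index running fastest — the ordering assumed by the model matrix.
#'
#' @param img an [image2d()].
#' @return numeric vector of length `nx * ny`.
#' @seealso [devectorize()]
#' @export
vectorize_image <- function(img) {
  stopifnot(inherits(img, "image2d"))
  as.vector(img$values)
}

#' Rebuild an image from its column-wise vectorization
#'
#' @param vec numeric vector of length `nx * ny`.
#' @param grid the [image_grid()] the vector was taken on.
#' @return an [image2d()].
#' @export
devectorize <- function(vec, grid) {
  stopifnot(inherits(grid, "image_grid"))
  n <- grid$nx * grid$ny
  if (length(vec) != n)
    stop(sprintf("expected vector of length %d (nx*ny), got %d", n, length(vec)))
  image2d(grid, matrix(vec, grid$ny, grid$nx))
}
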