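# File I/O: images as float TIFF (unit range) or a lossless plain-text
# array container, sinograms as TSV + JSON metadata sidecar, sparse model
# matrices as MatrixMarket + JSON metadata.

meta_path <- function(path) paste0(path, ".json")

grid_to_meta <- function(grid) {
  list(nx = grid$nx, ny = grid$ny, pixel_size = grid$pixel_size,
       origin = grid$origin)
}
grid_from_meta <- function(m) image_grid(m$nx, m$ny, m$pixel_size, unlist(m$origin))

geometry_to_meta <- function(g) {
  list(radius = g$radius, coverage_deg = g$coverage_deg,
       n_detectors = g$n_detectors, center = g$center,
       angles_deg = g$angles * 180 / pi)
}
geometry_from_meta <- function(m) {
  g <- detection_geometry(m$radius, m$coverage_deg, m$n_detectors,
                          unlist(m$center),
                          start_deg = unlist(m$angles_deg)[1])
  # subsampled geometries carry explicit angles
  ang <- unlist(m$angles_deg) * pi / 180
  g$angles <- ang
  g$det_x <- g$center[1] + g$radius * cos(ang)
  g$det_y <- g$center[2] + g$radius * sin(ang)
  g
}

time_to_meta <- function(ta) list(t0 = ta$t0, dt = ta$dt, nt = ta$nt, c = ta$c)
time_from_meta <- function(m) time_axis(m$t0, m$dt, m$nt, m$c)

write_matrix_tsv <- function(v, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(apply(v, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\t")),
             con)
}

read_matrix_tsv <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE,
                                   colClasses = "numeric"))
  dimnames(m) <- NULL
  m
}

#' Write an image to disk
#'
#' `.tif`/`.tiff` paths are written as 32-bit float TIFF (values must lie
#' in `[0, 1]`, the representable range of the TIFF writer); any other
#' extension uses a lossless plain-text array container that round-trips
#' doubles exactly, with a JSON grid sidecar.
#'
#' @param img an [image2d()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "image2d"))
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    v <- img$values
    if (min(v) < 0 || max(v) > 1)
      stop("TIFF output requires values in [0, 1]; use the .tsv container for unbounded images")
    # row 1 of a TIFF is the top of the picture; our row 1 is the lowest y
    tiff::writeTIFF(v[nrow(v):1, , drop = FALSE], path,
                    bits.per.sample = 32L, compression = "none", reduce = FALSE)
  } else {
    write_matrix_tsv(img$values, path)
  }
  jsonlite::write_json(grid_to_meta(img$grid), meta_path(path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image written by [write_image()]
#' @param path file path (TIFF or text container) with its JSON sidecar.
#' @return an [image2d()].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  if (!file.exists(meta_path(path))) stop("missing metadata sidecar: ", meta_path(path))
  grid <- grid_from_meta(jsonlite::read_json(meta_path(path)))
  v <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    m <- tiff::readTIFF(path)
    m[nrow(m):1, , drop = FALSE]
  } else read_matrix_tsv(path)
  if (!all(dim(v) == c(grid$ny, grid$nx)))
    stop("image dimensions do not match the metadata sidecar")
  image2d(grid, v)
}

#' Write a sinogram (TSV values + JSON geometry/time sidecar)
#' @param sino a [sinogram()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sinogram <- function(sino, path) {
  stopifnot(inherits(sino, "sinogram"))
  write_matrix_tsv(sino$values, path)
  jsonlite::write_json(list(geometry = geometry_to_meta(sino$geometry),
                            time = time_to_meta(sino$time)),
                       meta_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a sinogram written by [write_sinogram()]
#' @param path file path.
#' @return a [sinogram()].
#' @export
read_sinogram <- function(path) {
  if (!file.exists(path)) stop("sinogram file not found: ", path)
  m <- jsonlite::read_json(meta_path(path))
  sinogram(geometry_from_meta(m$geometry), time_from_meta(m$time),
           read_matrix_tsv(path))
}

#' Save a model matrix (MatrixMarket + JSON metadata)
#' @param M a [build_model_matrix()] result.
#' @param path output path; the sparse matrix goes to `path` (MatrixMarket
#'   format) and provenance metadata to `path.json`.
#' @return `path`, invisibly.
#' @export
save_matrix <- function(M, path) {
  stopifnot(inherits(M, "model_matrix"))
  write_mm_full_precision(M$matrix, path)
  jsonlite::write_json(list(grid = grid_to_meta(M$grid),
                            geometry = geometry_to_meta(M$geometry),
                            time = time_to_meta(M$time),
                            samples_per_pixel = M$samples_per_pixel,
                            scale = M$scale),
                       meta_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# MatrixMarket coordinate writer emitting %.17g values (Matrix::writeMM
# truncates to %g, which breaks exact round trips); readMM reads it back.
write_mm_full_precision <- function(m, path) {
  m <- methods::as(methods::as(m, "generalMatrix"), "TsparseMatrix")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("%%MatrixMarket matrix coordinate real general",
               sprintf("%d %d %d", nrow(m), ncol(m), length(m@x))), con)
  writeLines(sprintf("%d %d %.17g", m@i + 1L, m@j + 1L, m@x), con)
}

#' Load a model matrix written by [save_matrix()]
#' @param path file path.
#' @return a `model_matrix`.
#' @export
load_matrix <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  m <- jsonlite::read_json(meta_path(path))
  mat <- methods::as(Matrix::readMM(path), "CsparseMatrix")
  grid <- grid_from_meta(m$grid)
  geom <- geometry_from_meta(m$geometry)
  ta <- time_from_meta(m$time)
  if (ncol(mat) != grid$nx * grid$ny || nrow(mat) != geom$n_detectors * ta$nt)
    stop("matrix dimensions do not match the metadata sidecar")
  structure(list(matrix = mat, grid = grid, geometry = geom, time = ta,
                 samples_per_pixel = m$samples_per_pixel, scale = m$scale),
            class = "model_matrix")
}
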