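# Reconstruction-quality metrics and profile diagnostics.

#' Mean absolute distance between two images
#'
#' `MAD = (1/N) ||u_orig - u||_1` with `N` the number of pixels; the
#' headline fidelity measure for simulated reconstructions. Symmetric in
#' its arguments and zero iff the images are identical.
#'
#' @param u_orig,u two [image2d()] objects on the same grid (or plain
#'   matrices of equal size).
#' @return non-negative scalar.
#' @export
image_mad <- function(u_orig, u) {
  a <- if (inherits(u_orig, "image2d")) u_orig$values else as.matrix(u_orig)
  b <- if (inherits(u, "image2d")) u$values else as.matrix(u)
  if (!all(dim(a) == dim(b)))
    stop("images must be on the same grid to compare")
  mean(abs(a - b))
}

#' Relative L2 reconstruction error
#'
#' `||u - u_orig||_2 / ||u_orig||_2`; a supporting diagnostic alongside
#' [image_mad()].
#'
#' @inheritParams image_mad
#' @return non-negative scalar (`NaN` for an all-zero reference).
#' @export
rel_l2_error <- function(u_orig, u) {
  a <- if (inherits(u_orig, "image2d")) u_orig$values else as.matrix(u_orig)
  b <- if (inherits(u, "image2d")) u$values else as.matrix(u)
  if (!all(dim(a) == dim(b)))
    stop("images must be on the same grid to compare")
  sqrt(sum((b - a)^2)) / sqrt(sum(a^2))
}

#' Metrics report for a reconstruction
#'
#' @inheritParams image_mad
#' @return list of class `metrics_report` with `mad` and `rel_l2`.
#' @export
metrics_report <- function(u_orig, u) {
  structure(list(mad = image_mad(u_orig, u),
                 rel_l2 = rel_l2_error(u_orig, u)),
            class = "metrics_report")
}

#' Extract a 1D slice through an image
#'
#' Returns one row or column of the image, optionally normalized by its
#' maximum — the standard way of comparing reconstructed and true vessel
#' cross-sections.
#'
#' @param img an [image2d()].
#' @param axis `"x"` for a row (fixed y index) or `"y"` for a column
#'   (fixed x index).
#' @param index 1-based index of the row/column.
#' @param normalize if `TRUE`, divide by `max(profile)` (nonzero slices).
#' @return numeric vector.
#' @export
slice_profile <- function(img, axis = c("y", "x"), index, normalize = FALSE) {
  stopifnot(inherits(img, "image2d"))
  axis <- match.arg(axis)
  v <- img$values
  if (axis == "x") {
    if (index < 1 || index > nrow(v)) stop("row index out of range")
    prof <- v[index, ]
  } else {
    if (index < 1 || index > ncol(v)) stop("column index out of range")
    prof <- v[, index]
  }
  if (normalize && max(prof) > 0) prof <- prof / max(prof)
  prof
}
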