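# Orthonormal periodic Daubechies-4 discrete wavelet transform, the
# sparsifying basis Phi of the TV-L1 inversion. The transform is a 2D
# multilevel separable DWT with periodic extension at maximal dyadic depth
# (coarsest block 4x4); as an orthonormal operator it has unit spectral
# norm and Phi^T Phi = I, which the primal-dual solver relies on.

daub4_h <- c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2))
daub4_g <- c(daub4_h[4], -daub4_h[3], daub4_h[2], -daub4_h[1])

# one periodic analysis step along rows of a matrix (n rows -> n/2 + n/2)
dwt_step_rows <- function(v) {
  n <- nrow(v); n2 <- n %/% 2L
  s <- matrix(0, n2, ncol(v)); d <- matrix(0, n2, ncol(v))
  for (m in 0:3) {
    sel <- ((2L * (seq_len(n2) - 1L) + m) %% n) + 1L
    s <- s + daub4_h[m + 1L] * v[sel, , drop = FALSE]
    d <- d + daub4_g[m + 1L] * v[sel, , drop = FALSE]
  }
  rbind(s, d)
}

idwt_step_rows <- function(v) {
  n <- nrow(v); n2 <- n %/% 2L
  s <- v[seq_len(n2), , drop = FALSE]
  d <- v[n2 + seq_len(n2), , drop = FALSE]
  out <- matrix(0, n, ncol(v))
  for (m in 0:3) {
    sel <- ((2L * (seq_len(n2) - 1L) + m) %% n) + 1L
    out[sel, ] <- out[sel, , drop = FALSE] +
      daub4_h[m + 1L] * s + daub4_g[m + 1L] * d
  }
  out
}

check_dyadic <- function(n) {
  if (n < 4L || bitwAnd(n, n - 1L) != 0L)
    stop(sprintf(paste0("wavelet transform needs dyadic dimensions >= 4, got %d; ",
                        "pad the image to the next power of two"), n))
}

#' Orthonormal 2D Daubechies-4 wavelet transform (periodic)
#'
#' @param v numeric matrix with dyadic dimensions (powers of two, >= 4).
#' @return coefficient matrix of the same size (multilevel, coarsest
#'   block 4x4 in the top-left corner).
#' @seealso [idwt2()]
#' @export
dwt2 <- function(v) {
  v <- as.matrix(v)
  check_dyadic(nrow(v)); check_dyadic(ncol(v))
  cr <- nrow(v); cc <- ncol(v)
  while (cr >= 8L && cc >= 8L) {
    blk <- v[seq_len(cr), seq_len(cc), drop = FALSE]
    blk <- dwt_step_rows(blk)
    blk <- t(dwt_step_rows(t(blk)))
    v[seq_len(cr), seq_len(cc)] <- blk
    cr <- cr %/% 2L; cc <- cc %/% 2L
  }
  v
}

#' Inverse of [dwt2()]
#' @param v coefficient matrix produced by [dwt2()].
#' @return the reconstructed matrix (exact up to rounding error).
#' @export
idwt2 <- function(v) {
  v <- as.matrix(v)
  check_dyadic(nrow(v)); check_dyadic(ncol(v))
  sizes <- NULL
  cr <- nrow(v); cc <- ncol(v)
  while (cr >= 8L && cc >= 8L) {
    sizes <- c(list(c(cr, cc)), sizes)
    cr <- cr %/% 2L; cc <- cc %/% 2L
  }
  for (sz in sizes) {
    ri <- seq_len(sz[1]); ci <- seq_len(sz[2])
    blk <- v[ri, ci, drop = FALSE]
    blk <- t(idwt_step_rows(t(blk)))
    blk <- idwt_step_rows(blk)
    v[ri, ci] <- blk
  }
  v
}
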