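#' Non-uniform Fourier encoding operator
#'
#' Exact non-uniform discrete Fourier transform between a square image grid
#' and arbitrary 2D k-space sample locations, realized as a dense complex
#' matrix applied with BLAS. Exactness (no gridding-kernel approximation)
#' makes the operator its own adjoint-consistent pair, which the
#' reconstruction and the density-compensation fixed point both rely on. At
#' the matrix sizes this package targets (up to 128 x 128 in-plane) the
#' dense transform is fast and the matrix is built once per trajectory and
#' reused across channels, partitions, repetitions and timeframes.
#'
#' Conventions: image arrays are indexed `[y, x]`; grid coordinates are
#' centred, `x_i = (i - 1 - floor(n/2)) * dx` mm with `dx = fov/n`; k-space
#' locations are complex `kx + i ky` in cycles/mm. Forward maps image to
#' samples with kernel `exp(-2 pi i (kx x + ky y))`; adjoint is the
#' conjugate transpose.
#'
#' @param k complex vector of sample locations (cycles/mm).
#' @param matrix image grid size `n` (square).
#' @param fov_mm field of view (mm).
#' @return list with `forward(img)` (image matrix or vector -> complex
#'   sample matrix), `adjoint(s)` (samples -> image-vector matrix), `n`,
#'   `fov_mm`, `dx`, `n_samples`.
#' @export
make_encoding <- function(k, matrix, fov_mm) {
  n <- as.integer(matrix)
  dx <- fov_mm / n
  xs <- centered_coords(n, dx)
  # vec order matches R column-major image [y, x]: y varies fastest
  Y <- rep(xs, times = n)
  X <- rep(xs, each = n)
  kx <- Re(k)
  ky <- Im(k)
  E <- exp(-2i * pi * (outer(kx, X) + outer(ky, Y)))
  forward <- function(img) {
    v <- if (is.null(dim(img)) || length(dim(img)) <= 1) cbind(c(img))
         else if (length(dim(img)) == 2 && all(dim(img) == c(n, n))) cbind(c(img))
         else img  # npix x m matrix of vectorized images
    E %*% v
  }
  adjoint <- function(s) {
    sm <- if (is.null(dim(s))) cbind(c(s)) else s
    # conj(t(E)) %*% s without materializing the transpose
    Conj(crossprod(E, Conj(sm)))
  }
  list(forward = forward, adjoint = adjoint, n = n, fov_mm = fov_mm,
       dx = dx, n_samples = length(k))
}
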