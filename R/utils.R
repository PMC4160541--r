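# Internal numeric helpers shared across modules.

#' Round half away from zero to a fixed number of decimals
#'
#' Scanner protocol sheets round half-up (35.2 ms prints as 35 ms,
#' 33.79 s as 34 s), unlike [base::round()]'s round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Normalized root-mean-square error
#'
#' @param x estimate array.
#' @param ref reference array (same shape).
#' @param mask optional logical array restricting the comparison.
#' @return scalar \code{sqrt(mean(|x - ref|^2)) / sqrt(mean(|ref|^2))}.
#' @export
nrmse <- function(x, ref, mask = NULL) {
  stopifnot(length(x) == length(ref))
  if (!is.null(mask)) {
    stopifnot(length(mask) == length(ref))
    x <- x[mask]
    ref <- ref[mask]
  }
  sqrt(mean(Mod(x - ref)^2)) / sqrt(mean(Mod(ref)^2))
}

# Centred orthonormal FFT pair along the last margin of a matrix whose
# columns are the transform direction; used for the partition (kz) encode.
# DC sits at index floor(n/2) + 1.
fft_centered <- function(x, inverse = FALSE) {
  n <- length(x)
  sh <- function(v, k) if (k %% n == 0) v else c(v[(k + 1):n], v[1:k])
  h <- floor(n / 2)
  # ifftshift -> fft -> fftshift, orthonormal scaling
  v <- sh(x, h)
  v <- stats::fft(v, inverse = inverse) / sqrt(n)
  sh(v, n - h)
}

# Apply fft_centered along margin `dim` of an array.
fft_centered_along <- function(a, dim, inverse = FALSE) {
  d <- base::dim(a)
  stopifnot(dim <= length(d))
  perm <- c(dim, seq_along(d)[-dim])
  m <- aperm(a, perm)
  dm <- base::dim(m)
  m <- matrix(m, nrow = dm[1])
  m <- apply(m, 2, fft_centered, inverse = inverse)
  m <- array(m, dm)
  aperm(m, order(perm))
}

# Centred spatial-frequency values for an n-point grid with spacing dx:
# k_i = (i - 1 - floor(n/2)) / (n * dx), DC at floor(n/2) + 1.
centered_freqs <- function(n, dx) {
  ((seq_len(n) - 1) - floor(n / 2)) / (n * dx)
}

# Centred spatial coordinates: x_i = (i - 1 - floor(n/2)) * dx.
centered_coords <- function(n, dx) {
  ((seq_len(n) - 1) - floor(n / 2)) * dx
}

# Separable Gaussian smoothing of a 2D matrix with edge renormalization
# (kernel truncated at 3 sigma and re-scaled so flat inputs stay flat).
gaussian_smooth2d <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  smooth1 <- function(v) {
    n <- length(v)
    out <- numeric(n)
    for (i in seq_len(n)) {
      lo <- max(1L, i - r)
      hi <- min(n, i + r)
      kk <- k[(lo - i + r + 1L):(hi - i + r + 1L)]
      out[i] <- sum(v[lo:hi] * kk) / sum(kk)
    }
    out
  }
  m2 <- apply(m, 2, smooth1)
  t(apply(t(m2), 2, smooth1))
}

# Clamp integer indices into [lo, hi].
clamp <- function(i, lo, hi) pmin(pmax(i, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a
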