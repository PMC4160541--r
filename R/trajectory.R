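#' Design a variable-density spiral arm
#'
#' Analytic two-density Archimedean-type spiral in k-space. The radial pitch
#' is set so that `center_arms` rotated copies satisfy Nyquist (adjacent
#' spiral turns no farther apart than `1/fov`) over the central
#' `center_matrix` x `center_matrix` region, while the full set of
#' `arms_total` copies satisfies Nyquist out to the designed k-space edge
#' `k_max = matrix / (2 fov)`. Samples are placed at constant arc-length
#' increments of one Nyquist interval `1/fov` per dwell, i.e. constant
#' readout speed, so the along-readout spacing also meets Nyquist. A small
#' design margin keeps all gaps strictly inside the Nyquist limit.
#'
#' Only the k-space geometry is designed: gradient and slew-rate waveforms
#' (and the zeroth/first-moment rewinders played after the useful readout)
#' are outside the scope of the reconstruction, which consumes sample
#' coordinates alone. The rewinder is represented by the short post-edge
#' tail that [truncate_at_kmax()] discards.
#'
#' @param fov_mm field of view (mm).
#' @param matrix in-plane matrix size.
#' @param center_matrix size of the central fully-dense k-space region (in
#'   matrix units, e.g. 8 for an 8x8 centre).
#' @param center_arms number of arms sufficient for Nyquist in the centre.
#' @param arms_total number of arms covering the full matrix.
#' @param dwell_us sample interval (microseconds).
#' @param max_readout_ms maximum admissible readout duration to the k-space
#'   edge (ms).
#' @param margin design safety factor (< 1) applied to all Nyquist gaps.
#'   The default 0.88 keeps even the worst-case sample-to-sample distance
#'   between adjacent arms inside one Nyquist interval: with line spacing
#'   and arc spacing both `margin/fov`, the nearest sample of the
#'   neighbouring arm can sit half an arc step away along the readout,
#'   i.e. at distance up to `sqrt(margin^2 + (margin/2)^2)/fov`, which stays
#'   below `1/fov` for `margin <= 0.894`.
#' @return object of class `spiral_arm` with fields `k` (complex sample
#'   coordinates, cycles/mm; `Re` = kx, `Im` = ky), `dwell_us`,
#'   `truncation_index`, `k_max`, `fov_mm`, `matrix`.
#' @examples
#' arm <- design_variable_density_spiral()
#' arm$truncation_index * arm$dwell_us / 1000  # readout time to the edge, ms
#' @export
design_variable_density_spiral <- function(fov_mm = 316, matrix = 128,
                                           center_matrix = 8, center_arms = 4,
                                           arms_total = 48, dwell_us = 5,
                                           max_readout_ms = 2.5,
                                           margin = 0.88) {
  stopifnot(center_arms <= arms_total, center_matrix <= matrix,
            fov_mm > 0, matrix > 0, dwell_us > 0, margin > 0, margin <= 1)
  k_max <- matrix / (2 * fov_mm)           # cycles/mm
  k_c <- center_matrix / (2 * fov_mm)      # edge of the dense centre
  k_t <- min(2 * k_c, k_max)               # end of the density transition
  # effective arm count: how many rotated copies are needed for Nyquist at
  # radius r; smoothstep between the two density levels
  n_eff <- function(r) {
    u <- (r - k_c) / (k_t - k_c)
    u <- pmin(pmax(u, 0), 1)
    s <- u * u * (3 - 2 * u)
    center_arms + (arms_total - center_arms) * s
  }
  ds <- margin / fov_mm                    # arc length per dwell
  n_guard <- ceiling(0.08 * k_max / ds)    # post-edge tail (stands in for rewind)
  max_samples <- ceiling(1.5 * pi * k_max^2 * fov_mm^2 / margin^2) + 200L
  th <- 0; r <- 0
  k <- complex(length.out = 0)
  trunc_idx <- NA_integer_
  for (i in seq_len(max_samples)) {
    k[i] <- complex(modulus = r, argument = th)
    if (is.na(trunc_idx) && r >= k_max) {
      trunc_idx <- i
      if ((i - 1) * dwell_us / 1000 > max_readout_ms) {
        stop("infeasible spiral design: readout to the k-space edge takes ",
             format((i - 1) * dwell_us / 1000, digits = 3),
             " ms, exceeding max_readout_ms = ", max_readout_ms)
      }
    }
    if (!is.na(trunc_idx) && i >= trunc_idx + n_guard) break
    rp <- margin * n_eff(r) / (2 * pi * fov_mm)  # dr/dtheta
    # arc-length parameterization: path speed per radian is sqrt(r'^2 + r^2);
    # the angular step is capped so the linearized step stays accurate where
    # the spiral turns tightly near the origin
    dth <- min(ds / sqrt(rp^2 + r^2), 0.4)
    th <- th + dth
    r <- r + rp * dth
  }
  if (is.na(trunc_idx)) {
    stop("infeasible spiral design: trajectory never reached k_max")
  }
  structure(list(k = k, dwell_us = dwell_us, truncation_index = trunc_idx,
                 k_max = k_max, fov_mm = fov_mm, matrix = as.integer(matrix)),
            class = "spiral_arm")
}

#' Rotate a spiral arm to interleaf position n
#'
#' Arm `n` of an interleaved spiral is the base arm multiplied by the unit
#' phasor of angle `2 pi n / arms_total`; the truncation index is unchanged.
#'
#' @param base a `spiral_arm`.
#' @param n interleaf index in `0 .. arms_total - 1`.
#' @param arms_total number of interleaves.
#' @return rotated `spiral_arm`.
#' @export
rotate_arm <- function(base, n, arms_total) {
  stopifnot(inherits(base, "spiral_arm"))
  if (n < 0 || n >= arms_total) {
    stop("interleaf index ", n, " out of range 0..", arms_total - 1)
  }
  out <- base
  out$k <- base$k * exp(2i * pi * n / arms_total)
  out
}

#' Truncate an arm at the designed k-space edge
#'
#' Retains samples up to and including the first index at which
#' `|k| >= k_max`; everything after (rewinder data) is discarded before
#' reconstruction.
#'
#' @param arm a `spiral_arm`.
#' @param k_max k-space radius (cycles/mm); defaults to the arm's design.
#' @return truncated `spiral_arm` with `truncation_index = length(k)`.
#' @export
truncate_at_kmax <- function(arm, k_max = arm$k_max) {
  stopifnot(inherits(arm, "spiral_arm"), length(arm$k) > 0)
  hit <- which(Mod(arm$k) >= k_max - 1e-12)
  if (length(hit) == 0) {
    stop("under-designed readout: |k| never reaches k_max = ", k_max)
  }
  i <- hit[1]
  out <- arm
  out$k <- arm$k[seq_len(i)]
  out$truncation_index <- i
  out$k_max <- k_max
  out
}

#' Full interleaved stack-of-spirals trajectory
#'
#' The base arm is truncated at the designed k-space edge and replicated at
#' all `arms_total` azimuthal rotations `2 pi n / arms_total`.
#'
#' @param base_arm a `spiral_arm` (typically from
#'   [design_variable_density_spiral()]).
#' @param arms_total number of interleaves.
#' @return object of class `spiral_trajectory` with fields `k` (complex
#'   matrix, readout x arm), `arms_total`, `n_readout`, `k_max`, `fov_mm`,
#'   `matrix`, `dwell_us`, `base_arm`.
#' @export
spiral_trajectory <- function(base_arm, arms_total) {
  stopifnot(inherits(base_arm, "spiral_arm"), arms_total >= 1)
  arm <- truncate_at_kmax(base_arm)
  rot <- exp(2i * pi * (seq_len(arms_total) - 1) / arms_total)
  k <- outer(arm$k, rot)
  structure(list(k = k, arms_total = as.integer(arms_total),
                 n_readout = arm$truncation_index, k_max = arm$k_max,
                 fov_mm = arm$fov_mm, matrix = arm$matrix,
                 dwell_us = arm$dwell_us, base_arm = arm),
            class = "spiral_trajectory")
}

#' Angular undersampling pattern
#'
#' Indices (0-based) of the arms acquired per partition encode per
#' timeframe: every `r`-th arm starting at `arm_offset`.
#'
#' @param arms_total total interleaves.
#' @param r acceleration factor (must divide `arms_total`).
#' @param arm_offset index of the first acquired arm, in `0 .. r - 1`.
#' @return object of class `sampling_pattern` with fields
#'   `acquired` (0-based indices), `r`, `arms_total`, `arm_offset`.
#' @examples
#' undersampling_pattern(48, 6)$acquired  # 0 6 12 18 24 30 36 42
#' @export
undersampling_pattern <- function(arms_total, r, arm_offset = 0) {
  stopifnot(arms_total >= 1, r >= 1)
  if (arms_total %% r != 0) {
    stop("irregular undersampling pattern: ", arms_total,
         " arms are not divisible by r = ", r)
  }
  if (arm_offset < 0 || arm_offset >= r) {
    stop("'arm_offset' must lie in 0 .. r - 1")
  }
  structure(list(acquired = as.integer(seq(arm_offset, arms_total - 1, by = r)),
                 r = as.integer(r), arms_total = as.integer(arms_total),
                 arm_offset = as.integer(arm_offset)),
            class = "sampling_pattern")
}

#' Density compensation weights
#'
#' Per-sample positive weights equal to the k-space area element each sample
#' covers, so that adjoint gridding approximates the continuous inverse
#' Fourier integral. For an interleaved spiral sampled at constant
#' arc-length increments the Voronoi-like cell of a sample is, to first
#' order, its local arc spacing along the readout times the gap to the
#' nearest sample of the azimuthally adjacent acquired arm; both are
#' computed numerically from the sample coordinates, so variable density
#' and angular undersampling are compensated automatically. Rotational
#' symmetry of the interleaves makes the weights identical across arms.
#' Exactly duplicated sample locations (all arms start at k = 0) share the
#' local cell equally instead of failing.
#'
#' @param traj a `spiral_trajectory` (truncated).
#' @param pattern optional [undersampling_pattern()]; `NULL` means all arms.
#' @return numeric matrix of positive weights, readout x acquired-arm
#'   (units: cycles^2/mm^2, i.e. k-space area per sample).
#' @export
density_compensation <- function(traj, pattern = NULL) {
  stopifnot(inherits(traj, "spiral_trajectory"))
  n_acq <- if (is.null(pattern)) traj$arms_total else length(pattern$acquired)
  kb <- traj$k[, 1]
  n <- length(kb)
  if (n == 1L) return(matrix(1, 1, n_acq))
  # local arc spacing along the readout (one-sided at the ends)
  seg <- Mod(diff(kb))
  ds <- c(seg[1], (seg[-1] + seg[-(n - 1)]) / 2, seg[n - 1])
  # gap to the azimuthally adjacent acquired arm: exact point-to-polyline
  # distance (nearest-vertex distance alone oscillates by the sampling step)
  kn <- kb * exp(2i * pi * (traj$arms_total / n_acq) / traj$arms_total)
  a <- kn[-n]; b <- kn[-1]
  ab <- b - a
  len2 <- pmax(Mod(ab)^2, 1e-300)
  gap <- vapply(seq_len(n), function(j) {
    p <- kb[j]
    t <- pmin(pmax(Re(Conj(ab) * (p - a)) / len2, 0), 1)
    sqrt(min(Mod(p - (a + t * ab))^2))
  }, numeric(1))
  # clip cells protruding past the designed k-space edge
  rr <- Mod(kb)
  over <- pmax(rr + gap / 2 - traj$k_max, 0)
  frac <- pmax((gap - over) / gap, 0)
  w <- ds * gap * ifelse(is.finite(frac), frac, 1)
  dup <- gap < 1e-12 * traj$k_max
  if (any(dup)) w[dup] <- ds[dup]^2 / n_acq  # shared cell at coincident points
  matrix(w, nrow = n, ncol = n_acq)
}

#' @export
print.spiral_trajectory <- function(x, ...) {
  cat(sprintf(paste0("variable-density spiral trajectory: %d arms x %d samples, ",
                     "k_max %.4f cycles/mm (matrix %d, FOV %g mm)\n"),
              x$arms_total, x$n_readout, x$k_max, x$matrix, x$fov_mm))
  cat(sprintf("  readout to edge: %.2f ms at dwell %g us\n",
              x$n_readout * x$dwell_us / 1000, x$dwell_us))
  invisible(x)
}

#' @export
print.sampling_pattern <- function(x, ...) {
  cat(sprintf("undersampling pattern: R = %d, %d of %d arms acquired: %s\n",
              x$r, length(x$acquired), x$arms_total,
              paste(x$acquired, collapse = " ")))
  invisible(x)
}
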