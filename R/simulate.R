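#' Acquisition simulation parameters
#'
#' @param noise_sd standard deviation of complex Gaussian noise added per
#'   k-space sample (applied independently to real and imaginary parts with
#'   sd `noise_sd / sqrt(2)` so the complex magnitude has sd `noise_sd`).
#' @param resp_amplitude_mm peak respiratory displacement applied (as a
#'   rigid translation, predominantly along z) to each calibration
#'   repetition; the breathheld dynamic scan stays at the reference
#'   position.
#' @param n_reps fully sampled calibration repetitions.
#' @param resp_direction unit-normalized direction `(x, y, z)` of the
#'   respiratory translation.
#' @param seed RNG seed governing calibration cardiac phases, respiratory
#'   excursions and noise.
#' @return object of class `acquisition_sim`.
#' @export
acquisition_sim <- function(noise_sd = 0, resp_amplitude_mm = 10, n_reps = 10,
                            resp_direction = c(0.1, 0.3, 0.95), seed = 1) {
  stopifnot(noise_sd >= 0, resp_amplitude_mm >= 0, n_reps >= 1)
  d <- resp_direction / sqrt(sum(resp_direction^2))
  structure(list(noise_sd = noise_sd, resp_amplitude_mm = resp_amplitude_mm,
                 n_reps = as.integer(n_reps), resp_direction = d,
                 seed = as.integer(seed)),
            class = "acquisition_sim")
}

#' Forward-encode one image volume into stack-of-spirals k-space
#'
#' Applies coil sensitivities, Fourier-transforms along z into kz
#' partitions (centred orthonormal DFT), and evaluates the 2D non-uniform
#' Fourier transform of every kz plane at the spiral sample locations of
#' the selected arms. Noise-free and linear in the input volume.
#'
#' @param vol intensity array `[y, x, z]`.
#' @param sens a [make_coil_sensitivities()] `coil_set` on the same grid.
#' @param traj a `spiral_trajectory` matching the grid's in-plane FOV and
#'   matrix.
#' @param arms 1-based arm indices to sample (default: all).
#' @param encoding optional cached [make_encoding()] operator built on the
#'   full trajectory (all arms).
#' @return complex array `[readout, arm, channel, partition]`.
#' @export
encode_volume <- function(vol, sens, traj, arms = seq_len(traj$arms_total),
                          encoding = NULL) {
  stopifnot(inherits(traj, "spiral_trajectory"), inherits(sens, "coil_set"))
  d <- dim(sens$maps)
  if (!all(dim(vol) == d[1:3])) stop("volume and coil grids disagree")
  if (d[1] != traj$matrix) {
    stop("trajectory was designed for matrix ", traj$matrix,
         ", volume grid is ", d[1])
  }
  if (any(arms < 1 | arms > traj$arms_total)) {
    stop("arm index out of range 1..", traj$arms_total)
  }
  nch <- d[4]; nz <- d[3]; n <- d[1]
  coil_vols <- sens$maps * array(rep(vol, nch), d)
  hybrid <- fft_centered_along(coil_vols, 3)          # z -> kz partitions
  X <- matrix(hybrid, n * n)                          # columns over (kz, ch)
  enc <- encoding %||% make_encoding(as.vector(traj$k), traj$matrix, traj$fov_mm)
  s <- enc$forward(X)                                 # (read*arm) x (kz*ch)
  s <- array(s, c(traj$n_readout, traj$arms_total, nz, nch))
  s <- aperm(s, c(1, 2, 4, 3))                        # read, arm, ch, part
  s[, arms, , , drop = FALSE]
}

# phase ramp implementing a rigid translation (dx, dy, dz) mm in k-space
translation_ramp <- function(traj, shift_mm, nz, dz_mm) {
  k2d <- exp(-2i * pi * (Re(traj$k) * shift_mm[1] + Im(traj$k) * shift_mm[2]))
  kz <- centered_freqs(nz, dz_mm)
  rz <- exp(-2i * pi * kz * shift_mm[3])
  list(k2d = k2d, rz = rz)
}

add_complex_noise <- function(x, sd) {
  if (sd <= 0) return(x)
  n <- length(x)
  x + complex(real = stats::rnorm(n, sd = sd / sqrt(2)),
              imaginary = stats::rnorm(n, sd = sd / sqrt(2)))
}

#' Simulate dynamic and calibration stack-of-spirals acquisitions
#'
#' For each cardiac phase the phantom is rasterized, coil-weighted and
#' forward-encoded (see [encode_volume()]). The breathheld dynamic scan
#' acquires only the arms of `pattern` at the reference respiratory
#' position. Calibration repetitions acquire all arms, each at a cardiac
#' phase drawn uniformly from the phantom's phase grid (the scan is ungated)
#' and at a respiratory displacement sampled from a smooth breathing trace,
#' applied as a rigid-body k-space phase ramp. Complex Gaussian noise is
#' added to both.
#'
#' @param ph an [lv_phantom()].
#' @param sens a `coil_set`.
#' @param traj a `spiral_trajectory`.
#' @param pattern an [undersampling_pattern()].
#' @param sim an [acquisition_sim()].
#' @param encoding optional cached encoding operator (full trajectory).
#' @return object of class `sim_data`: list with
#'   `dynamic` (`kspace_set`, acquired arms only, one frame per phase),
#'   `calibration` (`kspace_set`, all arms, one frame per repetition),
#'   `full` (noise-free fully sampled reference, `[read, arm, ch, part,
#'   phase]`), `truth` (ground-truth [lv_function_report()]), and the
#'   calibration draw bookkeeping (`calib_phases`, `calib_shift_mm`).
#' @export
simulate_kspace <- function(ph, sens, traj, pattern, sim = acquisition_sim(),
                            encoding = NULL) {
  stopifnot(inherits(ph, "lv_phantom"), inherits(sim, "acquisition_sim"))
  if (max(pattern$acquired) >= traj$arms_total) {
    stop("pattern arm index ", max(pattern$acquired), " out of range: ",
         "trajectory has ", traj$arms_total, " arms")
  }
  set.seed(sim$seed)
  n_ph <- ph$n_phases
  nz <- ph$grid_nz
  nch <- sens$n_channels
  enc <- encoding %||% make_encoding(as.vector(traj$k), traj$matrix, traj$fov_mm)

  full <- array(0i, c(traj$n_readout, traj$arms_total, nch, nz, n_ph))
  for (p in seq_len(n_ph)) {
    t <- (p - 1) / n_ph
    vol <- make_lv_phantom(ph, t)$vol
    full[, , , , p] <- encode_volume(vol, sens, traj, encoding = enc)
  }

  acq <- pattern$acquired + 1L
  dyn <- full[, acq, , , , drop = FALSE]
  dyn <- add_complex_noise(dyn, sim$noise_sd)

  reps <- sim$n_reps
  calib_phases <- sample.int(n_ph, reps, replace = TRUE)
  # smooth breathing trace sampled once per repetition
  excursion <- sim$resp_amplitude_mm * sin(2 * pi * stats::runif(1) +
                                             2 * pi * 0.37 * seq_len(reps))
  calib <- array(0i, c(traj$n_readout, traj$arms_total, nch, nz, reps))
  shifts <- matrix(0, reps, 3)
  for (r in seq_len(reps)) {
    shift <- excursion[r] * sim$resp_direction
    shifts[r, ] <- shift
    ramp <- translation_ramp(traj, shift, nz, ph$dz_mm)
    r2d <- array(ramp$k2d, c(traj$n_readout, traj$arms_total))
    fr <- full[, , , , calib_phases[r]]
    for (m in seq_len(nz)) {
      fr[, , , m] <- fr[, , , m] * as.vector(r2d) * ramp$rz[m]
    }
    calib[, , , , r] <- fr
  }
  calib <- add_complex_noise(calib, sim$noise_sd)

  structure(list(
    dynamic = kspace_set(dyn, arms = pattern$acquired, kind = "dynamic", traj = traj),
    calibration = kspace_set(calib, arms = seq_len(traj$arms_total) - 1L,
                             kind = "calibration", traj = traj),
    full = full,
    truth = ground_truth_function(ph),
    calib_phases = calib_phases, calib_shift_mm = shifts,
    phantom = ph, pattern = pattern, sim = sim), class = "sim_data")
}

#' Multi-channel non-Cartesian sample container
#'
#' @param data complex array `[readout, arm, channel, partition, frame]`
#'   (frame = timeframe for dynamic data, repetition for calibration data).
#' @param arms 0-based indices of the arms present in the `arm` dimension.
#' @param kind `"dynamic"` or `"calibration"`.
#' @param traj optionally the `spiral_trajectory` the samples live on.
#' @return object of class `kspace_set`.
#' @export
kspace_set <- function(data, arms, kind = c("dynamic", "calibration"),
                       traj = NULL) {
  kind <- match.arg(kind)
  stopifnot(length(dim(data)) == 5, length(arms) == dim(data)[2])
  structure(list(data = data, arms = as.integer(arms), kind = kind,
                 n_readout = dim(data)[1], n_channels = dim(data)[3],
                 n_partitions = dim(data)[4], n_frames = dim(data)[5],
                 fov_mm = traj$fov_mm %||% NA, matrix = traj$matrix %||% NA),
            class = "kspace_set")
}

#' @export
print.kspace_set <- function(x, ...) {
  cat(sprintf("%s k-space set: %d readout x %d arms x %d channels x %d partitions x %d %s\n",
              x$kind, x$n_readout, length(x$arms), x$n_channels,
              x$n_partitions, x$n_frames,
              if (x$kind == "dynamic") "timeframes" else "repetitions"))
  invisible(x)
}

#' Noise level giving a target single-coil blood-pool SNR
#'
#' Propagates per-sample k-space noise through density-compensated adjoint
#' gridding to the image domain and solves for the k-space noise standard
#' deviation at which unit-intensity blood reaches `snr` in a single coil
#' image (before coil combination; root-sum-of-squares combination of `nc`
#' similar channels improves this by roughly `sqrt(nc)`).
#'
#' @param dcf density-compensation weights of the gridded trajectory.
#' @param dx_mm image voxel size (mm).
#' @param snr target single-coil blood SNR.
#' @param blood_intensity blood signal level.
#' @return k-space complex noise sd.
#' @export
noise_sd_for_snr <- function(dcf, dx_mm, snr = 15, blood_intensity = 1) {
  # image noise sd = noise_sd * dx^2 * sqrt(sum(w^2)) for the scaled adjoint
  blood_intensity / (snr * dx_mm^2 * sqrt(sum(dcf^2)))
}
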