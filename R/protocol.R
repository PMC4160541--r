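#' Acquisition protocol for the 3D stack-of-spirals cine sequence
#'
#' Validated record of every acquisition parameter of the ECG-gated 3D
#' stack-of-spirals bSSFP cine protocol. Derived quantities (temporal
#' footprint, in-plane resolution, acceleration, calibration-scan duration,
#' banding interval, encoded partition count) are never stored; they are
#' computed on demand by the `protocol_*` / arithmetic helpers and collected
#' by [protocol_report()].
#'
#' @param tr_ms repetition time (ms).
#' @param te_ms echo time (ms).
#' @param fov_mm in-plane field of view (square, mm).
#' @param matrix in-plane matrix size (square).
#' @param arms_total spiral interleaves needed for Nyquist coverage.
#' @param arms_acquired interleaves acquired per partition encode per
#'   timeframe (undersampling keeps every `arms_total / arms_acquired`-th arm).
#' @param partitions_nominal slice-direction partitions before oversampling.
#' @param partition_oversampling oversampling fraction (e.g. 0.33).
#' @param partition_thickness_mm partition thickness (mm).
#' @param readout_bandwidth_hz_per_px readout bandwidth (Hz/pixel).
#' @param flip_deg nominal flip angle (degrees).
#' @param calibration_repetitions fully sampled free-breathing repetitions
#'   acquired for through-time calibration.
#' @return object of class `sequence_protocol`.
#' @examples
#' p <- sequence_protocol()
#' protocol_report(p)$temporal_footprint_ms  # 35
#' @export
sequence_protocol <- function(tr_ms = 4.4,
                              te_ms = 2.2,
                              fov_mm = 316,
                              matrix = 128,
                              arms_total = 48,
                              arms_acquired = 8,
                              partitions_nominal = 12,
                              partition_oversampling = 0.33,
                              partition_thickness_mm = 8,
                              readout_bandwidth_hz_per_px = 1563,
                              flip_deg = 29,
                              calibration_repetitions = 10) {
  p <- list(
    tr_ms = tr_ms, te_ms = te_ms, fov_mm = fov_mm, matrix = as.integer(matrix),
    arms_total = as.integer(arms_total), arms_acquired = as.integer(arms_acquired),
    partitions_nominal = as.integer(partitions_nominal),
    partition_oversampling = partition_oversampling,
    partition_thickness_mm = partition_thickness_mm,
    readout_bandwidth_hz_per_px = readout_bandwidth_hz_per_px,
    flip_deg = flip_deg,
    calibration_repetitions = as.integer(calibration_repetitions)
  )
  counts <- c("matrix", "arms_total", "arms_acquired", "partitions_nominal")
  for (f in counts) {
    if (p[[f]] < 1L) stop("'", f, "' must be >= 1")
  }
  if (p$tr_ms <= 0) stop("'tr_ms' must be > 0")
  if (p$fov_mm <= 0) stop("'fov_mm' must be > 0")
  if (p$partition_oversampling < 0) stop("'partition_oversampling' must be >= 0")
  if (p$calibration_repetitions < 0) stop("'calibration_repetitions' must be >= 0")
  if (p$arms_total %% p$arms_acquired != 0L) {
    stop("irregular undersampling pattern: 'arms_total' (", p$arms_total,
         ") is not divisible by 'arms_acquired' (", p$arms_acquired, ")")
  }
  structure(p, class = "sequence_protocol")
}

#' Reference 2D segmented cine protocol
#'
#' Record of the multi-breathhold 2D Cartesian GRAPPA cine protocol used as
#' the clinical comparison; only its timing/resolution arithmetic is
#' represented (no 2D reconstruction is performed by this package).
#'
#' @param tr_ms repetition time (ms).
#' @param lines_acquired phase-encode lines acquired (before zero-filling).
#' @param lines_zerofilled phase-encode lines after symmetric zero-filling.
#' @param grappa_r Cartesian GRAPPA acceleration factor.
#' @param segment_size phase-encode lines collected per heartbeat.
#' @param fov_ro_mm field of view along the readout direction (mm).
#' @param matrix_ro matrix size along the readout direction.
#' @param dummy_beats heartbeats discarded to reach steady state.
#' @return object of class `protocol_2d`.
#' @export
protocol_2d <- function(tr_ms = 3.26,
                        lines_acquired = 144,
                        lines_zerofilled = 174,
                        grappa_r = 2,
                        segment_size = 12,
                        fov_ro_mm = 340,
                        matrix_ro = 208,
                        dummy_beats = 1) {
  p <- list(tr_ms = tr_ms, lines_acquired = as.integer(lines_acquired),
            lines_zerofilled = as.integer(lines_zerofilled),
            grappa_r = as.integer(grappa_r), segment_size = as.integer(segment_size),
            fov_ro_mm = fov_ro_mm, matrix_ro = as.integer(matrix_ro),
            dummy_beats = as.integer(dummy_beats))
  if (p$segment_size < 1L) stop("'segment_size' must be >= 1")
  if (p$grappa_r < 1L) stop("'grappa_r' must be >= 1")
  if (p$lines_zerofilled < p$lines_acquired) {
    stop("'lines_zerofilled' must be >= 'lines_acquired'")
  }
  structure(p, class = "protocol_2d")
}

#' In-plane parallel-imaging acceleration factor
#'
#' @param arms_total interleaves for Nyquist coverage.
#' @param arms_acquired interleaves actually acquired per partition encode.
#' @return integer acceleration factor R.
#' @examples
#' acceleration_factor(48, 8)  # 6
#' @export
acceleration_factor <- function(arms_total, arms_acquired) {
  stopifnot(arms_total >= 1, arms_acquired >= 1)
  if (arms_total %% arms_acquired != 0) {
    stop("irregular undersampling pattern: ", arms_total,
         " arms are not evenly divided by ", arms_acquired, " acquired arms")
  }
  as.integer(arms_total / arms_acquired)
}

#' Temporal footprint per cardiac phase
#'
#' Time spent within each heartbeat collecting the data of one cardiac-phase
#' image: number of excitations per phase times TR, rounded half-up to
#' integer milliseconds.
#'
#' @param units_per_phase excitations (arms or phase-encode lines) per phase.
#' @param tr_ms repetition time (ms).
#' @return integer milliseconds.
#' @examples
#' temporal_footprint_ms(8, 4.4)    # 35
#' temporal_footprint_ms(12, 3.26)  # 39
#' @export
temporal_footprint_ms <- function(units_per_phase, tr_ms) {
  stopifnot(units_per_phase > 0, tr_ms > 0)
  round_half_up(units_per_phase * tr_ms)
}

#' In-plane spatial resolution
#'
#' @param fov_mm field of view (mm).
#' @param matrix matrix size.
#' @return resolution in mm, rounded half-up to 2 decimals.
#' @examples
#' in_plane_resolution_mm(316, 128)  # 2.47
#' @export
in_plane_resolution_mm <- function(fov_mm, matrix) {
  stopifnot(fov_mm > 0, matrix > 0)
  round_half_up(fov_mm / matrix, 2)
}

#' Duration of the free-breathing calibration scan
#'
#' All arms in every encoded partition, repeated `repetitions` times, one TR
#' per arm; rounded half-up to integer seconds.
#'
#' @param arms_total spiral interleaves per partition.
#' @param partitions_encoded encoded partitions (including oversampling).
#' @param repetitions fully sampled repetitions.
#' @param tr_ms repetition time (ms).
#' @return integer seconds.
#' @examples
#' calibration_duration_s(48, 16, 10, 4.4)  # 34
#' calibration_duration_s(48, 16, 2, 4.4)   # 7
#' @export
calibration_duration_s <- function(arms_total, partitions_encoded, repetitions, tr_ms) {
  stopifnot(arms_total > 0, partitions_encoded > 0, repetitions >= 0, tr_ms > 0)
  round_half_up(arms_total * partitions_encoded * repetitions * tr_ms / 1000)
}

#' Time separating consecutive acquired arms in the calibration data
#'
#' In the fully sampled calibration scan the arms that sit `r` positions
#' apart (the acquired-arm stride of the undersampled dynamic scan) are
#' separated by `r * TR`; the heart is quasi-stationary on this timescale,
#' which is what makes the fully sampled repetitions usable for calibration.
#'
#' @param r acceleration factor.
#' @param tr_ms repetition time (ms).
#' @return integer milliseconds.
#' @examples
#' calibration_arm_separation_ms(6, 4.4)  # 26
#' @export
calibration_arm_separation_ms <- function(r, tr_ms) {
  stopifnot(r >= 1, tr_ms > 0)
  round_half_up(r * tr_ms)
}

#' Off-resonance interval between bSSFP signal nulls
#'
#' Dark-band (signal null) spacing of a balanced SSFP sequence: 1/TR.
#'
#' @param tr_ms repetition time (ms).
#' @return integer Hz.
#' @examples
#' bssfp_band_spacing_hz(4.4)  # 227
#' @export
bssfp_band_spacing_hz <- function(tr_ms) {
  stopifnot(tr_ms > 0)
  round_half_up(1000 / tr_ms)
}

#' Number of encoded slice-direction partitions
#'
#' Nominal partitions inflated by the slab oversampling fraction, rounded up,
#' then rounded up to the nearest even integer so the partition DFT stays
#' symmetric about DC.
#'
#' @param partitions_nominal nominal partitions.
#' @param oversampling oversampling fraction (e.g. 0.33).
#' @return integer count.
#' @examples
#' encoded_partitions(12, 0.33)  # 16
#' @export
encoded_partitions <- function(partitions_nominal, oversampling) {
  stopifnot(partitions_nominal >= 1, oversampling >= 0)
  n <- ceiling(partitions_nominal * (1 + oversampling))
  as.integer(n + n %% 2)
}

#' Heartbeats needed to encode one 2D segmented cine slice
#'
#' @param lines_acquired phase-encode lines acquired.
#' @param grappa_r Cartesian GRAPPA factor.
#' @param segment_size lines per heartbeat.
#' @param dummy_beats steady-state preparation beats.
#' @return named integer vector `c(imaging = ..., total = ...)`.
#' @examples
#' heartbeats_per_2d_slice(144, 2, 12, 1)  # imaging 6, total 7
#' @export
heartbeats_per_2d_slice <- function(lines_acquired, grappa_r, segment_size, dummy_beats) {
  stopifnot(lines_acquired >= 1, grappa_r >= 1, segment_size >= 1, dummy_beats >= 0)
  imaging <- as.integer(ceiling(lines_acquired / grappa_r / segment_size))
  c(imaging = imaging, total = imaging + as.integer(dummy_beats))
}

#' Breathhold duration of the dynamic 3D scan
#'
#' The partition encode advances once per ECG trigger, so the breathhold
#' spans one RR interval per encoded partition.
#'
#' @param partitions_encoded encoded partitions.
#' @param rr_ms RR interval (ms).
#' @return seconds (not rounded).
#' @examples
#' breathhold_duration_s(16, 1000)  # 16
#' @export
breathhold_duration_s <- function(partitions_encoded, rr_ms) {
  if (!(partitions_encoded > 0)) stop("'partitions_encoded' must be > 0")
  if (!(rr_ms > 0)) stop("'rr_ms' must be > 0")
  partitions_encoded * rr_ms / 1000
}

#' All derived protocol quantities
#'
#' @param protocol a [sequence_protocol()].
#' @param protocol2d optionally a [protocol_2d()] whose comparison arithmetic
#'   is appended.
#' @return named list of derived quantities.
#' @export
protocol_report <- function(protocol, protocol2d = NULL) {
  p <- protocol
  r <- acceleration_factor(p$arms_total, p$arms_acquired)
  enc <- encoded_partitions(p$partitions_nominal, p$partition_oversampling)
  rep <- list(
    acceleration_factor = r,
    temporal_footprint_ms = temporal_footprint_ms(p$arms_acquired, p$tr_ms),
    in_plane_resolution_mm = in_plane_resolution_mm(p$fov_mm, p$matrix),
    encoded_partitions = enc,
    calibration_duration_s = calibration_duration_s(
      p$arms_total, enc, p$calibration_repetitions, p$tr_ms),
    calibration_arm_separation_ms = calibration_arm_separation_ms(r, p$tr_ms),
    bssfp_band_spacing_hz = bssfp_band_spacing_hz(p$tr_ms)
  )
  if (!is.null(protocol2d)) {
    q <- protocol2d
    hb <- heartbeats_per_2d_slice(q$lines_acquired, q$grappa_r, q$segment_size,
                                  q$dummy_beats)
    rep$protocol_2d <- list(
      temporal_footprint_ms = temporal_footprint_ms(q$segment_size, q$tr_ms),
      in_plane_resolution_mm = in_plane_resolution_mm(q$fov_ro_mm, q$matrix_ro),
      imaging_heartbeats_per_slice = unname(hb["imaging"]),
      total_heartbeats_per_slice = unname(hb["total"])
    )
  }
  rep
}

#' @export
print.sequence_protocol <- function(x, ...) {
  cat("3D stack-of-spirals bSSFP cine protocol\n")
  cat(sprintf("  TR %.2f ms, FOV %g mm, matrix %d, %d/%d arms (R = %d)\n",
              x$tr_ms, x$fov_mm, x$matrix, x$arms_acquired, x$arms_total,
              acceleration_factor(x$arms_total, x$arms_acquired)))
  cat(sprintf("  %d partitions (+%.0f%% oversampling -> %d encoded) at %g mm\n",
              x$partitions_nominal, 100 * x$partition_oversampling,
              encoded_partitions(x$partitions_nominal, x$partition_oversampling),
              x$partition_thickness_mm))
  cat(sprintf("  %d fully sampled calibration repetitions\n",
              x$calibration_repetitions))
  invisible(x)
}
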