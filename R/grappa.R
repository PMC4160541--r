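#' Spiral GRAPPA kernel specification
#'
#' Geometry of the through-time spiral GRAPPA kernel: each missing sample is
#' synthesized from the two acquired arms flanking it (`source_arms = 2`) at
#' three readout positions centred on the target (`source_readout = 3`),
#' across all channels, giving `n_channels * 2 * 3` unknowns per target
#' channel. Kernel geometry is presumed similar over
#' `segment_arms x segment_readout` blocks of k-space (default 1 x 8: one
#' arm gap by eight readout points), so all readout points of a segment
#' share one calibrated weight block and contribute calibration equations
#' to it.
#'
#' @param n_channels receiver channels.
#' @param source_arms acquired arms used as sources (the flanking pair).
#' @param source_readout readout positions per source arm.
#' @param segment_arms arm extent of a trajectory segment.
#' @param segment_readout readout extent of a trajectory segment.
#' @return object of class `kernel_spec`.
#' @export
kernel_spec <- function(n_channels, source_arms = 2, source_readout = 3,
                        segment_arms = 1, segment_readout = 8) {
  stopifnot(n_channels >= 1, source_arms >= 1, source_readout >= 1,
            segment_arms >= 1, segment_readout >= 1)
  structure(list(n_channels = as.integer(n_channels),
                 source_arms = as.integer(source_arms),
                 source_readout = as.integer(source_readout),
                 segment_arms = as.integer(segment_arms),
                 segment_readout = as.integer(segment_readout),
                 n_unknowns = as.integer(n_channels * source_arms * source_readout)),
            class = "kernel_spec")
}

# readout indices of segment s (1-based)
segment_points <- function(n_readout, segment_readout, s) {
  lo <- (s - 1L) * segment_readout + 1L
  seq(lo, min(lo + segment_readout - 1L, n_readout))
}

#' Enumerate spiral GRAPPA kernel geometries
#'
#' One geometry per (acquired-arm gap, missing-arm offset, readout segment):
#' every missing sample of the undersampling pattern is covered by exactly
#' one geometry. Each geometry names the missing arm, its two flanking
#' acquired source arms (wrapping azimuthally), the readout points of its
#' segment, and the clamped source readout offsets used at the ends of the
#' readout.
#'
#' @param traj a `spiral_trajectory` (truncated).
#' @param pattern an [undersampling_pattern()].
#' @param spec a [kernel_spec()].
#' @return list of geometries (empty when `r = 1`); each element has fields
#'   `gap`, `offset`, `segment`, `missing_arm`, `arm_left`, `arm_right`
#'   (0-based arms), `points` (readout indices) and `key`.
#' @export
build_kernel_geometries <- function(traj, pattern, spec) {
  stopifnot(inherits(pattern, "sampling_pattern"), inherits(spec, "kernel_spec"))
  r <- pattern$r
  if (r == 1L) return(list())
  n_seg <- ceiling(traj$n_readout / spec$segment_readout)
  acq <- pattern$acquired
  geoms <- list()
  i <- 0L
  for (g in seq_along(acq)) {
    left <- acq[g]
    right <- acq[if (g == length(acq)) 1L else g + 1L]
    for (m in seq_len(r - 1L)) {
      missing <- (left + m) %% pattern$arms_total
      for (s in seq_len(n_seg)) {
        i <- i + 1L
        geoms[[i]] <- list(
          gap = g, offset = m, segment = s,
          missing_arm = missing, arm_left = left, arm_right = right,
          points = segment_points(traj$n_readout, spec$segment_readout, s),
          key = sprintf("g%d_m%d_s%d", g, m, s))
      }
    }
  }
  geoms
}

# Gather the stacked source matrix S (rows x n_unknowns) and target matrix
# T (rows x n_channels) for one geometry from a [read, arm, ch, part, frame]
# array. Rows run over (point-in-segment, partition, frame/repetition).
# Column order: (source arm side, readout offset) outer, channel inner.
# `arm_col` maps 0-based arm index -> column in the array's arm dimension.
gather_block <- function(arr, geom, spec, arm_col, with_target = TRUE) {
  nr <- dim(arr)[1]
  offs <- seq_len(spec$source_readout) - 1L - (spec$source_readout - 1L) %/% 2L
  pts <- geom$points
  sides <- c(geom$arm_left, geom$arm_right)
  cols <- vector("list", length(sides) * length(offs))
  j <- 0L
  for (a in sides) {
    ac <- arm_col[[as.character(a)]]
    if (is.null(ac)) stop("source arm ", a, " not present in data")
    for (o in offs) {
      j <- j + 1L
      idx <- clamp(pts + o, 1L, nr)
      blk <- arr[idx, ac, , , , drop = FALSE]   # npts x 1 x nch x npart x nfr
      blk <- aperm(array(blk, dim(blk)[c(1, 3, 4, 5)]), c(1, 3, 4, 2))
      cols[[j]] <- matrix(blk, ncol = dim(arr)[3])
    }
  }
  S <- do.call(cbind, cols)
  out <- list(S = S)
  if (with_target) {
    tc <- arm_col[[as.character(geom$missing_arm)]]
    if (is.null(tc)) stop("target arm ", geom$missing_arm, " not present in data")
    blk <- arr[pts, tc, , , , drop = FALSE]
    blk <- aperm(array(blk, dim(blk)[c(1, 3, 4, 5)]), c(1, 3, 4, 2))
    out$target <- matrix(blk, ncol = dim(arr)[3])
  }
  out
}

# complex least squares with optional Tikhonov ridge; falls back to a
# minimum-norm pseudo-inverse solution when the system is rank deficient
solve_weights <- function(S, T, ridge = 0) {
  if (ridge > 0) {
    p <- ncol(S)
    S <- rbind(S, sqrt(ridge) * diag(1 + 0i, p))
    T <- rbind(T, matrix(0i, p, ncol(T)))
  }
  W <- if (nrow(S) >= ncol(S)) {
    tryCatch(qr.solve(S, T), error = function(e) NULL)
  } else NULL
  if (!is.null(W) && any(!is.finite(Re(W)) | !is.finite(Im(W)))) W <- NULL
  if (is.null(W)) {
    warning("rank-deficient calibration block; using minimum-norm solution")
    sv <- svd(S)
    tol <- max(dim(S)) * .Machine$double.eps * sv$d[1]
    pos <- sv$d > tol
    W <- sv$v[, pos, drop = FALSE] %*%
      ((Conj(t(sv$u[, pos, drop = FALSE])) %*% T) / sv$d[pos])
  }
  W
}

#' Calibrate one spiral GRAPPA weight block
#'
#' Solves, per target channel, the least-squares problem `min ||S w - t||^2
#' (+ ridge ||w||^2)` whose rows stack the exact replicas of the local
#' sampling pattern found in the fully sampled calibration data: one
#' equation per (repetition x partition x readout point in the segment).
#' Through-time (repetitions), through-k-space (segment points) and
#' through-volume (partitions) information is thereby combined.
#'
#' @param calib a calibration `kspace_set` (all arms present) or its data
#'   array `[read, arm, ch, part, rep]` covering all arms in order.
#' @param geometry one geometry from [build_kernel_geometries()].
#' @param spec a [kernel_spec()].
#' @param ridge Tikhonov regularization scalar (default 0: plain least
#'   squares).
#' @return list with `W` (complex `n_unknowns x n_channels` weight matrix),
#'   `residual` (per-target-channel residual norms), `n_equations`.
#' @export
calibrate_weights <- function(calib, geometry, spec, ridge = 0) {
  arr <- if (inherits(calib, "kspace_set")) calib$data else calib
  arms <- if (inherits(calib, "kspace_set")) calib$arms else seq_len(dim(arr)[2]) - 1L
  arm_col <- as.list(stats::setNames(seq_along(arms), as.character(arms)))
  gb <- gather_block(arr, geometry, spec, arm_col)
  W <- solve_weights(gb$S, gb$target, ridge)
  res <- sqrt(colSums(Mod(gb$S %*% W - gb$target)^2))
  list(W = W, residual = res, n_equations = nrow(gb$S))
}

#' Calibrate the full through-time spiral GRAPPA weight set
#'
#' @param calib calibration `kspace_set` containing all arms and at least
#'   one repetition.
#' @param traj a `spiral_trajectory`.
#' @param pattern an [undersampling_pattern()].
#' @param spec a [kernel_spec()]; defaults to the 2-arm x 3-readout kernel
#'   with 1 x 8 segmentation at the set's channel count.
#' @param ridge Tikhonov regularization scalar.
#' @return object of class `grappa_weights`: named list of weight blocks
#'   keyed by geometry plus the spec and geometry list.
#' @export
calibrate_grappa <- function(calib, traj, pattern,
                             spec = kernel_spec(calib$n_channels),
                             ridge = 0) {
  stopifnot(inherits(calib, "kspace_set"), calib$kind == "calibration")
  if (length(calib$arms) != pattern$arms_total) {
    stop("calibration set must contain all ", pattern$arms_total, " arms")
  }
  geoms <- build_kernel_geometries(traj, pattern, spec)
  blocks <- list()
  for (g in geoms) {
    blocks[[g$key]] <- calibrate_weights(calib, g, spec, ridge)
  }
  structure(list(blocks = blocks, geometries = geoms, spec = spec,
                 pattern = pattern, n_readout = traj$n_readout),
            class = "grappa_weights")
}

#' Apply spiral GRAPPA weights to undersampled dynamic data
#'
#' Acquired samples pass through unchanged (bitwise); every missing sample
#' is synthesized by applying its geometry's weight block to the stacked
#' source vector. The same weight block is re-used at the same spiral
#' sampling location in every partition encode and every timeframe.
#'
#' @param dynamic a dynamic `kspace_set` (acquired arms only).
#' @param weights a [calibrate_grappa()] `grappa_weights` object.
#' @param traj the `spiral_trajectory`.
#' @param pattern the [undersampling_pattern()] of the acquisition.
#' @return complex array `[read, arm, ch, part, frame]` over all arms.
#' @export
apply_weights <- function(dynamic, weights, traj, pattern) {
  stopifnot(inherits(dynamic, "kspace_set"), inherits(weights, "grappa_weights"))
  d <- dim(dynamic$data)
  narms <- pattern$arms_total
  filled <- array(0i, c(d[1], narms, d[3], d[4], d[5]))
  filled[, pattern$acquired + 1L, , , ] <- dynamic$data
  arm_col <- as.list(stats::setNames(pattern$acquired + 1L,
                                     as.character(pattern$acquired)))
  geoms <- build_kernel_geometries(traj, pattern, weights$spec)
  for (g in geoms) {
    blk <- weights$blocks[[g$key]]
    if (is.null(blk)) {
      stop("no calibrated weights for geometry ", g$key,
           " (missing arm ", g$missing_arm, ", segment ", g$segment, ")")
    }
    gb <- gather_block(filled, g, weights$spec, arm_col, with_target = FALSE)
    M <- gb$S %*% blk$W                      # rows x nch
    npts <- length(g$points)
    M <- array(M, c(npts, d[4], d[5], d[3]))  # pts, part, frame, ch
    filled[g$points, g$missing_arm + 1L, , , ] <- aperm(M, c(1, 4, 2, 3))
  }
  filled
}

#' @export
print.grappa_weights <- function(x, ...) {
  cat(sprintf(paste0("through-time spiral GRAPPA weights: %d blocks ",
                     "(%d x %d per block), %d-point segments\n"),
              length(x$blocks), x$spec$n_unknowns, x$spec$n_channels,
              x$spec$segment_readout))
  invisible(x)
}
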