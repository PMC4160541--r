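# Shared fixtures, built once per test run and cached across files.

.fx_cache <- new.env(parent = emptyenv())

# Desk-scale study fixture: the default phantom/protocol configuration with
# three acquisition conditions (motionless noiseless, free-breathing
# noiseless, free-breathing noisy) and the reconstructions the acceptance
# properties are stated on.
desk_fixture <- function() {
  if (!is.null(.fx_cache$desk)) return(.fx_cache$desk)
  arm <- design_variable_density_spiral(fov_mm = 280, matrix = 64,
                                        arms_total = 24)
  traj <- spiral_trajectory(arm, 24)
  pattern <- undersampling_pattern(24, 6)
  enc <- make_encoding(as.vector(traj$k), 64, 280)
  dcf <- density_compensation(traj)
  ph <- lv_phantom()
  sens <- make_coil_sensitivities(8)
  voxel <- c(280 / 64, 280 / 64, 8)
  noise_sd <- noise_sd_for_snr(dcf, 280 / 64, snr = 15)

  sim_still <- simulate_kspace(ph, sens, traj, pattern,
                               acquisition_sim(0, 0, 10, seed = 7),
                               encoding = enc)
  sim_breath <- simulate_kspace(ph, sens, traj, pattern,
                                acquisition_sim(0, 10, 10, seed = 7),
                                encoding = enc)
  sim_noisy <- simulate_kspace(ph, sens, traj, pattern,
                               acquisition_sim(noise_sd, 10, 10, seed = 7),
                               encoding = enc)

  full_set <- kspace_set(sim_still$full, 0:23, "dynamic", traj)
  reference <- reconstruct_series(full_set, NULL, traj,
                                  undersampling_pattern(24, 1), 8,
                                  encoding = enc, dcf = dcf,
                                  voxel_mm = voxel, tr_ms = 4.4)
  weights_still <- calibrate_grappa(sim_still$calibration, traj, pattern)
  filled_still <- apply_weights(sim_still$dynamic, weights_still, traj, pattern)
  recon <- function(sim, reps = NULL, method = "grappa") {
    cal <- sim$calibration
    if (!is.null(reps)) {
      cal <- kspace_set(cal$data[, , , , seq_len(reps), drop = FALSE],
                        cal$arms, "calibration", traj)
    }
    reconstruct_series(sim$dynamic, cal, traj, pattern, 8, method = method,
                       encoding = enc, dcf = dcf, voxel_mm = voxel,
                       tr_ms = 4.4)
  }
  ser_still <- reconstruct_series(sim_still$dynamic, NULL, traj, pattern, 8,
                                  weights = weights_still, encoding = enc,
                                  dcf = dcf, voxel_mm = voxel, tr_ms = 4.4)
  ser_breath <- recon(sim_breath)
  ser_noisy <- recon(sim_noisy)
  ser_zf <- recon(sim_breath, method = "zerofill")
  nrmse_reps <- vapply(c(1, 2, 10), function(r) {
    s <- recon(sim_breath, reps = r)
    nrmse_support(s, reference, ph)
  }, numeric(1))

  fx <- list(traj = traj, pattern = pattern, enc = enc, dcf = dcf, ph = ph,
             sens = sens, voxel = voxel, noise_sd = noise_sd,
             sim_still = sim_still, sim_breath = sim_breath,
             sim_noisy = sim_noisy, full_set = full_set,
             reference = reference, weights_still = weights_still,
             filled_still = filled_still, ser_still = ser_still,
             ser_breath = ser_breath, ser_noisy = ser_noisy, ser_zf = ser_zf,
             nrmse_reps = nrmse_reps, truth = sim_still$truth)
  .fx_cache$desk <- fx
  fx
}

# NRMSE over the torso support (central nominal slices, all phases)
nrmse_support <- function(series, reference, ph) {
  nz <- ph$grid_nz
  nom <- dim(series$arr)[3]
  lo <- floor((nz - nom) / 2)
  supp <- (make_lv_phantom(ph, 0)$vol > 0)[, , seq(lo + 1, lo + nom)]
  supp <- array(rep(supp, dim(series$arr)[4]), dim(series$arr))
  nrmse(series$arr, reference$arr, supp)
}

# Tiny trajectory/grid for fast transform-level tests.
small_fixture <- function() {
  if (!is.null(.fx_cache$small)) return(.fx_cache$small)
  arm <- design_variable_density_spiral(fov_mm = 256, matrix = 32,
                                        center_matrix = 8, center_arms = 4,
                                        arms_total = 12)
  traj <- spiral_trajectory(arm, 12)
  enc <- make_encoding(as.vector(traj$k), 32, 256)
  dcf <- density_compensation(traj)
  sens1 <- make_coil_sensitivities(1, grid_n = 32, grid_nz = 4,
                                   fov_mm = 256, dz_mm = 8)
  sens2 <- make_coil_sensitivities(2, grid_n = 32, grid_nz = 4,
                                   fov_mm = 256, dz_mm = 8)
  fx <- list(traj = traj, enc = enc, dcf = dcf, sens1 = sens1, sens2 = sens2)
  .fx_cache$small <- fx
  fx
}

# Synthetic calibration/dynamic sets in which every missing sample is
# exactly 0.5 * (left source + right source) at the same readout index,
# with otherwise independent random data: the least-squares calibration
# must recover that sparse weight pattern exactly.
planted_model <- function(seed = 1, nread = 24, narms = 12, r = 3, nc = 2,
                          npart = 3, nreps = 3, nframes = 2) {
  set.seed(seed)
  pattern <- undersampling_pattern(narms, r)
  traj <- structure(list(n_readout = nread, arms_total = narms,
                         k = matrix(0i, nread, narms), k_max = 1,
                         fov_mm = 256, matrix = 32, dwell_us = 5),
                    class = "spiral_trajectory")
  rnd <- function(n) complex(real = stats::rnorm(n),
                             imaginary = stats::rnorm(n))
  plant <- function(arr) {
    acq <- pattern$acquired
    for (g in seq_along(acq)) {
      left <- acq[g]
      right <- acq[if (g == length(acq)) 1L else g + 1L]
      for (m in seq_len(r - 1)) {
        miss <- (left + m) %% narms
        arr[, miss + 1, , , ] <- 0.5 * (arr[, left + 1, , , ] +
                                          arr[, right + 1, , , ])
      }
    }
    arr
  }
  calib <- plant(array(rnd(nread * narms * nc * npart * nreps),
                       c(nread, narms, nc, npart, nreps)))
  dyn_full <- plant(array(rnd(nread * narms * nc * npart * nframes),
                          c(nread, narms, nc, npart, nframes)))
  list(traj = traj, pattern = pattern, spec = kernel_spec(nc),
       calib = kspace_set(calib, 0:(narms - 1), "calibration"),
       dyn = kspace_set(dyn_full[, pattern$acquired + 1, , , , drop = FALSE],
                        pattern$acquired, "dynamic"),
       dyn_full = dyn_full, nc = nc)
}

# Brute-force two-sided exact p for the signed-rank statistic by
# enumerating all 2^n sign assignments (mid-ranks included).
wilcoxon_enum_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  ws <- signs %*% r
  p_le <- mean(ws <= w + 1e-9)
  p_ge <- mean(ws >= w - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Closed-form Welch statistic, written independently of welch_t_test()
welch_oracle <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}
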