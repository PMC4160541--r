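test_that("half-ellipsoid cavity volume matches the closed form and its rasterization", {
  # semi-axes 25 x 25 x 40 mm: (2/3) pi a b c = 52.36 mL
  v <- 2 / 3 * pi * 25 * 25 * 40 / 1000
  ph <- lv_phantom(grid_n = 128, fov_mm = 280, edv_ml = v, aspect = 40 / 25,
                   myo_volume_ml = 60)
  expect_equal(ph$a_ed, 25, tolerance = 1e-10)
  expect_equal(lv_blood_volume_ml(ph, 0), 52.36, tolerance = 1e-3)
  # voxel counting on the rasterized mask agrees within 2%
  m <- make_lv_phantom(ph, 0)
  vox_ml <- ph$dx_mm^2 * ph$dz_mm / 1000
  expect_lt(abs(sum(m$endo_mask) * vox_ml - v) / v, 0.02)
  expect_equal(m$blood_ml, v, tolerance = 1e-10)
})

test_that("default motion profile fixes ED at phase 0 and EF at 63%", {
  ph <- lv_phantom()
  gt <- ground_truth_function(ph)
  expect_equal(gt$ef_pct, 63)
  expect_equal(gt$edv_ml, 150)
  expect_equal(gt$esv_ml, 55.5)
  expect_identical(gt$ed_phase, 1L)
  expect_identical(gt$es_phase, 6L)  # t = 0.5 on the 10-phase grid
  # EDV 100 / ESV 37 parameterization and the mass constant
  gt2 <- ground_truth_function(lv_phantom(edv_ml = 100, ves_fraction = 0.37))
  expect_equal(gt2$ef_pct, 63)
  expect_equal(ground_truth_function(lv_phantom(myo_volume_ml = 140))$edm_g,
               147)
  # motionless phantom ejects nothing
  expect_equal(ground_truth_function(lv_phantom(ves_fraction = 1))$ef_pct, 0)
})

test_that("degenerate phantom requests are rejected or flagged", {
  expect_error(lv_phantom(myo_volume_ml = 0), "degenerate")
  expect_warning(lv_phantom(grid_n = 16), "too coarse")
  expect_true(all(make_lv_phantom(lv_phantom(), 0.3)$vol >= 0))
  # epicardium always strictly outside the endocardium
  ph <- lv_phantom()
  for (t in c(0, 0.25, 0.5)) {
    m <- make_lv_phantom(ph, t)
    expect_true(all(m$epi_mask[m$endo_mask]))
    expect_gt(sum(m$epi_mask), sum(m$endo_mask))
  }
})

test_that("coil sensitivities are smooth, distinct and nowhere jointly null", {
  s1 <- make_coil_sensitivities(1, grid_n = 32, grid_nz = 4)
  expect_true(all(s1$maps == 1 + 0i))
  s8 <- make_coil_sensitivities(8, grid_n = 64, grid_nz = 10)
  for (i in 1:7) expect_false(identical(s8$maps[, , , i], s8$maps[, , , i + 1]))
  rss <- sqrt(apply(Mod(s8$maps)^2, 1:3, sum))
  expect_true(all(rss > 0))
  # max relative voxel-to-voxel RSS step below 5% along every axis
  rel_step <- function(a, d) {
    n <- dim(a)[d]
    i1 <- lapply(dim(a), seq_len); i2 <- i1
    i1[[d]] <- 1:(n - 1); i2[[d]] <- 2:n
    x1 <- do.call(`[`, c(list(a), i1)); x2 <- do.call(`[`, c(list(a), i2))
    max(abs(x2 - x1) / pmax(x1, x2))
  }
  expect_lt(rel_step(rss, 1), 0.05)
  expect_lt(rel_step(rss, 2), 0.05)
  expect_lt(rel_step(rss, 3), 0.05)
})

test_that("forward encoding is linear, exact for deltas and flat along uniform z", {
  fx <- small_fixture()
  traj <- fx$traj
  # zero phantom encodes to exactly zero
  z <- encode_volume(array(0, c(32, 32, 4)), fx$sens1, traj, encoding = fx$enc)
  expect_true(all(z == 0))
  # single bright voxel at the grid centre: flat spectrum
  vol <- array(0, c(32, 32, 4)); vol[17, 17, 3] <- 1
  ks <- encode_volume(vol, fx$sens1, traj, encoding = fx$enc)
  m <- Mod(ks)
  expect_lt((max(m) - min(m)) / mean(m), 1e-6)
  # uniform along z concentrates energy in the central kz partition
  sl <- matrix(0, 32, 32); sl[10:20, 12:24] <- 1
  volz <- array(rep(sl, 4), c(32, 32, 4))
  ksz <- encode_volume(volz, fx$sens1, traj, encoding = fx$enc)
  en <- apply(Mod(ksz)^2, 4, sum)
  expect_gte(en[3] / sum(en), 0.99)
  # linearity
  set.seed(5)
  v1 <- array(runif(32 * 32 * 4), c(32, 32, 4))
  v2 <- array(runif(32 * 32 * 4), c(32, 32, 4))
  lhs <- encode_volume(2 * v1 - 3 * v2, fx$sens2, traj, encoding = fx$enc)
  rhs <- 2 * encode_volume(v1, fx$sens2, traj, encoding = fx$enc) -
    3 * encode_volume(v2, fx$sens2, traj, encoding = fx$enc)
  expect_lt(max(Mod(lhs - rhs)) / max(Mod(rhs)), 1e-9)
  expect_error(encode_volume(vol, fx$sens1, traj, arms = 13), "out of range")
})

test_that("simulation is seed-deterministic and calibration matches dynamic data when motionless", {
  fx <- small_fixture()
  ph <- suppressWarnings(lv_phantom(grid_n = 32, grid_nz = 4, fov_mm = 256,
                                    n_phases = 3, edv_ml = 60,
                                    myo_volume_ml = 50, base_z_mm = 8))
  pattern <- undersampling_pattern(12, 2)
  sim <- acquisition_sim(noise_sd = 0.1, resp_amplitude_mm = 8, n_reps = 3,
                         seed = 42)
  s1 <- simulate_kspace(ph, fx$sens2, fx$traj, pattern, sim, encoding = fx$enc)
  s2 <- simulate_kspace(ph, fx$sens2, fx$traj, pattern, sim, encoding = fx$enc)
  expect_identical(s1$dynamic$data, s2$dynamic$data)
  expect_identical(s1$calibration$data, s2$calibration$data)
  # motionless, noiseless: each calibration repetition is the fully sampled
  # timeframe at its drawn cardiac phase; dynamic frames are its arm subset
  s0 <- simulate_kspace(ph, fx$sens2, fx$traj, pattern,
                        acquisition_sim(0, 0, 3, seed = 9), encoding = fx$enc)
  for (r in 1:3) {
    expect_equal(s0$calibration$data[, , , , r],
                 s0$full[, , , , s0$calib_phases[r]], tolerance = 1e-12)
  }
  for (p in 1:3) {
    expect_identical(s0$dynamic$data[, , , , p],
                     s0$full[, pattern$acquired + 1, , , p])
  }
  expect_error(simulate_kspace(ph, fx$sens2, fx$traj,
                               structure(list(acquired = 12L, r = 1L,
                                              arms_total = 13L),
                                         class = "sampling_pattern"),
                               acquisition_sim(n_reps = 1)),
               "out of range")
})
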