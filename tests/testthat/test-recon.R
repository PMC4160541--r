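test_that("adjoint gridding is the exact adjoint and maps zero to zero", {
  fx <- small_fixture()
  enc <- fx$enc
  z <- grid_nufft(array(0i, c(fx$traj$n_readout, 12, 2, 3)), fx$traj, fx$dcf,
                  encoding = enc)
  expect_true(all(z == 0))
  set.seed(8)
  x <- complex(real = rnorm(32 * 32), imaginary = rnorm(32 * 32))
  y <- complex(real = rnorm(enc$n_samples), imaginary = rnorm(enc$n_samples))
  lhs <- sum(Conj(enc$forward(x)) * y)
  rhs <- sum(Conj(x) * enc$adjoint(y))
  expect_lt(Mod(lhs - rhs) / Mod(rhs), 1e-6)
})

test_that("flat k-space grids to a sharp centred point spread", {
  fx <- small_fixture()
  flat <- array(1 + 0i, c(fx$traj$n_readout, 12, 1, 1))
  img <- Mod(grid_nufft(flat, fx$traj, fx$dcf, encoding = fx$enc)[, , 1, 1])
  pk <- which(img == max(img), arr.ind = TRUE)[1, ]
  expect_equal(unname(pk), c(17, 17))  # centre voxel for n = 32
  far <- img
  far[14:20, 14:20] <- 0
  expect_gte(max(img) / max(far), 10)
})

test_that("partition DFT resolves slices and discards oversampling symmetrically", {
  # 16 encoded partitions -> 12 nominal slices, central block retained
  set.seed(10)
  vols <- array(0i, c(4, 4, 2, 16))
  vols[, , , 3:14] <- complex(real = rnorm(4 * 4 * 2 * 12),
                              imaginary = rnorm(4 * 4 * 2 * 12))
  hybrid <- fft_centered_along(vols, 4)
  back <- partition_fft(hybrid, 12)
  expect_equal(back, vols[, , , 3:14, drop = FALSE], tolerance = 1e-12)
  # signal confined to the central kz plane: all slices identical
  h2 <- array(0i, c(4, 4, 1, 10))
  h2[, , , 6] <- 1 + 2i  # DC plane for n = 10
  s2 <- partition_fft(h2, 8)
  for (z in 2:8) expect_equal(s2[, , , z], s2[, , , 1], tolerance = 1e-12)
  expect_error(partition_fft(h2, 12), "cannot retain")
})

test_that("two-slab object lands on the correct slices after the full z chain", {
  fx <- small_fixture()
  vol <- array(0, c(32, 32, 4))
  vol[12:20, 12:20, 1] <- 1
  vol[12:20, 12:20, 4] <- 2
  ks <- encode_volume(vol, fx$sens1, fx$traj, encoding = fx$enc)
  hyb <- grid_nufft(ks, fx$traj, fx$dcf, encoding = fx$enc)
  sl <- partition_fft(hyb, 4)
  en <- apply(Mod(sl[, , 1, ])^2, 3, sum)
  expect_identical(which.max(en), 4L)
  expect_identical(order(en, decreasing = TRUE)[2], 1L)
})

test_that("adaptive combination reduces to the single-coil magnitude and rank-1 scaling", {
  set.seed(12)
  v <- array(complex(real = rnorm(8 * 8 * 2), imaginary = rnorm(8 * 8 * 2)),
             c(8, 8, 2, 1))
  out <- adaptive_combine(v)
  expect_equal(out, Mod(v[, , , 1]), tolerance = 1e-10)
  # identical sensitivities across channels: proportional to any channel
  one <- array(complex(real = rnorm(16 * 16 * 2),
                       imaginary = rnorm(16 * 16 * 2)), c(16, 16, 2, 1))
  v4 <- array(rep(one, 4), c(16, 16, 2, 4))
  out4 <- adaptive_combine(v4)
  ratio <- out4 / Mod(one[, , , 1])
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-6)
  # an all-zero region stays zero
  v0 <- v; v0[1:8, 1:8, , ] <- 0
  expect_true(all(adaptive_combine(v0)[1:4, 1:4, 1] == 0))
})

test_that("normalization flattens Gaussian-lobe shading on a uniform object", {
  sens <- make_coil_sensitivities(8, grid_n = 64, grid_nz = 8, fov_mm = 280,
                                  dz_mm = 8, sigma_mm = 60)
  xs <- seq_len(64); xs <- (xs - 1 - 32) * (280 / 64)
  X <- matrix(rep(xs, each = 64), 64, 64); Y <- matrix(xs, 64, 64)
  torso <- (X / 120)^2 + (Y / 80)^2 <= 1
  vols <- sens$maps * array(rep(torso * 0.5, 8 * 8), c(64, 64, 8, 8))
  norm <- adaptive_combine(vols, normalize = TRUE)
  rss <- sqrt(apply(Mod(vols)^2, 1:3, sum))
  inner <- array(rep((X / 100)^2 + (Y / 65)^2 <= 1, 8), c(64, 64, 8))
  cv <- function(x) stats::sd(x) / mean(x)
  expect_lt(cv(norm[inner]), cv(rss[inner]))
  expect_true(all(norm >= 0))
})

test_that("fully sampled input bypasses GRAPPA and equals the staged pipeline bitwise", {
  fx <- desk_fixture()
  r1 <- undersampling_pattern(24, 1)
  ser <- reconstruct_series(fx$full_set, NULL, fx$traj, r1, 8,
                            encoding = fx$enc, dcf = fx$dcf,
                            voxel_mm = fx$voxel, tr_ms = 4.4)
  manual <- adaptive_combine(aperm(partition_fft(
    grid_nufft(fx$sim_still$full, fx$traj, fx$dcf, encoding = fx$enc), 8),
    c(1, 2, 4, 3, 5)))
  expect_identical(ser$arr, manual)
  expect_identical(ser$method, "fully-sampled")
})

test_that("the reconstruction chain before combination is linear in k-space", {
  fx <- small_fixture()
  set.seed(13)
  d <- c(fx$traj$n_readout, 12, 2, 4)
  k1 <- array(complex(real = rnorm(prod(d)), imaginary = rnorm(prod(d))), d)
  k2 <- array(complex(real = rnorm(prod(d)), imaginary = rnorm(prod(d))), d)
  lhs <- partition_fft(grid_nufft(3i * k1 - k2, fx$traj, fx$dcf,
                                  encoding = fx$enc), 4)
  rhs <- 3i * partition_fft(grid_nufft(k1, fx$traj, fx$dcf,
                                       encoding = fx$enc), 4) -
    partition_fft(grid_nufft(k2, fx$traj, fx$dcf, encoding = fx$enc), 4)
  expect_lt(max(Mod(lhs - rhs)) / max(Mod(rhs)), 1e-9)
})

test_that("reconstructed energy stays inside the phantom support", {
  fx <- desk_fixture()
  supp <- (make_lv_phantom(fx$ph, 0)$vol > 0)[, , 2:9]
  supp <- array(rep(supp, 10), dim(fx$ser_still$arr))
  frac <- sum(fx$ser_still$arr[!supp]^2) / sum(fx$ser_still$arr^2)
  expect_lt(frac, 0.05)
})

test_that("stage failures are reported with the failing stage", {
  fx <- desk_fixture()
  expect_error(reconstruct_series(fx$sim_still$dynamic, NULL, fx$traj,
                                  fx$pattern, 8),
               "\\[grappa\\].*calibration")
})
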