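test_that("kernel geometries cover every missing sample exactly once", {
  pm <- planted_model()
  spec <- pm$spec
  geoms <- build_kernel_geometries(pm$traj, pm$pattern, spec)
  n_seg <- ceiling(pm$traj$n_readout / spec$segment_readout)
  n_gaps <- length(pm$pattern$acquired)
  expect_length(geoms, (pm$pattern$r - 1) * n_gaps * n_seg)
  covered <- unlist(lapply(geoms, function(g)
    paste(g$missing_arm, g$points, sep = ":")))
  missing_arms <- setdiff(0:(pm$pattern$arms_total - 1), pm$pattern$acquired)
  expect_setequal(covered, as.vector(outer(missing_arms,
                                           seq_len(pm$traj$n_readout),
                                           paste, sep = ":")))
  expect_identical(anyDuplicated(covered), 0L)
  # fully sampled: nothing to synthesize
  expect_length(build_kernel_geometries(pm$traj,
                                        undersampling_pattern(12, 1), spec), 0)
  # full-scale readout: ceil(340 / 8) = 43 segments
  traj340 <- structure(list(n_readout = 340L, arms_total = 48L),
                       class = "spiral_trajectory")
  g340 <- build_kernel_geometries(traj340, undersampling_pattern(48, 6),
                                  kernel_spec(32))
  expect_length(g340, 5 * 8 * 43)
})

test_that("calibration block size matches the full-scale protocol arithmetic", {
  # 10 repetitions x 16 partitions x 8 segment points = 1280 equations
  # against 2 x 3 x n_channels unknowns per target channel
  set.seed(3)
  arr <- array(complex(real = rnorm(16 * 48 * 2 * 16 * 10),
                       imaginary = rnorm(16 * 48 * 2 * 16 * 10)),
               c(16, 48, 2, 16, 10))
  traj <- structure(list(n_readout = 16L, arms_total = 48L),
                    class = "spiral_trajectory")
  spec <- kernel_spec(2)
  g <- build_kernel_geometries(traj, undersampling_pattern(48, 6), spec)[[1]]
  blk <- calibrate_weights(arr, g, spec)
  expect_identical(blk$n_equations, 1280L)
  expect_identical(dim(blk$W), c(spec$n_unknowns, 2L))
  expect_identical(spec$n_unknowns, 12L)
})

test_that("least-squares calibration matches the normal-equations oracle", {
  set.seed(11)
  nread <- 16L; narms <- 6L; nc <- 2L; npart <- 4L; nreps <- 3L
  arr <- array(complex(real = rnorm(nread * narms * nc * npart * nreps),
                       imaginary = rnorm(nread * narms * nc * npart * nreps)),
               c(nread, narms, nc, npart, nreps))
  traj <- structure(list(n_readout = nread, arms_total = narms),
                    class = "spiral_trajectory")
  pattern <- undersampling_pattern(narms, 2)
  spec <- kernel_spec(nc)
  geoms <- build_kernel_geometries(traj, pattern, spec)
  for (g in geoms[c(1, 4, 6)]) {
    blk <- calibrate_weights(arr, g, spec)
    # brute-force assembly with explicit loops, independent of the package's
    # gathering code; columns ordered (source arm, readout offset) x channel
    S <- NULL; Tg <- NULL
    for (rep in seq_len(nreps)) for (p in seq_len(npart)) for (t in g$points) {
      row <- c()
      for (a in c(g$arm_left, g$arm_right)) for (o in -1:1) {
        row <- c(row, arr[min(max(t + o, 1), nread), a + 1, , p, rep])
      }
      S <- rbind(S, row)
      Tg <- rbind(Tg, arr[t, g$missing_arm + 1, , p, rep])
    }
    W_oracle <- solve(Conj(t(S)) %*% S, Conj(t(S)) %*% Tg)
    expect_lt(max(Mod(blk$W - W_oracle)), 1e-10)
  }
})

test_that("a planted linear relation is recovered exactly and applied exactly", {
  pm <- planted_model()
  w <- calibrate_grappa(pm$calib, pm$traj, pm$pattern, pm$spec)
  nc <- pm$nc
  W_true <- matrix(0i, pm$spec$n_unknowns, nc)
  for (ch in seq_len(nc)) {
    W_true[(2 - 1) * nc + ch, ch] <- 0.5  # left arm, offset 0
    W_true[(5 - 1) * nc + ch, ch] <- 0.5  # right arm, offset 0
  }
  for (blk in w$blocks) {
    expect_lt(max(Mod(blk$W - W_true)), 1e-8)
    expect_lt(max(blk$residual), 1e-8)
  }
  filled <- apply_weights(pm$dyn, w, pm$traj, pm$pattern)
  expect_lt(max(Mod(filled - pm$dyn_full)), 1e-8)
  # acquired samples pass through bitwise
  expect_identical(filled[, pm$pattern$acquired + 1, , , ], pm$dyn$data)
})

test_that("weight application is linear in the dynamic data", {
  pm <- planted_model(seed = 2)
  w <- calibrate_grappa(pm$calib, pm$traj, pm$pattern, pm$spec)
  f1 <- apply_weights(pm$dyn, w, pm$traj, pm$pattern)
  dyn2 <- kspace_set((2 - 1i) * pm$dyn$data, pm$pattern$acquired, "dynamic")
  f2 <- apply_weights(dyn2, w, pm$traj, pm$pattern)
  expect_lt(max(Mod(f2 - (2 - 1i) * f1)), 1e-10 * max(Mod(f1)))
})

test_that("rank-deficient calibration falls back to the minimum-norm solution", {
  set.seed(4)
  nread <- 4L
  arr <- array(complex(real = rnorm(nread * 6 * 4),
                       imaginary = rnorm(nread * 6 * 4)),
               c(nread, 6, 4, 1, 1))  # 4 equations vs 24 unknowns
  traj <- structure(list(n_readout = nread, arms_total = 6L),
                    class = "spiral_trajectory")
  spec <- kernel_spec(4)
  g <- build_kernel_geometries(traj, undersampling_pattern(6, 2), spec)[[1]]
  expect_warning(blk <- calibrate_weights(arr, g, spec), "rank-deficient")
  expect_true(all(is.finite(Mod(blk$W))))
  expect_lt(max(blk$residual), 1e-8)  # consistent underdetermined system
})

test_that("GRAPPA fills k-space far better than zero-filling on the desk phantom", {
  fx <- desk_fixture()
  zf <- array(0i, dim(fx$sim_still$full))
  zf[, fx$pattern$acquired + 1, , , ] <- fx$sim_still$dynamic$data
  e_grappa <- nrmse(fx$filled_still, fx$sim_still$full)
  e_zf <- nrmse(zf, fx$sim_still$full)
  expect_lt(e_grappa, e_zf)
  expect_lt(e_grappa, 0.05)
  # acquired samples pass through bitwise on simulated data too
  expect_identical(fx$filled_still[, fx$pattern$acquired + 1, , , ],
                   fx$sim_still$dynamic$data)
  # a missing weight block is reported with its geometry
  w2 <- fx$weights_still
  w2$blocks[[1]] <- NULL
  expect_error(apply_weights(fx$sim_still$dynamic, w2, fx$traj, fx$pattern),
               "no calibrated weights")
})
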