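test_that("variable-density spiral starts at the origin and reaches the designed edge in time", {
  arm <- design_variable_density_spiral()  # full-scale protocol
  expect_equal(Mod(arm$k[1]), 0)
  k_max <- 128 / (2 * 316)
  expect_equal(arm$k_max, k_max)
  kt <- Mod(arm$k[arm$truncation_index])
  expect_lt(abs(kt - k_max) / k_max, 0.01)
  t_edge <- arm$truncation_index * arm$dwell_us / 1000
  expect_lte(t_edge, 2.5)
  expect_gte(t_edge, 1.5)
  expect_lte(t_edge, 2.0)
  expect_error(design_variable_density_spiral(max_readout_ms = 0.5),
               "infeasible")
})

test_that("interleaf rotation is the unit phasor and preserves radius and truncation", {
  arm <- small_fixture()$traj$base_arm
  expect_identical(rotate_arm(arm, 0, 12)$k, arm$k)
  half <- rotate_arm(arm, 6, 12)
  expect_equal(half$k, -arm$k, tolerance = 1e-12)
  # explicit 2x2 rotation-matrix oracle at 2*pi/48
  base48 <- design_variable_density_spiral()
  r1 <- rotate_arm(base48, 1, 48)
  th <- 2 * pi / 48
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  xy <- R %*% rbind(Re(base48$k), Im(base48$k))
  expect_equal(r1$k, complex(real = xy[1, ], imaginary = xy[2, ]),
               tolerance = 1e-12)
  expect_equal(Mod(r1$k), Mod(base48$k), tolerance = 1e-12)
  expect_identical(r1$truncation_index, base48$truncation_index)
  expect_error(rotate_arm(arm, 12, 12), "out of range")
})

test_that("truncation keeps samples through the first edge crossing", {
  # synthetic arm with |k| a linear ramp crossing k_max = 1 at sample 101
  ramp <- structure(list(k = complex(real = (0:200) * 0.01), dwell_us = 5,
                         truncation_index = NA, k_max = 1, fov_mm = 256,
                         matrix = 32), class = "spiral_arm")
  tr <- truncate_at_kmax(ramp, 1)
  oracle <- which(Mod(ramp$k) >= 1)[1]
  expect_identical(length(tr$k), oracle)
  expect_identical(length(tr$k), 101L)
  expect_identical(truncate_at_kmax(tr, 1)$k, tr$k)  # idempotent
  expect_error(truncate_at_kmax(tr, 10), "never reaches")
})

test_that("undersampling pattern strides and its offsets tile the arm set", {
  expect_identical(undersampling_pattern(48, 6)$acquired,
                   as.integer(c(0, 6, 12, 18, 24, 30, 36, 42)))
  expect_identical(undersampling_pattern(48, 1)$acquired, 0:47)
  expect_identical(undersampling_pattern(6, 2, 1)$acquired,
                   as.integer(c(1, 3, 5)))
  expect_error(undersampling_pattern(48, 5), "irregular")
  expect_error(undersampling_pattern(48, 6, 6), "arm_offset")
  all_idx <- unlist(lapply(0:5, function(o)
    undersampling_pattern(48, 6, o)$acquired))
  expect_identical(sort(all_idx), 0:47)       # union covers all arms
  expect_identical(anyDuplicated(all_idx), 0L)  # pairwise disjoint
})

test_that("trajectory satisfies the Nyquist audit at full and centre density", {
  traj <- desk_fixture()$traj
  fov <- traj$fov_mm
  audit <- function(arms, r_lim) {
    mx <- 0
    for (i in seq_along(arms)) {
      a <- traj$k[, arms[i]]
      b <- traj$k[, arms[if (i == length(arms)) 1 else i + 1]]
      a <- a[Mod(a) <= r_lim]
      d2 <- outer(Re(a), Re(b), `-`)^2 + outer(Im(a), Im(b), `-`)^2
      mx <- max(mx, max(sqrt(apply(d2, 1, min))))
    }
    mx
  }
  expect_lte(audit(1:24, traj$k_max), 1 / fov)
  # four-arm subset covers the dense 8x8 centre alone
  expect_lte(audit(c(1, 7, 13, 19), 4 / fov), 1 / fov)
})

test_that("density compensation approximates k-space area elements", {
  fx <- desk_fixture()
  traj <- fx$traj
  dcf <- fx$dcf
  # single-sample trajectory: unit weight
  tiny <- structure(list(k = matrix(0.05 + 0i, 1, 3), arms_total = 3L,
                         n_readout = 1L, k_max = 0.1, fov_mm = 256,
                         matrix = 32L, dwell_us = 5), class = "spiral_trajectory")
  expect_equal(as.vector(density_compensation(tiny)), c(1, 1, 1))
  # total weight = area of the sampled disc, within 5%
  expect_lt(abs(sum(dcf) - pi * traj$k_max^2) / (pi * traj$k_max^2), 0.05)
  # uniform-density outer region: weights match the analytic area element
  # (arc spacing x line spacing = (margin/fov)^2) within 10%
  kk <- Mod(traj$k[, 1])
  w <- dcf[, 1]
  sel <- kk > 0.4 * traj$k_max & kk < 0.85 * traj$k_max
  analytic <- (0.88 / traj$fov_mm)^2
  expect_true(all(abs(w[sel] - analytic) / analytic < 0.10))
  # weights are positive and identical across rotated arms
  expect_true(all(dcf > 0))
  expect_equal(dcf[, 2], dcf[, 1])
})

test_that("density compensation sharpens the point-spread of flat k-space", {
  fx <- small_fixture()
  traj <- fx$traj
  flat <- rep(1 + 0i, length(traj$k))
  psf_w <- Mod(matrix(fx$enc$adjoint(as.vector(fx$dcf) * flat), 32, 32))
  psf_u <- Mod(matrix(fx$enc$adjoint(flat), 32, 32))
  ratio <- function(p) {
    pk <- which(p == max(p), arr.ind = TRUE)[1, ]
    side <- p
    side[pmax(pk[1] - 3, 1):pmin(pk[1] + 3, 32),
         pmax(pk[2] - 3, 1):pmin(pk[2] + 3, 32)] <- 0
    max(p) / max(side)
  }
  expect_gt(ratio(psf_w), ratio(psf_u))
})
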