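#' Dynamic left-ventricular phantom
#'
#' Analytic beating-LV phantom: the blood pool is a half ellipsoid
#' (base-to-apex along z, cut by the fixed base plane), the myocardium a
#' surrounding half-ellipsoidal shell of constant volume (incompressible
#' wall), embedded in an elliptic-cylinder torso of background tissue. The
#' cardiac cycle scales the endocardial semi-axes isotropically so that the
#' cavity volume follows `V(t) = V_ED (1 - (1 - ves_fraction) sin^2(pi t))`
#' for phase `t` in `[0, 1)`: end-diastole at `t = 0`, end-systole at
#' `t = 0.5`. All volumes are available in closed form, which makes
#' ejection-fraction recovery an exact-oracle test.
#'
#' @param grid_n in-plane grid size.
#' @param grid_nz encoded partitions (slab including oversampling).
#' @param fov_mm in-plane field of view (mm).
#' @param dz_mm partition thickness (mm).
#' @param edv_ml end-diastolic cavity volume (mL).
#' @param ves_fraction end-systolic volume as a fraction of EDV
#'   (default 0.37, i.e. ejection fraction 63%).
#' @param myo_volume_ml myocardial shell volume (mL), constant over the
#'   cycle.
#' @param n_phases cardiac phases per cycle.
#' @param lv_center_mm in-plane LV centre `(x, y)` in mm.
#' @param base_z_mm z position of the (fixed) base plane in mm.
#' @param aspect ratio of long semi-axis c to short semi-axis a at ED.
#' @param intensities named numeric vector with `blood`, `myocardium`,
#'   `tissue` signal levels (arbitrary units).
#' @param torso_semiaxes_mm in-plane torso semi-axes `(x, y)` in mm.
#' @return object of class `lv_phantom`.
#' @export
lv_phantom <- function(grid_n = 64, grid_nz = 10, fov_mm = 280, dz_mm = 8,
                       edv_ml = 150, ves_fraction = 0.37, myo_volume_ml = 120,
                       n_phases = 10,
                       lv_center_mm = c(-30, -15), base_z_mm = 28,
                       aspect = NULL,
                       intensities = c(blood = 1, myocardium = 0.3, tissue = 0.15),
                       torso_semiaxes_mm = c(120, 80)) {
  stopifnot(edv_ml > 0, ves_fraction > 0, ves_fraction <= 1, myo_volume_ml >= 0,
            n_phases >= 1, all(intensities >= 0))
  if (myo_volume_ml == 0) stop("zero-thickness myocardial shell is degenerate")
  if (is.null(aspect)) {
    # default long axis spans the nominal slab below the base plane
    c_ed <- 56
    a_ed <- sqrt(edv_ml * 1000 * 3 / (2 * pi * c_ed))
  } else {
    a_ed <- (edv_ml * 1000 * 3 / (2 * pi * aspect))^(1 / 3)
    c_ed <- aspect * a_ed
  }
  ph <- structure(list(
    grid_n = as.integer(grid_n), grid_nz = as.integer(grid_nz),
    fov_mm = fov_mm, dz_mm = dz_mm, dx_mm = fov_mm / grid_n,
    edv_ml = edv_ml, ves_fraction = ves_fraction,
    myo_volume_ml = myo_volume_ml, n_phases = as.integer(n_phases),
    lv_center_mm = lv_center_mm, base_z_mm = base_z_mm,
    a_ed = a_ed, c_ed = c_ed, intensities = intensities,
    torso_semiaxes_mm = torso_semiaxes_mm), class = "lv_phantom")
  # wall-thickness sanity at ES (thinnest grid coverage is in-plane)
  wes <- lv_wall_thickness(ph, 0.5)
  if (wes < 2 * ph$dx_mm) {
    warning("grid too coarse to resolve the myocardial shell (wall ",
            format(wes, digits = 3), " mm < 2 voxels)")
  }
  ph
}

# endocardial semi-axes (a, a, c) in mm at phase t
lv_semiaxes <- function(ph, t) {
  v <- lv_blood_volume_ml(ph, t)
  f <- (v / ph$edv_ml)^(1 / 3)
  c(a = ph$a_ed * f, c = ph$c_ed * f)
}

#' Analytic blood-pool volume at a cardiac phase
#'
#' @param ph an [lv_phantom()].
#' @param t cardiac phase in `[0, 1)`.
#' @return volume in mL (closed form, no rasterization).
#' @export
lv_blood_volume_ml <- function(ph, t) {
  stopifnot(all(t >= 0), all(t < 1))
  ph$edv_ml * (1 - (1 - ph$ves_fraction) * sin(pi * t)^2)
}

# epicardial wall thickness w(t): (a+w)^2 (c+w) = (V_endo + V_myo) 3/(2 pi)
lv_wall_thickness <- function(ph, t) {
  ax <- lv_semiaxes(ph, t)
  target <- (lv_blood_volume_ml(ph, t) + ph$myo_volume_ml) * 1000 * 3 / (2 * pi)
  f <- function(w) (ax["a"] + w)^2 * (ax["c"] + w) - target
  stats::uniroot(f, c(0, 100))$root
}

#' Rasterize the phantom at a cardiac phase
#'
#' Evaluates region membership on a subvoxel lattice (`oversample^3` points
#' per voxel) and averages, so voxel intensities carry partial-volume
#' information as a band-limited acquisition would.
#'
#' @param ph an [lv_phantom()].
#' @param t cardiac phase in `[0, 1)`.
#' @param oversample subvoxel sampling factor per axis.
#' @return list with `vol` (array `[y, x, z]` of intensities),
#'   `blood_ml` and `myo_ml` (analytic volumes), `endo_mask`, `epi_mask`
#'   (voxel-centre binary masks, array `[y, x, z]`).
#' @export
make_lv_phantom <- function(ph, t, oversample = 2) {
  stopifnot(inherits(ph, "lv_phantom"), t >= 0, t < 1, oversample >= 1)
  n <- ph$grid_n; nz <- ph$grid_nz
  dx <- ph$dx_mm; dz <- ph$dz_mm
  ax <- lv_semiaxes(ph, t)
  w <- lv_wall_thickness(ph, t)
  x0 <- ph$lv_center_mm[1]; y0 <- ph$lv_center_mm[2]; zb <- ph$base_z_mm
  tx <- ph$torso_semiaxes_mm[1]; ty <- ph$torso_semiaxes_mm[2]
  ints <- ph$intensities
  level <- function(xs, ys, zs) {
    # xs, ys, zs: coordinate vectors defining a lattice [y, x, z]
    nyl <- length(ys); nxl <- length(xs); nzl <- length(zs)
    X <- array(rep(xs, each = nyl), c(nyl, nxl, nzl))
    Y <- array(ys, c(nyl, nxl, nzl))
    Z <- array(rep(zs, each = nyl * nxl), c(nyl, nxl, nzl))
    torso <- (X / tx)^2 + (Y / ty)^2 <= 1
    below <- Z <= zb
    q_endo <- ((X - x0) / ax["a"])^2 + ((Y - y0) / ax["a"])^2 +
      ((Z - zb) / ax["c"])^2
    q_epi <- ((X - x0) / (ax["a"] + w))^2 + ((Y - y0) / (ax["a"] + w))^2 +
      ((Z - zb) / (ax["c"] + w))^2
    endo <- below & (q_endo <= 1)
    epi <- below & (q_epi <= 1)
    list(vol = ints["tissue"] * (torso & !epi) +
           ints["myocardium"] * (epi & !endo) +
           ints["blood"] * endo,
         endo = endo, epi = epi)
  }
  xs <- centered_coords(n, dx); zs <- centered_coords(nz, dz)
  if (oversample == 1) {
    lv <- level(xs, xs, zs)
    vol <- lv$vol
  } else {
    os <- oversample
    sub <- function(coords, d) {
      off <- ((seq_len(os) - 0.5) / os - 0.5) * d
      as.vector(t(outer(coords, off, `+`)))  # subpoints grouped per voxel
    }
    lvs <- level(sub(xs, dx), sub(xs, dx), sub(zs, dz))
    big <- lvs$vol
    # block-average os x os x os
    v <- array(big, c(os, n, os, n, os, nz))
    vol <- apply(v, c(2, 4, 6), mean)
    lv <- level(xs, xs, zs)  # voxel-centre masks
  }
  dimnames(vol) <- NULL
  list(vol = vol,
       blood_ml = lv_blood_volume_ml(ph, t),
       myo_ml = ph$myo_volume_ml,
       endo_mask = lv$endo, epi_mask = lv$epi)
}

#' Smooth complex coil sensitivity maps
#'
#' Gaussian magnitude lobes centred on a ring of coil positions around the
#' torso (alternating slightly above/below the slab midplane so channels
#' differ along z) with channel-specific linear phase ramps. Fully
#' deterministic for a given geometry. A single channel yields the uniform
#' unit map.
#'
#' @param n_channels number of receiver channels.
#' @param grid_n in-plane grid size.
#' @param grid_nz number of slices.
#' @param fov_mm in-plane field of view (mm).
#' @param dz_mm slice thickness (mm).
#' @param ring_radius_mm radius of the coil ring (mm).
#' @param sigma_mm Gaussian lobe width (mm).
#' @return object of class `coil_set`: complex array `[y, x, z, channel]`
#'   plus geometry attributes.
#' @export
make_coil_sensitivities <- function(n_channels, grid_n = 64, grid_nz = 10,
                                    fov_mm = 280, dz_mm = 8,
                                    ring_radius_mm = fov_mm / 2,
                                    sigma_mm = 110) {
  stopifnot(n_channels >= 1)
  n <- as.integer(grid_n); nz <- as.integer(grid_nz)
  maps <- array(0i, c(n, n, nz, n_channels))
  if (n_channels == 1) {
    maps[] <- 1 + 0i
  } else {
    xs <- centered_coords(n, fov_mm / n)
    zs <- centered_coords(nz, dz_mm)
    X <- matrix(rep(xs, each = n), n, n)
    Y <- matrix(xs, n, n)
    for (ch in seq_len(n_channels)) {
      phi <- 2 * pi * (ch - 1) / n_channels
      cx <- ring_radius_mm * cos(phi)
      cy <- ring_radius_mm * sin(phi)
      cz <- 30 * (-1)^ch
      ramp <- exp(2i * pi * (cos(phi) * X + sin(phi) * Y) / (6 * fov_mm) +
                    1i * phi)
      for (iz in seq_len(nz)) {
        d2 <- (X - cx)^2 + (Y - cy)^2 + (zs[iz] - cz)^2
        maps[, , iz, ch] <- exp(-d2 / (2 * sigma_mm^2)) * ramp
      }
    }
  }
  structure(list(maps = maps, n_channels = as.integer(n_channels)),
            class = "coil_set")
}

#' Ground-truth LV functional parameters of a phantom
#'
#' Evaluates the analytic volume profile on the phantom's phase grid and
#' reports EDV, ESV, SV, EF and EDM exactly as [functional_report()] would
#' from segmentation masks.
#'
#' @param ph an [lv_phantom()].
#' @param density_g_per_ml myocardial density (g/mL).
#' @return object of class `lv_function_report`.
#' @export
ground_truth_function <- function(ph, density_g_per_ml = 1.05) {
  t <- (seq_len(ph$n_phases) - 1) / ph$n_phases
  v <- vapply(t, function(ti) lv_blood_volume_ml(ph, ti), numeric(1))
  ed <- which.max(v); es <- which.min(v)
  new_function_report(edv = v[ed], esv = v[es],
                      edm = ph$myo_volume_ml * density_g_per_ml,
                      ed_phase = ed, es_phase = es)
}

#' @export
print.lv_phantom <- function(x, ...) {
  cat(sprintf(paste0("dynamic LV phantom: grid %d x %d x %d (%.2f x %.2f x %g mm), ",
                     "%d phases\n"),
              x$grid_n, x$grid_n, x$grid_nz, x$dx_mm, x$dx_mm, x$dz_mm,
              x$n_phases))
  cat(sprintf("  EDV %.1f mL, ESV %.1f mL (EF %.1f%%), myocardium %.1f mL\n",
              x$edv_ml, x$edv_ml * x$ves_fraction,
              100 * (1 - x$ves_fraction), x$myo_volume_ml))
  invisible(x)
}
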