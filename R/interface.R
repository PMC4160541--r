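#' Default pipeline configuration
#'
#' Nested configuration consumed by [run_pipeline()]. The defaults describe
#' the desk-scale study: a 64 x 64 in-plane grid over a 280 mm FOV, 24
#' spiral arms undersampled six-fold (4 acquired), 8 + 2 partitions at 8 mm,
#' 8 receiver channels and 10 cardiac phases, with 10 free-breathing
#' fully sampled calibration repetitions. The full-scale protocol (128
#' matrix, 48 arms, 32 channels, 12 + 4 partitions) is obtained by
#' overriding the corresponding keys.
#'
#' @return nested named list of class `pipeline_config`.
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    protocol = list(
      tr_ms = 4.4, te_ms = 2.2, fov_mm = 280, matrix = 64L,
      arms_total = 24L, arms_acquired = 4L,
      partitions_nominal = 8L, partition_oversampling = 0.25,
      partition_thickness_mm = 8, readout_bandwidth_hz_per_px = 1563,
      flip_deg = 29, calibration_repetitions = 10L),
    trajectory = list(center_matrix = 8L, center_arms = 4L, dwell_us = 5,
                      max_readout_ms = 2.5),
    phantom = list(edv_ml = 150, ves_fraction = 0.37, myo_volume_ml = 120,
                   n_phases = 10L),
    coils = list(n_channels = 8L),
    sim = list(noise_sd = 0, snr = NA, resp_amplitude_mm = 10),
    grappa = list(ridge = 0, segment_readout = 8L, source_readout = 3L),
    recon = list(normalize = FALSE, block = 8L, norm_sigma = 2),
    analysis = list(density_g_per_ml = 1.05, threshold = 0.65)
  ), class = "pipeline_config")
}

validate_config_keys <- function(cfg, ref, path = "") {
  for (k in names(cfg)) {
    if (!k %in% names(ref)) {
      stop("unknown configuration key: ", paste0(path, k))
    }
    if (is.list(ref[[k]]) && is.list(cfg[[k]])) {
      validate_config_keys(cfg[[k]], ref[[k]], paste0(path, k, "."))
    }
  }
  invisible(TRUE)
}

#' Load a pipeline configuration from YAML
#'
#' Keys absent from the file keep their defaults; keys unknown to
#' [default_config()] are rejected.
#'
#' @param path YAML file path.
#' @return `pipeline_config`.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  ref <- default_config()
  validate_config_keys(user, ref)
  merge <- function(ref, usr) {
    for (k in names(usr)) {
      ref[[k]] <- if (is.list(ref[[k]]) && is.list(usr[[k]]))
        merge(ref[[k]], usr[[k]]) else usr[[k]]
    }
    ref
  }
  structure(merge(unclass(ref), user), class = "pipeline_config")
}

raw_dim_order <- c("readout", "arm", "channel", "partition", "frame")

#' Write raw multi-channel non-Cartesian data to the package container
#'
#' Serializes calibration and dynamic sample sets with their arm indices,
#' dimension order and geometry attributes under fixed names
#' (`calibration/data`, `dynamic/data`, attributes `fov_mm`, `matrix`,
#' `dwell_us`) so foreign writers can declare a permuted dimension order
#' that [read_raw()] undoes.
#'
#' @param path output file.
#' @param calibration,dynamic `kspace_set` objects (either may be `NULL`).
#' @param attrs named list of geometry attributes.
#' @param dim_order character vector declaring the storage order of the
#'   five dimensions (a permutation of
#'   `c("readout","arm","channel","partition","frame")`).
#' @return `path`, invisibly.
#' @export
write_raw <- function(path, calibration = NULL, dynamic = NULL,
                      attrs = list(), dim_order = raw_dim_order) {
  stopifnot(setequal(dim_order, raw_dim_order))
  perm <- match(dim_order, raw_dim_order)
  pack <- function(ks) {
    if (is.null(ks)) return(NULL)
    list(data = aperm(ks$data, perm), arms = ks$arms, kind = ks$kind,
         dim_order = dim_order)
  }
  obj <- list(format = "spiralcine-raw", version = 1L,
              calibration = pack(calibration), dynamic = pack(dynamic),
              attrs = attrs)
  saveRDS(obj, path)
  invisible(path)
}

#' Read raw data written by [write_raw()]
#'
#' @param path container file.
#' @return list with `calibration` and `dynamic` `kspace_set`s (either may
#'   be `NULL`) and `attrs`.
#' @export
read_raw <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop("cannot read raw container '", path, "': ", conditionMessage(e))
  })
  if (!identical(obj$format, "spiralcine-raw")) {
    stop("not a spiralcine raw container: missing 'format' marker")
  }
  unpack <- function(x, name) {
    if (is.null(x)) return(NULL)
    for (f in c("data", "arms", "kind", "dim_order")) {
      if (is.null(x[[f]])) stop("raw container is missing dataset '",
                                name, "/", f, "'")
    }
    perm <- match(raw_dim_order, x$dim_order)
    if (any(is.na(perm))) stop("undeclared dimension order in '", name, "'")
    kspace_set(aperm(x$data, perm), arms = x$arms, kind = x$kind)
  }
  list(calibration = unpack(obj$calibration, "calibration"),
       dynamic = unpack(obj$dynamic, "dynamic"),
       attrs = obj$attrs)
}

#' Write a cine series as a 4D NIfTI volume
#'
#' @param series a `cine_series`.
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_cine_nifti <- function(series, path) {
  stopifnot(inherits(series, "cine_series"))
  img <- RNifti::asNifti(series$arr)
  RNifti::pixdim(img) <- c(series$voxel_mm, 1)[seq_along(dim(series$arr))]
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read segmentation label masks from NIfTI
#'
#' Label convention: 1 = blood pool (endocardium), 2 = myocardium; the
#' epicardial mask is the union of both labels.
#'
#' @param path NIfTI file of integer labels `[y, x, z(, phase)]`.
#' @param voxel_mm voxel dimensions; defaults to the file's pixdim.
#' @return a [segmentation_masks()].
#' @export
read_masks_nifti <- function(path, voxel_mm = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (is.null(voxel_mm)) voxel_mm <- unname(RNifti::pixdim(img)[1:3])
  has_myo <- any(arr == 2)
  segmentation_masks(endo = arr == 1,
                     epi = if (has_myo) arr >= 1 else NULL,
                     voxel_mm = voxel_mm)
}

#' Run the full simulate-calibrate-reconstruct-analyze pipeline
#'
#' Deterministic given `config$seed`. Writes (when `out_dir` is given) the
#' raw sample container, calibrated weights, the reconstructed NIfTI
#' series, JSON reports and a plain-text log; always returns the in-memory
#' results.
#'
#' @param config a `pipeline_config` (see [default_config()],
#'   [load_config()]).
#' @param out_dir output directory (`NULL`: nothing written).
#' @param verbose print stage progress.
#' @return list with `series` (GRAPPA reconstruction), `reference`
#'   (fully sampled reconstruction), `report` (recovered
#'   [functional_report()]), `truth` (analytic ground truth), `nrmse`
#'   (GRAPPA vs fully sampled, over the torso support), `protocol_report`,
#'   `fully_sampled` flag, `weights`, `sim`, and the objects needed to
#'   reuse the run (`traj`, `pattern`, `phantom`).
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         verbose = FALSE) {
  validate_config_keys(config, default_config())
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  say <- function(...) if (verbose) message(sprintf(...))
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- t1 - t0
    t0 <<- t1
  }
  pc <- config$protocol
  prot <- sequence_protocol(
    tr_ms = pc$tr_ms, te_ms = pc$te_ms, fov_mm = pc$fov_mm, matrix = pc$matrix,
    arms_total = pc$arms_total, arms_acquired = pc$arms_acquired,
    partitions_nominal = pc$partitions_nominal,
    partition_oversampling = pc$partition_oversampling,
    partition_thickness_mm = pc$partition_thickness_mm,
    readout_bandwidth_hz_per_px = pc$readout_bandwidth_hz_per_px,
    flip_deg = pc$flip_deg,
    calibration_repetitions = pc$calibration_repetitions)
  r <- acceleration_factor(prot$arms_total, prot$arms_acquired)
  nz <- encoded_partitions(prot$partitions_nominal, prot$partition_oversampling)

  say("designing trajectory (R = %d)", r)
  tc <- config$trajectory
  arm <- design_variable_density_spiral(
    fov_mm = prot$fov_mm, matrix = prot$matrix,
    center_matrix = tc$center_matrix, center_arms = tc$center_arms,
    arms_total = prot$arms_total, dwell_us = tc$dwell_us,
    max_readout_ms = tc$max_readout_ms)
  traj <- spiral_trajectory(arm, prot$arms_total)
  pattern <- undersampling_pattern(prot$arms_total, r)
  enc <- make_encoding(as.vector(traj$k), traj$matrix, traj$fov_mm)
  dcf <- density_compensation(traj)
  tick("trajectory")

  say("simulating acquisition")
  ph <- lv_phantom(grid_n = prot$matrix, grid_nz = nz, fov_mm = prot$fov_mm,
                   dz_mm = prot$partition_thickness_mm,
                   edv_ml = config$phantom$edv_ml,
                   ves_fraction = config$phantom$ves_fraction,
                   myo_volume_ml = config$phantom$myo_volume_ml,
                   n_phases = config$phantom$n_phases)
  sens <- make_coil_sensitivities(config$coils$n_channels, grid_n = prot$matrix,
                                  grid_nz = nz, fov_mm = prot$fov_mm,
                                  dz_mm = prot$partition_thickness_mm)
  noise_sd <- config$sim$noise_sd
  if (!is.na(config$sim$snr %||% NA) && is.numeric(config$sim$snr)) {
    noise_sd <- noise_sd_for_snr(dcf, prot$fov_mm / prot$matrix,
                                 snr = config$sim$snr)
  }
  sim <- acquisition_sim(noise_sd = noise_sd,
                         resp_amplitude_mm = config$sim$resp_amplitude_mm,
                         n_reps = prot$calibration_repetitions,
                         seed = config$seed)
  sd <- simulate_kspace(ph, sens, traj, pattern, sim, encoding = enc)
  tick("simulation")

  weights <- NULL
  if (r > 1L) {
    say("calibrating GRAPPA weights")
    spec <- kernel_spec(config$coils$n_channels,
                        source_readout = config$grappa$source_readout,
                        segment_readout = config$grappa$segment_readout)
    weights <- calibrate_grappa(sd$calibration, traj, pattern, spec,
                                ridge = config$grappa$ridge)
  }
  tick("calibration")

  say("reconstructing")
  voxel <- c(prot$fov_mm / prot$matrix, prot$fov_mm / prot$matrix,
             prot$partition_thickness_mm)
  series <- reconstruct_series(sd$dynamic, sd$calibration, traj, pattern,
                               partitions_nominal = prot$partitions_nominal,
                               weights = weights,
                               normalize = config$recon$normalize,
                               encoding = enc, dcf = dcf, voxel_mm = voxel,
                               tr_ms = prot$tr_ms)
  full_set <- kspace_set(sd$full, arms = seq_len(prot$arms_total) - 1L,
                         kind = "dynamic", traj = traj)
  reference <- reconstruct_series(full_set, NULL, traj,
                                  undersampling_pattern(prot$arms_total, 1),
                                  partitions_nominal = prot$partitions_nominal,
                                  normalize = config$recon$normalize,
                                  encoding = enc, dcf = dcf, voxel_mm = voxel,
                                  tr_ms = prot$tr_ms)
  tick("reconstruction")

  say("analyzing LV function")
  masks <- segment_blood_pool(series, threshold = config$analysis$threshold)
  report <- functional_report(masks,
                              density_g_per_ml = config$analysis$density_g_per_ml)
  support <- make_lv_phantom(ph, 0)$vol > 0
  support <- array(rep(support[, , seq(
    floor((nz - prot$partitions_nominal) / 2) + 1,
    length.out = prot$partitions_nominal)], ph$n_phases),
    dim(series$arr))
  err <- nrmse(series$arr, reference$arr, support)
  tick("analysis")

  out <- list(series = series, reference = reference, report = report,
              truth = sd$truth, nrmse = err,
              protocol_report = protocol_report(prot),
              fully_sampled = (r == 1L), weights = weights, sim = sd,
              traj = traj, pattern = pattern, phantom = ph, config = config,
              timings = timings)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_raw(file.path(out_dir, "raw.rds"), calibration = sd$calibration,
              dynamic = sd$dynamic,
              attrs = list(fov_mm = prot$fov_mm, matrix = prot$matrix,
                           dwell_us = traj$dwell_us))
    if (!is.null(weights)) saveRDS(weights, file.path(out_dir, "weights.rds"))
    write_cine_nifti(series, file.path(out_dir, "cine.nii.gz"))
    jsonlite::write_json(
      list(protocol = protocol_report(prot),
           fully_sampled = (r == 1L),
           function_recovered = as.list(report),
           function_truth = as.list(sd$truth),
           nrmse_vs_fully_sampled = err),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
    writeLines(c(
      sprintf("spiralcine pipeline, seed %d", config$seed),
      sprintf("R version: %s", R.version.string),
      sprintf("stage timings (s): %s",
              paste(names(timings), round(unlist(timings), 2),
                    sep = "=", collapse = ", "))),
      file.path(out_dir, "pipeline.log"))
  }
  invisible(out)
}
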