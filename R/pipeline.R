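# Configuration and the end-to-end pipeline binding the modules together.

#' Assemble a run configuration
#'
#' Builds (and validates) the configuration driving [run_pipeline()].
#' Every parameter of the chain is explicit and serializable, so a saved
#' configuration re-runs to bit-identical outputs.
#'
#' @param ... Named overrides of the defaults (see Details).
#' @details Fields: `geometry` (arguments of [scanner_geometry()]),
#'   `downsample` (detector coarsening for desk-scale runs), `n_views`,
#'   `spectrum` (arguments of [build_spectrum()]), `phantom` (preset name),
#'   `fov_raw_cm`/`fov_alt_cm` (the two axial fields of view),
#'   `photons_per_view` (for the raw scan; the companion scan is scaled to
#'   the same per-pixel fluence), `detector`, `target_slit_mm`,
#'   `smoothing` (`window`, `sigma`), `floor`, `recon` (`nx`, `ny`, `nz`,
#'   `voxel_mm`), `seed`.
#' @return A validated `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    geometry = list(), downsample = 4L, n_views = 48L,
    spectrum = list(kvp = 120, filtration_al_mm = 10, mode = "monoenergetic",
                    energy_keV = 60),
    phantom = "mc_10cm_five_tissue",
    fov_raw_cm = 4, fov_alt_cm = 13,
    photons_per_view = 2e5, detector = "ideal",
    target_slit_mm = 2.7,
    smoothing = list(window = 11L, sigma = 5),
    floor = 1,
    recon = list(nx = 128L, ny = 128L, nz = 16L, voxel_mm = 1),
    seed = 1L)
  cfg <- modifyList(cfg, list(...))
  # validate against module preconditions before any computation
  g <- do.call(scanner_geometry, cfg$geometry)
  g <- downsample_geometry(g, cfg$downsample, n_views = cfg$n_views)
  slit_for_fov(cfg$fov_raw_cm, g)
  slit_for_fov(cfg$fov_alt_cm, g)
  do.call(build_spectrum, cfg$spectrum)
  build_phantom(cfg$phantom)
  do.call(smoothing_config, cfg$smoothing)
  do.call(recon_grid, cfg$recon)
  if (cfg$photons_per_view < 1) stop("photons_per_view must be >= 1")
  if (cfg$target_slit_mm <= 0) stop("target_slit_mm must be positive")
  structure(cfg, class = "run_config")
}

#' Load a run configuration from a YAML file
#' @param path Path to a YAML file of [run_config()] overrides.
#' @return A `run_config`.
#' @export
load_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

.cfg_geometry <- function(cfg) {
  g <- do.call(scanner_geometry, cfg$geometry)
  downsample_geometry(g, cfg$downsample, n_views = cfg$n_views)
}

#' Run the scatter-correction pipeline
#'
#' Stage order: `simulate` (Monte Carlo scans at the two fields of view
#' plus analytic flat fields), `correct` (two-FOV log-fit scatter
#' correction of the raw scan), `reconstruct` (FDK of raw, alternate and
#' corrected stacks, HU-calibrated against a water-only analytic
#' calibration run), `evaluate` (CNR report and cupping indices). Later
#' stages require the artifacts of earlier ones (from this call or a
#' previous run's `out_dir`); a missing dependency is an error naming the
#' missing stage.
#'
#' @param config A [run_config()].
#' @param stages Subset of `c("simulate", "correct", "reconstruct",
#'   "evaluate")`.
#' @param out_dir Output directory for artifacts and JSON sidecars, or
#'   NULL to keep everything in memory.
#' @param artifacts Optional artifact list from a previous invocation.
#' @return A list of artifacts (`stacks`, `flats`, `correction`,
#'   `volumes`, `cnr`, `cupping`, `log`).
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "correct", "reconstruct",
                                    "evaluate"),
                         out_dir = NULL, artifacts = list()) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  cfg_hash <- rlang::hash(unclass(config))
  log <- list()
  note <- function(...) {
    msg <- sprintf(...)
    message(msg)
    log[[length(log) + 1]] <<- msg
  }
  g <- .cfg_geometry(config)
  sp <- do.call(build_spectrum, config$spectrum)
  phantom <- build_phantom(config$phantom)
  coll_raw <- slit_for_fov(config$fov_raw_cm, g)
  coll_alt <- slit_for_fov(config$fov_alt_cm, g)
  band_ratio <- (coll_alt$v_hi - coll_alt$v_lo) / (coll_raw$v_hi - coll_raw$v_lo)
  n_raw <- config$photons_per_view
  n_alt <- round(n_raw * band_ratio)  # matched per-pixel fluence
  det <- config$detector

  if ("simulate" %in% stages) {
    note("simulate: %s, %d views, %g + %g photons/view [config %s, seed %d]",
         phantom$name, g$n_views, n_raw, n_alt, cfg_hash, config$seed)
    artifacts$stacks <- list(
      raw = simulate_scan(phantom, g, coll_raw, sp, n_raw,
                          seed = config$seed, detector = det),
      alt = simulate_scan(phantom, g, coll_alt, sp, n_alt,
                          seed = config$seed + 1L, detector = det))
    artifacts$flats <- list(
      raw = expected_flat_field(g, coll_raw, sp, n_raw, det),
      alt = expected_flat_field(g, coll_alt, sp, n_alt, det))
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_stack(artifacts$stacks$raw, file.path(out_dir, "scan_raw"))
      write_stack(artifacts$stacks$alt, file.path(out_dir, "scan_alt"))
    }
  }
  if ("correct" %in% stages) {
    if (is.null(artifacts$stacks)) {
      stop("correct stage needs the 'simulate' stage outputs (two stacks)")
    }
    note("correct: slits %.3g/%.3g mm -> target %.3g mm",
         coll_raw$slit_equivalent_mm, coll_alt$slit_equivalent_mm,
         config$target_slit_mm)
    artifacts$correction <- correct_fov_scan(
      artifacts$stacks$raw, artifacts$stacks$alt,
      coll_raw$slit_equivalent_mm, coll_alt$slit_equivalent_mm,
      artifacts$flats$raw, artifacts$flats$alt,
      target_slit_mm = config$target_slit_mm,
      smoothing = do.call(smoothing_config, config$smoothing),
      floor = config$floor)
    nfb <- sum(artifacts$correction$model$fallback_mask)
    if (nfb > 0) note("correct: %d pixels used the flat-slope fallback", nfb)
    if (!is.null(out_dir)) {
      write_stack(artifacts$correction$corrected,
                  file.path(out_dir, "scan_corrected"))
    }
  }
  if ("reconstruct" %in% stages) {
    if (is.null(artifacts$stacks)) {
      stop("reconstruct stage needs the 'simulate' stage outputs")
    }
    grid <- do.call(recon_grid, config$recon)
    # water-only calibration reconstruction (analytic, noiseless)
    note("reconstruct: %d x %d x %d @ %.3g mm", grid$nx, grid$ny, grid$nz,
         grid$voxel_mm)
    water <- phantom_spec(phantom$body_diameter_cm, phantom$body_height_cm,
                          name = "water_calibration")
    wstack <- project_primary(water, g, coll_raw, sp, i0 = 1, detector = "ideal")
    wflat <- project_primary(build_phantom("air"), g, coll_raw, sp, i0 = 1,
                             detector = "ideal")$total[, , 1]
    wvol <- fdk_reconstruct(to_line_integrals(wstack, wflat), g, grid)
    mu_w <- measure_mu_water(wvol)
    recon_one <- function(stack, flat) {
      p <- to_line_integrals(stack, flat)
      hu_calibrate(fdk_reconstruct(p, g, grid), mu_w)
    }
    artifacts$volumes <- list(
      raw = recon_one(artifacts$stacks$raw, artifacts$flats$raw),
      alt = recon_one(artifacts$stacks$alt, artifacts$flats$alt),
      corrected = if (!is.null(artifacts$correction))
        recon_one(artifacts$correction$corrected, artifacts$flats$raw))
    artifacts$mu_water <- mu_w
    if (!is.null(out_dir)) {
      for (nm in names(artifacts$volumes)) {
        if (!is.null(artifacts$volumes[[nm]])) {
          write_volume(artifacts$volumes[[nm]],
                       file.path(out_dir, paste0("vol_", nm)))
        }
      }
    }
  }
  if ("evaluate" %in% stages) {
    if (is.null(artifacts$volumes)) {
      stop("evaluate stage needs the 'reconstruct' stage outputs (volumes)")
    }
    vols <- artifacts$volumes[!vapply(artifacts$volumes, is.null, logical(1))]
    artifacts$cnr <- dplyr::bind_rows(lapply(names(vols), function(nm) {
      r <- compute_cnr(vols[[nm]], phantom)
      r$acquisition <- nm
      r
    }))
    artifacts$cupping <- vapply(vols, cupping_index, numeric(1),
                                phantom = phantom)
    note("evaluate: mean CNR %s",
         paste(sprintf("%s=%.2f", unique(artifacts$cnr$acquisition),
                       tapply(artifacts$cnr$cnr, artifacts$cnr$acquisition,
                              mean)[unique(artifacts$cnr$acquisition)]),
               collapse = ", "))
    if (!is.null(out_dir)) {
      write.csv(artifacts$cnr, file.path(out_dir, "cnr_report.csv"),
                row.names = FALSE)
    }
  }
  artifacts$log <- c(artifacts$log, log)
  artifacts$config_hash <- cfg_hash
  if (!is.null(out_dir)) {
    jsonlite::write_json(
      list(config = unclass(config), config_hash = cfg_hash,
           log = unlist(artifacts$log)),
      file.path(out_dir, "run.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(artifacts)
}
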