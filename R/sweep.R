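# Collimator-slit sweep: the simulation campaign characterizing
# scatter-to-primary ratio versus axial collimation.

#' Enumerate the slit-sweep factorial
#'
#' The default factors (3 phantom diameters x 4 insert layouts x 7
#' collimation settings) enumerate 84 scan configurations.
#'
#' @param diameters_cm Body diameters in cm.
#' @param layouts Insert layouts (suffixes of the `mc_*` phantom presets).
#' @param slits_mm Collimator slit openings in mm; use `"open"` for no
#'   collimation.
#' @return A tibble with one row per (diameter, layout, slit)
#'   configuration, including the phantom preset name and the numeric
#'   abscissa `slit_x_mm` used for log fits (the uncollimated setting maps
#'   to the slit size that exactly covers the detector height).
#' @examples
#' nrow(sweep_grid())
#' @export
sweep_grid <- function(diameters_cm = c(10, 15, 20),
                       layouts = c("muscle", "dense_bone_800", "adipose",
                                   "five_tissue"),
                       slits_mm = list(0.5, 1, 2, 5, 10, 20, "open")) {
  if (!length(diameters_cm) || !length(layouts) || !length(slits_mm)) {
    stop("all factor lists must be non-empty")
  }
  g <- tidyr::expand_grid(diameter_cm = diameters_cm, layout = layouts,
                          slit = slits_mm)
  g$slit <- lapply(g$slit, identity)
  g$phantom <- sprintf("mc_%dcm_%s", g$diameter_cm, g$layout)
  g$slit_label <- vapply(g$slit, function(s) format(s), character(1))
  g
}

# central square ROI tallies. `flat_full` is the expected open-field value
# a *fully illuminated* pixel would see at this setting's emission density,
# so counts / flat_full is an exposure-normalized intensity matching a
# constant-output tube at fixed per-pixel fluence (the ROI signal drops when the
# collimated band no longer covers it).
.sweep_roi_tally <- function(view, flat_full, roi_px) {
  nr <- nrow(flat_full); nc <- ncol(flat_full)
  half <- roi_px %/% 2
  rows <- (nr %/% 2 - half + 1):(nr %/% 2 + half + 1)
  cols <- (nc %/% 2 - half + 1):(nc %/% 2 + half + 1)
  rows <- rows[rows >= 1 & rows <= nr]
  cols <- cols[cols >= 1 & cols <= nc]
  tot <- view$total[rows, cols]
  pri <- view$primary[rows, cols]
  sca <- view$scatter[rows, cols]
  fl <- flat_full[rows, cols]
  s_pri <- sum(pri); s_sca <- sum(sca)
  spr <- if (s_pri > 0) s_sca / s_pri else NA_real_
  tibble::tibble(
    n_roi_px = length(tot),
    mean_total = mean(tot), sd_total = sd(as.vector(tot)),
    mean_primary = mean(pri), sd_primary = sd(as.vector(pri)),
    mean_scatter = mean(sca), sd_scatter = sd(as.vector(sca)),
    mean_total_norm = mean(tot / fl),
    mean_primary_norm = mean(pri / fl),
    mean_scatter_norm = mean(sca / fl),
    spr = spr,
    se_spr = if (s_sca > 0 && s_pri > 0) spr * sqrt(1 / s_sca + 1 / s_pri)
             else if (s_pri > 0) 1 / s_pri else NA_real_)
}

#' Run the collimator-slit Monte Carlo sweep
#'
#' Simulates one projection per configuration of the factorial and
#' tallies a central region of interest on the total, primary and scatter
#' channels, reporting raw and flat-field-normalized intensities and the
#' scatter-to-primary ratio (SPR).
#'
#' @inheritParams sweep_grid
#' @param n_photons Photon histories per configuration.
#' @param master_seed Master seed; each configuration gets a derived
#'   stream.
#' @param geometry Scanner geometry; the default is the nominal geometry
#'   with the detector downsampled 4x (desk scale).
#' @param spectrum Energy spectrum (default: monoenergetic 60 keV for
#'   speed; pass a polychromatic spectrum for realism).
#' @param roi_px Side of the central square ROI in pixels.
#' @param angle_deg Gantry angle of the simulated view.
#' @param detector Detector model, see [simulate_view()].
#' @return A tibble of class `cbct_sweep`: one row per configuration with
#'   ROI tallies and SPR (plus its Monte Carlo standard error).
#' @export
run_slit_sweep <- function(diameters_cm = c(10, 15, 20),
                           layouts = c("muscle", "dense_bone_800", "adipose",
                                       "five_tissue"),
                           slits_mm = list(0.5, 1, 2, 5, 10, 20, "open"),
                           n_photons = 2e5, master_seed = 1L,
                           geometry = NULL, spectrum = NULL, roi_px = 11L,
                           angle_deg = 0,
                           detector = c("scintillator", "ideal")) {
  detector <- match.arg(detector)
  if (is.null(geometry)) geometry <- downsample_geometry(build_default_geometry(), 4L)
  if (is.null(spectrum)) spectrum <- build_spectrum(120, 10, "monoenergetic", 60)
  grid <- sweep_grid(diameters_cm, layouts, slits_mm)
  open_coll <- collimator_setting("open", geometry)
  ff_open <- expected_flat_field(geometry, open_coll, spectrum, n_photons,
                                 detector)
  band_open <- open_coll$v_hi - open_coll$v_lo
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    coll <- collimator_setting(grid$slit[[i]], geometry)
    seed_i <- (as.integer(master_seed) * 1009L + i) %% .Machine$integer.max
    v <- simulate_view(grid$phantom[i], geometry, coll, spectrum, n_photons,
                       seed = seed_i, angle_deg = angle_deg,
                       detector = detector)
    flat_full <- ff_open * (band_open / (coll$v_hi - coll$v_lo))
    tal <- .sweep_roi_tally(v, flat_full, roi_px)
    tal$slit_x_mm <- coll$slit_equivalent_mm
    out[[i]] <- tal
  }
  res <- dplyr::bind_cols(
    grid[, c("diameter_cm", "layout", "phantom", "slit_label")],
    dplyr::bind_rows(out))
  res$n_photons <- n_photons
  class(res) <- c("cbct_sweep", class(res))
  res
}
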