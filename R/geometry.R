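#' Scanner geometry for a circular cone-beam orbit
#'
#' Distances are in cm, detector pitch in mm. The coordinate system is
#' right-handed with the origin at the isocenter and z along the rotation
#' axis; detector row 0 sits at the -z edge, pixel indices are 0-based and
#' index intervals half-open.
#'
#' @param sad Source-axis distance (cm).
#' @param sdd Source-detector distance (cm); must exceed `sad`.
#' @param det_rows,det_cols Detector grid size (rows run axially).
#' @param det_pitch_mm Detector pixel pitch in mm.
#' @param n_views Number of projections over the orbit.
#' @param angles_deg Optional explicit gantry angles in degrees (strictly
#'   increasing, spanning less than 360 degrees); default is `n_views`
#'   uniform steps over 360 degrees.
#' @param collimator_distance Source-to-collimator distance (cm). The
#'   default is calibrated so that a 4-cm axial field of view corresponds
#'   to a 14-mm slit.
#' @return An object of class `scanner_geometry`.
#' @examples
#' g <- scanner_geometry()
#' magnification(g)
#' @export
scanner_geometry <- function(sad = 49.54, sdd = 71.4, det_rows = 384,
                             det_cols = 480, det_pitch_mm = 0.5,
                             n_views = 301, angles_deg = NULL,
                             collimator_distance = NULL) {
  if (sad <= 0 || sdd <= 0) stop("distances must be positive")
  if (sad >= sdd) stop("sad must be smaller than sdd")
  if (det_rows < 1 || det_cols < 1 || n_views < 1) {
    stop("det_rows, det_cols and n_views must be >= 1")
  }
  if (det_pitch_mm <= 0) stop("det_pitch_mm must be positive")
  if (is.null(angles_deg)) {
    angles_deg <- (seq_len(n_views) - 1) * 360 / n_views
  }
  if (length(angles_deg) != n_views) stop("length(angles_deg) != n_views")
  if (any(diff(angles_deg) <= 0)) stop("angles must be strictly increasing")
  if (max(angles_deg) - min(angles_deg) >= 360 + 1e-9) {
    stop("angles must span less than 360 degrees")
  }
  if (is.null(collimator_distance)) {
    # anchored so slit_for_fov(4 cm) yields a 14 mm slit
    collimator_distance <- 1.4 * sad / 4
  }
  if (collimator_distance <= 0 || collimator_distance >= sad) {
    stop("collimator_distance must lie strictly between source and isocenter")
  }
  g <- list(sad = sad, sdd = sdd, det_rows = as.integer(det_rows),
            det_cols = as.integer(det_cols), det_pitch_mm = det_pitch_mm,
            n_views = as.integer(n_views), angles_deg = angles_deg,
            collimator_distance = collimator_distance)
  class(g) <- "scanner_geometry"
  g
}

#' Default dental-CBCT geometry
#'
#' Nominal scanner geometry: SAD 49.54 cm, SDD 71.4 cm, a 384 x 480
#' detector at 0.5 mm pitch and 301 projections over 360 degrees.
#'
#' @return A `scanner_geometry`.
#' @export
build_default_geometry <- function() scanner_geometry()

#' Geometric magnification sdd / sad
#' @param geometry A `scanner_geometry`.
#' @return The magnification factor.
#' @export
magnification <- function(geometry) geometry$sdd / geometry$sad

#' Coarsen the detector grid of a geometry
#'
#' Desk-scale runs use a downsampled detector: the pixel pitch is
#' multiplied and the grid divided by `factor`.
#'
#' @param geometry A `scanner_geometry`.
#' @param factor Integer downsampling factor.
#' @param n_views Optionally also reset the number of views.
#' @return A `scanner_geometry`.
#' @export
downsample_geometry <- function(geometry, factor = 4L, n_views = NULL) {
  scanner_geometry(
    sad = geometry$sad, sdd = geometry$sdd,
    det_rows = geometry$det_rows %/% factor,
    det_cols = geometry$det_cols %/% factor,
    det_pitch_mm = geometry$det_pitch_mm * factor,
    n_views = if (is.null(n_views)) geometry$n_views else n_views,
    collimator_distance = geometry$collimator_distance)
}

detector_height_cm <- function(geometry) {
  geometry$det_rows * geometry$det_pitch_mm / 10
}

#' Axial collimation setting
#'
#' Converts a slit opening at the collimator plane into the illuminated
#' axial band on the detector and the beam height at the isocenter, by
#' similar triangles through the (point) source.
#'
#' @param slit_mm Slit opening in mm, or `"open"` for no collimation.
#' @param geometry A `scanner_geometry`.
#' @return An object of class `collimator_setting` with fields `slit_mm`,
#'   `beam_height_at_iso` (cm), `v_lo`/`v_hi` (axial band limits on the
#'   detector, cm) and `illuminated_rows` (half-open 0-based row interval).
#' @examples
#' collimator_setting(14, scanner_geometry())
#' @export
collimator_setting <- function(slit_mm, geometry) {
  open_mode <- identical(slit_mm, "open")
  if (!open_mode && (!is.numeric(slit_mm) || slit_mm <= 0)) {
    stop("slit_mm must be a positive number or \"open\"")
  }
  h_det <- detector_height_cm(geometry)
  if (open_mode) {
    band <- h_det
    slit_equiv <- band * geometry$collimator_distance / geometry$sdd * 10
  } else {
    band <- slit_mm / 10 * geometry$sdd / geometry$collimator_distance
    slit_equiv <- slit_mm
  }
  band <- min(band, h_det)
  v_lo <- -band / 2
  v_hi <- band / 2
  pitch <- geometry$det_pitch_mm / 10
  r0 <- max(0L, as.integer(floor(v_lo / pitch + geometry$det_rows / 2)))
  r1 <- min(geometry$det_rows, as.integer(ceiling(v_hi / pitch + geometry$det_rows / 2)))
  s <- list(slit_mm = if (open_mode) "open" else slit_mm,
            slit_equivalent_mm = slit_equiv,
            beam_height_at_iso = band * geometry$sad / geometry$sdd,
            v_lo = v_lo, v_hi = v_hi,
            illuminated_rows = c(r0, r1))
  class(s) <- "collimator_setting"
  s
}

#' Slit opening that covers a requested axial field of view
#'
#' @param axial_fov_cm Desired axial field of view at the isocenter (cm).
#' @param geometry A `scanner_geometry`.
#' @return A `collimator_setting`.
#' @examples
#' slit_for_fov(4, scanner_geometry())$slit_mm
#' @export
slit_for_fov <- function(axial_fov_cm, geometry) {
  max_fov <- detector_height_cm(geometry) / magnification(geometry)
  if (axial_fov_cm <= 0) stop("axial_fov_cm must be positive")
  if (axial_fov_cm > max_fov + 1e-9) {
    stop(sprintf("FOV %.3g cm exceeds the detector axial coverage (%.3g cm)",
                 axial_fov_cm, max_fov))
  }
  slit_mm <- axial_fov_cm * 10 * geometry$collimator_distance / geometry$sad
  collimator_setting(slit_mm, geometry)
}

#' Axial field of view at the isocenter for a collimator setting
#' @param collimation A `collimator_setting`.
#' @return FOV in cm.
#' @export
fov_for_slit <- function(collimation) collimation$beam_height_at_iso

#' @export
print.scanner_geometry <- function(x, ...) {
  cat(sprintf(
    "<scanner_geometry> SAD %.4g cm, SDD %.4g cm, detector %d x %d @ %.3g mm, %d views\n",
    x$sad, x$sdd, x$det_rows, x$det_cols, x$det_pitch_mm, x$n_views))
  invisible(x)
}

#' @export
print.collimator_setting <- function(x, ...) {
  cat(sprintf(
    "<collimator_setting> slit %s mm, beam height at iso %.3g cm, rows [%d, %d)\n",
    format(x$slit_mm), x$beam_height_at_iso, x$illuminated_rows[1],
    x$illuminated_rows[2]))
  invisible(x)
}
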