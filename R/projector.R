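# Analytic forward model: exact Beer-Lambert line integrals through the
# cylinder phantom plus an optional parametric low-frequency scatter field.
# Serves as fixture generator and as the primary-channel oracle for the
# Monte Carlo engine.

#' Per-material intersection lengths of a source-to-pixel ray
#'
#' Exact chord lengths of the segment through the nested cylinders of a
#' phantom; nested structures (e.g. a bone core inside its sheath) are
#' resolved innermost-wins.
#'
#' @param phantom A `phantom_spec` or preset name.
#' @param src,dst Segment end points, numeric xyz in cm.
#' @return A tibble with one row per material and its path length in cm
#'   (materials the ray misses report zero).
#' @export
ray_path_lengths <- function(phantom, src, dst) {
  phantom <- build_phantom(phantom)
  pc <- phantom_cylinders(phantom)
  res <- cpp_ray_lengths(pc$cyl, as.numeric(src), as.numeric(dst))
  mat <- pc$materials[pc$cyl[, 6] + 1]
  tibble::tibble(material = mat, length_cm = as.numeric(res$net)) |>
    dplyr::group_by(.data$material) |>
    dplyr::summarise(length_cm = sum(.data$length_cm), .groups = "drop")
}

#' Analytic primary projection of a phantom
#'
#' Noiseless Beer-Lambert transmission per detector pixel,
#' \eqn{I = I_0 \sum_E w(E)\,\epsilon(E) \exp(-\sum_m \mu_m(E) L_m)},
#' zero outside the illuminated band (pixels partially covered by the band
#' are scaled by their coverage fraction).
#'
#' @inheritParams simulate_view
#' @param i0 Open-field value of a fully illuminated pixel.
#' @param views Optional subset of 0-based view indices.
#' @return A `projection_stack` whose total equals the primary channel
#'   (scatter identically zero).
#' @export
project_primary <- function(phantom, geometry, collimation, spectrum,
                            i0 = 1, detector = c("ideal", "scintillator"),
                            views = NULL) {
  detector <- match.arg(detector)
  phantom <- build_phantom(phantom)
  pc <- phantom_cylinders(phantom)
  mu <- .mu_matrices(pc$materials)
  csi <- mu_table("detector_scintillator")
  if (is.null(views)) views <- seq_len(geometry$n_views) - 1L
  angles <- geometry$angles_deg[views + 1] * pi / 180
  arr <- cpp_project_primary(
    geometry$sad, geometry$sdd, geometry$det_rows, geometry$det_cols,
    geometry$det_pitch_mm / 10, angles, collimation$v_lo, collimation$v_hi,
    pc$cyl, mu$tot, mu$e0, mu$de, spectrum$energies, spectrum$weights,
    if (detector == "ideal") 0L else 1L, csi$total, .CSI_THICKNESS_CM, i0)
  dims <- c(geometry$det_rows, geometry$det_cols, length(views))
  pri <- array(arr, dims)
  g <- geometry
  if (length(views) != geometry$n_views) {
    g <- scanner_geometry(geometry$sad, geometry$sdd, geometry$det_rows,
                          geometry$det_cols, geometry$det_pitch_mm,
                          n_views = length(views),
                          angles_deg = geometry$angles_deg[views + 1],
                          collimator_distance = geometry$collimator_distance)
  }
  projection_stack(total = pri, primary = pri, scatter = array(0, dims),
                   geometry = g, collimation = collimation,
                   meta = list(phantom = phantom$name, i0 = i0,
                               detector = detector, engine = "analytic"))
}

#' Parametric low-frequency scatter field
#'
#' A stand-in scatter model with the low-frequency character real scatter
#' exhibits: a smooth spatial profile multiplied by a slit response
#' `g(slit)`. The default response `g(s) = log(1 + s / s0)` mirrors the
#' empirically observed natural-log growth of total signal with slit
#' size; a saturating-exponential alternative is provided to probe the
#' estimator outside its favorable regime.
#'
#' @param amplitude Scatter amplitude as a fraction of the open-field
#'   intensity (at `g = 1`).
#' @param s0_mm Scale of the slit response in mm.
#' @param response `"log"` for `g(s) = log(1 + s/s0)` or `"satexp"` for
#'   `g(s) = 1 - exp(-s/s0)`.
#' @param profile_sigma_frac Width of the Gaussian spatial profile as a
#'   fraction of the detector width.
#' @return An object of class `analytic_scatter_field`.
#' @export
analytic_scatter_field <- function(amplitude = 0.25, s0_mm = 1,
                                   response = c("log", "satexp"),
                                   profile_sigma_frac = 0.5) {
  response <- match.arg(response)
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (s0_mm <= 0) stop("s0_mm must be positive")
  f <- list(amplitude = amplitude, s0_mm = s0_mm, response = response,
            profile_sigma_frac = profile_sigma_frac)
  class(f) <- "analytic_scatter_field"
  f
}

#' Slit response of an analytic scatter field
#' @param field An `analytic_scatter_field`.
#' @param slit_mm Slit opening in mm (vectorized); `g(0) = 0` and `g` is
#'   monotone increasing.
#' @return Numeric response values.
#' @export
scatter_slit_response <- function(field, slit_mm) {
  switch(field$response,
         log = log(1 + slit_mm / field$s0_mm),
         satexp = 1 - exp(-slit_mm / field$s0_mm))
}

# smooth spatial profile on the detector grid, in [0, 1]
.scatter_profile <- function(field, det_rows, det_cols, pitch_cm) {
  sig <- field$profile_sigma_frac * det_cols * pitch_cm
  u <- (seq_len(det_cols) - 0.5 - det_cols / 2) * pitch_cm
  v <- (seq_len(det_rows) - 0.5 - det_rows / 2) * pitch_cm
  outer(exp(-v^2 / (2 * sig^2)), exp(-u^2 / (2 * sig^2)))
}

#' Add a parametric scatter field (and optional Poisson noise) to a stack
#'
#' Scatter for each view is `amplitude * i0 * g(slit) * profile`, added on
#' the illuminated band only; channel conservation
#' (total = primary + scatter) holds exactly before noise and in
#' expectation under Poisson noise.
#'
#' @param stack A primary-only `projection_stack` from
#'   [project_primary()].
#' @param field An `analytic_scatter_field`.
#' @param slit_mm Numeric slit opening in mm driving the response.
#' @param poisson If TRUE, draw each channel from a Poisson law with the
#'   analytic mean.
#' @param seed Seed used when `poisson = TRUE`.
#' @return A `projection_stack` with total/primary/scatter channels.
#' @export
add_scatter_and_noise <- function(stack, field, slit_mm, poisson = FALSE,
                                  seed = 1L) {
  g <- stack$geometry
  i0 <- stack$meta$i0
  if (is.null(i0)) stop("stack carries no open-field intensity metadata")
  prof <- .scatter_profile(field, g$det_rows, g$det_cols, g$det_pitch_mm / 10)
  resp <- scatter_slit_response(field, slit_mm)
  # per-row coverage fraction of the illuminated band (edge rows receive
  # proportionally less scatter, as they do primary fluence)
  pitch <- g$det_pitch_mm / 10
  vc <- (seq_len(g$det_rows) - 0.5 - g$det_rows / 2) * pitch
  frac <- pmax(0, pmin(1, (pmin(vc + pitch / 2, stack$collimation$v_hi) -
                             pmax(vc - pitch / 2, stack$collimation$v_lo)) /
                         pitch))
  pri <- stack$primary
  nv <- n_views(stack)
  sca <- array(0, dim(pri))
  s_img <- field$amplitude * i0 * resp * prof * frac
  for (k in seq_len(nv)) sca[, , k] <- s_img
  if (poisson) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as.integer(seed))
    pri <- array(rpois(length(pri), pri), dim(pri))
    sca <- array(rpois(length(sca), sca), dim(sca))
  }
  projection_stack(primary = pri, scatter = sca, geometry = g,
                   collimation = stack$collimation,
                   meta = c(stack$meta, list(scatter_field = field,
                                             slit_mm = slit_mm,
                                             poisson = poisson)))
}

# save/restore the global RNG state so fixtures do not perturb user code
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
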