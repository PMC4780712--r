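# Monte Carlo engine wrappers

.CSI_THICKNESS_CM <- 0.06

# assemble the compiled-engine inputs shared by views of one acquisition
.mc_setup <- function(phantom, detector = c("scintillator", "ideal")) {
  detector <- match.arg(detector)
  pc <- phantom_cylinders(phantom)
  mu <- .mu_matrices(pc$materials)
  csi <- mu_table("detector_scintillator")
  list(cyl = pc$cyl, materials = pc$materials, mu = mu,
       det_mode = if (detector == "ideal") 0L else 1L,
       csi_pe = csi$photoelectric, csi_co = csi$compton,
       csi_ra = csi$rayleigh, csi_t = .CSI_THICKNESS_CM)
}

.records_tibble <- function(res, view_index) {
  n <- res$n_records
  m <- res$records
  tibble::tibble(
    view_index = rep(view_index, n),
    row = as.integer(m[seq_len(n), 1]),
    col = as.integer(m[seq_len(n), 2]),
    energy_keV = m[seq_len(n), 3],
    n_compton_phantom = as.integer(m[seq_len(n), 4]),
    n_rayleigh_phantom = as.integer(m[seq_len(n), 5]),
    n_compton_detector = as.integer(m[seq_len(n), 6]),
    n_rayleigh_detector = as.integer(m[seq_len(n), 7]))
}

#' Monte Carlo simulation of a single projection view
#'
#' Transports photons from the source through the collimated cone and the
#' phantom (Woodcock tracking; Compton scattering sampled from the
#' free-electron Klein-Nishina cross-section, Rayleigh scattering with a
#' Thomson angular law, photoelectric absorption terminating the history)
#' into the detector. Every interaction inside the phantom or detector is
#' counted per photon; a detected photon is classified as primary iff it
#' underwent no Compton or Rayleigh interaction in the phantom (optionally
#' also none in the detector).
#'
#' @param phantom A `phantom_spec` or preset name.
#' @param geometry A `scanner_geometry`.
#' @param collimation A `collimator_setting`.
#' @param spectrum An `energy_spectrum`.
#' @param n_photons Photon histories to launch.
#' @param seed Master seed (integer); together with `view_index` it selects
#'   a deterministic per-view random stream.
#' @param view_index 0-based view index used for the seed stream and, when
#'   `angle_deg` is NULL, to pick the gantry angle from the geometry.
#' @param angle_deg Optional explicit gantry angle in degrees.
#' @param detector `"scintillator"` (absorbing CsI slab with
#'   energy-dependent efficiency) or `"ideal"` (every arriving photon
#'   counted).
#' @param classify `"phantom"` (default) or `"phantom_or_detector"`:
#'   which interaction counters make a photon scattered.
#' @param energy_weighted If TRUE tally deposited signal as energy rather
#'   than photon counts.
#' @param record_photons If TRUE also return per-photon records
#'   (list-mode) up to `record_cap` rows.
#' @param record_cap Maximum number of photon records kept.
#' @return A list with `total`, `primary`, `scatter` matrices (rows x
#'   cols), `n_detected`, `n_runaway`, and `records` (tibble or NULL).
#' @export
simulate_view <- function(phantom, geometry, collimation, spectrum,
                          n_photons, seed = 1L, view_index = 0L,
                          angle_deg = NULL,
                          detector = c("scintillator", "ideal"),
                          classify = c("phantom", "phantom_or_detector"),
                          energy_weighted = FALSE, record_photons = FALSE,
                          record_cap = 100000L) {
  stopifnot(n_photons >= 1)
  phantom <- build_phantom(phantom)
  classify <- match.arg(classify)
  setup <- .mc_setup(phantom, match.arg(detector))
  if (is.null(angle_deg)) angle_deg <- geometry$angles_deg[view_index + 1]
  res <- cpp_simulate_view(
    geometry$sad, geometry$sdd, geometry$det_rows, geometry$det_cols,
    geometry$det_pitch_mm / 10, angle_deg * pi / 180,
    collimation$v_lo, collimation$v_hi, setup$cyl,
    setup$mu$pe, setup$mu$co, setup$mu$ra, setup$mu$e0, setup$mu$de,
    spectrum$energies, spectrum$weights, setup$det_mode, setup$csi_pe,
    setup$csi_co, setup$csi_ra, setup$csi_t, n_photons, as.integer(seed),
    as.integer(view_index), energy_weighted,
    if (classify == "phantom") 0L else 1L,
    if (record_photons) as.integer(record_cap) else 0L)
  if (res$n_runaway > 0) {
    warning(res$n_runaway, " photon histories hit the interaction cap")
  }
  list(total = res$total, primary = res$primary, scatter = res$scatter,
       n_detected = res$n_detected, n_runaway = res$n_runaway,
       records = if (record_photons) .records_tibble(res, view_index) else NULL)
}

#' Monte Carlo simulation of a full CBCT scan
#'
#' Runs [simulate_view()] for every gantry angle of the geometry; per-view
#' random streams are derived deterministically from the master seed and
#' the view index, so a fixed seed reproduces the stack bit-for-bit.
#'
#' @inheritParams simulate_view
#' @param n_photons Photon histories per view.
#' @param views Optional subset of 0-based view indices (default: all).
#' @return A `projection_stack` with total/primary/scatter channels.
#' @export
simulate_scan <- function(phantom, geometry, collimation, spectrum,
                          n_photons, seed = 1L,
                          detector = c("scintillator", "ideal"),
                          classify = c("phantom", "phantom_or_detector"),
                          energy_weighted = FALSE, views = NULL) {
  phantom <- build_phantom(phantom)
  detector <- match.arg(detector)
  classify <- match.arg(classify)
  if (is.null(views)) views <- seq_len(geometry$n_views) - 1L
  nr <- geometry$det_rows; nc <- geometry$det_cols; nv <- length(views)
  tot <- pri <- sca <- array(0, c(nr, nc, nv))
  for (k in seq_len(nv)) {
    v <- simulate_view(phantom, geometry, collimation, spectrum, n_photons,
                       seed = seed, view_index = views[k], detector = detector,
                       classify = classify, energy_weighted = energy_weighted)
    tot[, , k] <- v$total; pri[, , k] <- v$primary; sca[, , k] <- v$scatter
  }
  g <- geometry
  if (nv != geometry$n_views) {
    g <- scanner_geometry(geometry$sad, geometry$sdd, geometry$det_rows,
                          geometry$det_cols, geometry$det_pitch_mm,
                          n_views = nv,
                          angles_deg = geometry$angles_deg[views + 1],
                          collimator_distance = geometry$collimator_distance)
  }
  projection_stack(total = tot, primary = pri, scatter = sca, geometry = g,
                   collimation = collimation,
                   meta = list(phantom = phantom$name, n_photons = n_photons,
                               seed = seed, detector = detector,
                               classify = classify, engine = "mc"))
}

#' Expected open-field (flat-field) image of one view
#'
#' The noiseless expectation of the detector image with no object in the
#' beam, for the same emission model as the Monte Carlo engine (photons
#' aimed uniformly at the illuminated band). Used for flat-field
#' normalization.
#'
#' @inheritParams simulate_view
#' @param n_photons Photon budget whose expectation is computed.
#' @return A rows x cols matrix of expected counts.
#' @export
expected_flat_field <- function(geometry, collimation, spectrum, n_photons,
                                detector = c("scintillator", "ideal")) {
  detector <- match.arg(detector)
  csi <- mu_table("detector_scintillator")
  band <- collimation$v_hi - collimation$v_lo
  pitch <- geometry$det_pitch_mm / 10
  i0 <- n_photons * pitch^2 / (band * geometry$det_cols * pitch)
  e <- mu_energy_grid()
  arr <- cpp_project_primary(
    geometry$sad, geometry$sdd, geometry$det_rows, geometry$det_cols, pitch,
    0, collimation$v_lo, collimation$v_hi,
    matrix(numeric(0), 0, 8), matrix(0, length(e), 0), e[1], e[2] - e[1],
    spectrum$energies, spectrum$weights,
    if (detector == "ideal") 0L else 1L, csi$total, .CSI_THICKNESS_CM, i0)
  array(arr, c(geometry$det_rows, geometry$det_cols))
}

#' Sample Compton-scattered photon energies
#'
#' Draws scattered-photon energies for a fixed incident energy from the
#' same free-electron Klein-Nishina sampler used by the transport engine.
#' Exposed for physics diagnostics.
#'
#' @param energy_keV Incident photon energy.
#' @param n Number of samples.
#' @param seed Seed.
#' @return Numeric vector of scattered energies in keV.
#' @export
sample_compton_energies <- function(energy_keV, n, seed = 1L) {
  cpp_sample_compton(energy_keV, as.integer(n), as.integer(seed))
}
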