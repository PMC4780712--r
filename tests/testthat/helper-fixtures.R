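# shared desk-scale fixtures, built in code

desk_geometry <- function(n_views = 1L, factor = 4L) {
  downsample_geometry(build_default_geometry(), factor, n_views = n_views)
}

mono60 <- function() build_spectrum(120, 10, "monoenergetic", 60)

# expected open-field photons per fully illuminated pixel for a budget
photons_per_pixel <- function(geometry, collimation, n_photons) {
  pitch <- geometry$det_pitch_mm / 10
  n_photons * pitch^2 /
    ((collimation$v_hi - collimation$v_lo) * geometry$det_cols * pitch)
}

# photon budget giving `ppp` expected photons per illuminated pixel
budget_for <- function(geometry, collimation, ppp) {
  pitch <- geometry$det_pitch_mm / 10
  round(ppp * (collimation$v_hi - collimation$v_lo) *
          geometry$det_cols * pitch / pitch^2)
}

# single-view projection stack from a simulate_view() result
as_stack <- function(v, geometry, collimation, meta = list()) {
  projection_stack(
    total = array(v$total, c(dim(v$total), 1)),
    primary = array(v$primary, c(dim(v$primary), 1)),
    scatter = array(v$scatter, c(dim(v$scatter), 1)),
    geometry = scanner_geometry(
      geometry$sad, geometry$sdd, geometry$det_rows, geometry$det_cols,
      geometry$det_pitch_mm, n_views = 1,
      collimator_distance = geometry$collimator_distance),
    collimation = collimation, meta = meta)
}
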