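#' Build an x-ray tube energy spectrum
#'
#' Polychromatic spectra use a Kramers-type bremsstrahlung fluence model
#' \eqn{\phi(E) \propto (kVp - E)/E}, hardened by the stated
#' aluminium-equivalent filtration, plus tungsten K characteristic lines
#' (59.3 and 67.2 keV) when the tube voltage exceeds the K edge.
#' The monoenergetic mode returns a single bin and is intended for fast,
#' analytically checkable runs.
#'
#' @param kvp Peak tube voltage in kV (40-150).
#' @param filtration_al_mm Aluminium-equivalent filtration in mm (>= 0).
#' @param mode `"polychromatic"` or `"monoenergetic"`.
#' @param energy_keV Energy of the single bin in monoenergetic mode.
#' @param bin_keV Width of the energy bins in polychromatic mode.
#' @return An object of class `energy_spectrum`: a list with `energies`
#'   (keV bin centers, strictly increasing), `weights` (relative fluence,
#'   summing to one), `kvp` and `filtration_al_mm`.
#' @examples
#' sp <- build_spectrum(120, 10)
#' sum(sp$weights)
#' @export
build_spectrum <- function(kvp = 120, filtration_al_mm = 10,
                           mode = c("polychromatic", "monoenergetic"),
                           energy_keV = 60, bin_keV = 2) {
  mode <- match.arg(mode)
  if (kvp < 40 || kvp > 150) stop("kvp must be within [40, 150] kV")
  if (filtration_al_mm < 0) stop("filtration_al_mm must be >= 0")
  if (mode == "monoenergetic") {
    if (energy_keV > kvp) stop("monoenergetic energy cannot exceed kvp")
    if (energy_keV < 10) stop("energy below the tabulated range")
    sp <- list(energies = energy_keV, weights = 1, kvp = kvp,
               filtration_al_mm = filtration_al_mm)
    class(sp) <- "energy_spectrum"
    return(sp)
  }
  e <- seq(12, kvp, by = bin_keV)
  w <- (kvp - e) / e
  w[w < 0] <- 0
  mu_al <- material_mu("aluminum", pmin(e, 150))$total
  w <- w * exp(-mu_al * filtration_al_mm / 10)
  # tungsten K lines: a modest fixed fraction of the filtered continuum
  if (kvp > 69.5) {
    for (ln in list(c(59.3, 0.06), c(67.2, 0.03))) {
      i <- which.min(abs(e - ln[1]))
      w[i] <- w[i] + ln[2] * sum(w)
    }
  }
  keep <- w > 0
  sp <- list(energies = e[keep], weights = w[keep] / sum(w[keep]), kvp = kvp,
             filtration_al_mm = filtration_al_mm)
  class(sp) <- "energy_spectrum"
  sp
}

#' Mean (fluence-weighted) energy of a spectrum in keV
#' @param spectrum An `energy_spectrum`.
#' @return Mean energy in keV.
#' @export
spectrum_mean_energy <- function(spectrum) {
  sum(spectrum$energies * spectrum$weights)
}

#' @export
print.energy_spectrum <- function(x, ...) {
  cat(sprintf(
    "<energy_spectrum> %g kVp, %g mm Al; %d bins, mean %.1f keV\n",
    x$kvp, x$filtration_al_mm, length(x$energies), spectrum_mean_energy(x)))
  invisible(x)
}
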