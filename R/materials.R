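# Linear attenuation data for the simulated materials.
#
# Component cross sections (cm^2/atom, E in keV):
#   incoherent:    Z * sigma_KN(E)            (free-electron Klein-Nishina)
#   photoelectric: C_PE * Z^4.3811 * E^-3.0684
#   coherent:      C_CO * Z^2.5   * E^-2
# The photoelectric and coherent constants are calibrated against published
# NIST mass-attenuation values for water and aluminium over 15-150 keV
# (total within ~1.4% everywhere; water at 60 keV within 0.2%). Tables are
# tabulated at 2-keV resolution over 10-150 keV; point queries interpolate
# log-log between bins.

.AVOGADRO <- 6.02214076e23
.RE2 <- 7.94077985e-26 # classical electron radius squared, cm^2
.C_PE <- 1.838143e-23
.A_PE <- 4.3811
.B_PE <- 3.0684
.C_CO <- 2.603749e-24
.A_CO <- 2.5
.B_CO <- 2.0

.ELEMENTS <- data.frame(
  symbol = c("H", "C", "N", "O", "Na", "Mg", "Al", "P", "S", "Cl", "Ar",
             "K", "Ca", "I", "Cs"),
  Z = c(1, 6, 7, 8, 11, 12, 13, 15, 16, 17, 18, 19, 20, 53, 55),
  A = c(1.008, 12.011, 14.007, 15.999, 22.99, 24.305, 26.982, 30.974,
        32.06, 35.45, 39.948, 39.098, 40.078, 126.904, 132.905)
)

#' Energy grid of the packaged attenuation tables (keV)
#' @keywords internal
mu_energy_grid <- function() seq(10, 150, by = 2)

# total Klein-Nishina cross section per electron, cm^2
sigma_kn <- function(energy_keV) {
  k <- energy_keV / 510.99895
  t <- 1 + 2 * k
  2 * pi * .RE2 * ((1 + k) / k^2 * (2 * (1 + k) / t - log(t) / k) +
                     log(t) / (2 * k) - (1 + 3 * k) / t^2)
}

# hydroxyapatite-in-water bone surrogate: `ha` grams of mineral per cc
.bone_mix <- function(ha) {
  rho_ha <- 3.16
  f <- ha / rho_ha                    # mineral volume fraction
  rho <- f * rho_ha + (1 - f) * 1.0
  w_ha <- ha / rho
  # Ca10(PO4)6(OH)2 mass fractions
  ha_comp <- c(Ca = 0.3989, P = 0.1850, O = 0.4141, H = 0.0020)
  water <- c(H = 0.1119, O = 0.8881)
  w <- w_ha * ha_comp[c("H", "O", "P", "Ca")] +
    (1 - w_ha) * c(water["H"], water["O"], 0, 0)
  list(density = rho, composition = setNames(as.numeric(w), c("H", "O", "P", "Ca")))
}

.material_db <- function() {
  soft <- c(H = 0.105, C = 0.256, N = 0.027, O = 0.602, Na = 0.001,
            P = 0.002, S = 0.003, Cl = 0.002, K = 0.002)
  b8 <- .bone_mix(0.8); b12 <- .bone_mix(1.25); b17 <- .bone_mix(1.75)
  bt <- .bone_mix(0.25)
  list(
    water = list(density = 1.0, composition = c(H = 0.1119, O = 0.8881)),
    air = list(density = 0.001205, composition = c(N = 0.755, O = 0.232, Ar = 0.013)),
    soft_tissue = list(density = 1.03, composition = soft),
    muscle = list(density = 1.05, composition = c(
      H = 0.102, C = 0.143, N = 0.034, O = 0.710, Na = 0.001, P = 0.002,
      S = 0.003, Cl = 0.001, K = 0.004)),
    adipose = list(density = 0.95, composition = c(
      H = 0.114, C = 0.598, N = 0.007, O = 0.278, Na = 0.001, S = 0.001,
      Cl = 0.001)),
    breast = list(density = 0.99, composition = c(
      H = 0.106, C = 0.332, N = 0.030, O = 0.527, Na = 0.001, P = 0.001,
      S = 0.002, Cl = 0.001)),
    liver = list(density = 1.06, composition = c(
      H = 0.102, C = 0.139, N = 0.030, O = 0.716, Na = 0.002, P = 0.003,
      S = 0.003, Cl = 0.002, K = 0.003)),
    lung_inhale = list(density = 0.205, composition = soft),
    lung_exhale = list(density = 0.507, composition = soft),
    trabecular_bone = list(density = bt$density, composition = bt$composition),
    dense_bone_800 = list(density = b8$density, composition = b8$composition),
    dense_bone_1250 = list(density = b12$density, composition = b12$composition),
    dense_bone_1750 = list(density = b17$density, composition = b17$composition),
    detector_scintillator = list(density = 4.51,
                                 composition = c(Cs = 0.511, I = 0.489)),
    aluminum = list(density = 2.699, composition = c(Al = 1))
  )
}

#' List the materials known to the package
#'
#' @return Character vector of material names usable in phantom
#'   specifications and [material_mu()].
#' @export
list_materials <- function() names(.material_db())

# mass attenuation components (cm^2/g) at arbitrary energies, from the
# parametric model (used only to build the 2-keV tables)
.model_components <- function(composition, energy_keV) {
  idx <- match(names(composition), .ELEMENTS$symbol)
  if (anyNA(idx)) stop("unknown element in composition: ",
                       paste(names(composition)[is.na(idx)], collapse = ", "))
  Z <- .ELEMENTS$Z[idx]; A <- .ELEMENTS$A[idx]; w <- as.numeric(composition)
  natoms <- .AVOGADRO * w / A   # atoms per gram, per element
  pe <- co <- inc <- numeric(length(energy_keV))
  skn <- sigma_kn(energy_keV)
  for (i in seq_along(Z)) {
    inc <- inc + natoms[i] * Z[i] * skn
    pe <- pe + natoms[i] * .C_PE * Z[i]^.A_PE * energy_keV^(-.B_PE)
    co <- co + natoms[i] * .C_CO * Z[i]^.A_CO * energy_keV^(-.B_CO)
  }
  list(photoelectric = pe, compton = inc, rayleigh = co)
}

#' Tabulated linear attenuation coefficients for a material
#'
#' Returns the packaged 2-keV-resolution table of linear attenuation
#' coefficients, split into photoelectric, Compton (incoherent) and
#' Rayleigh (coherent) components.
#'
#' @param material A material name from [list_materials()].
#' @return A tibble with columns `energy_keV`, `photoelectric`, `compton`,
#'   `rayleigh`, `total` (all in 1/cm).
#' @export
mu_table <- function(material) {
  db <- .material_db()
  if (!material %in% names(db)) {
    stop("unknown material: '", material, "'. See list_materials().")
  }
  key <- paste0("mu_", material)
  if (is.null(the[[key]])) {
    e <- mu_energy_grid()
    m <- db[[material]]
    comp <- .model_components(m$composition, e)
    the[[key]] <- tibble::tibble(
      energy_keV = e,
      photoelectric = comp$photoelectric * m$density,
      compton = comp$compton * m$density,
      rayleigh = comp$rayleigh * m$density,
      total = (comp$photoelectric + comp$compton + comp$rayleigh) * m$density
    )
  }
  the[[key]]
}

#' Linear attenuation components of a material at given energies
#'
#' Interpolates the packaged 2-keV tables log-log between bins.
#'
#' @param material Material name (see [list_materials()]).
#' @param energy_keV Photon energies in keV, within the tabulated range
#'   10-150 keV.
#' @return A tibble with one row per energy and columns `energy_keV`,
#'   `photoelectric`, `compton`, `rayleigh` and `total`, in 1/cm.
#' @examples
#' material_mu("water", 60)
#' @export
material_mu <- function(material, energy_keV) {
  tab <- mu_table(material)
  rng <- range(tab$energy_keV)
  if (any(energy_keV < rng[1] | energy_keV > rng[2])) {
    stop("energy out of tabulated range [", rng[1], ", ", rng[2], "] keV")
  }
  loglin <- function(y) {
    exp(stats::approx(log(tab$energy_keV), log(pmax(y, 1e-300)),
                      xout = log(energy_keV))$y)
  }
  pe <- loglin(tab$photoelectric)
  co <- loglin(tab$compton)
  ra <- loglin(tab$rayleigh)
  tibble::tibble(energy_keV = energy_keV, photoelectric = pe, compton = co,
                 rayleigh = ra, total = pe + co + ra)
}

#' Density of a material in g/cm^3
#' @param material Material name.
#' @return Density in g/cm^3.
#' @export
material_density <- function(material) {
  db <- .material_db()
  if (!material %in% names(db)) stop("unknown material: '", material, "'")
  db[[material]]$density
}

# (ne x nmat) matrices of one mu component on the standard grid, for C++
.mu_matrices <- function(materials) {
  e <- mu_energy_grid()
  comp <- function(which) {
    vapply(materials, function(m) mu_table(m)[[which]], numeric(length(e)))
  }
  list(pe = comp("photoelectric"), co = comp("compton"), ra = comp("rayleigh"),
       tot = comp("total"), e0 = e[1], de = e[2] - e[1], ne = length(e))
}
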