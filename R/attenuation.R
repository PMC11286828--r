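# Synthetic monoenergetic photon attenuation model and CT scan models.
#
# The forward model is deliberately simple: each tube is represented by a
# single effective energy, and elemental mass attenuation is a parametric
# per-electron cross section
#
#     sigma_e(Z, E) = sigma_KN(E) + C_pe Z^3.62 / E^3.2 + C_coh Z^1.86 / E^1.9
#
# (exact Klein-Nishina incoherent term plus photoelectric-like and
# coherent-like power laws).  The two amplitudes are anchored to plausible
# water photoelectric / coherent mass-attenuation values at 60 keV.  This
# is a SYNTHETIC model, not a measured cross-section table: it preserves
# the electron-density / atomic-number structure that dual-energy CT
# exploits without spectra or beam hardening.

ELECTRON_RADIUS_CM <- 2.8179403262e-13
PE_EXPONENT_Z <- 3.62
COH_EXPONENT_Z <- 1.86
PE_EXPONENT_E <- 3.2
COH_EXPONENT_E <- 1.9
PE_WATER_60KEV <- 0.0063   # cm^2/g, photoelectric anchor for water at 60 keV
COH_WATER_60KEV <- 0.0112  # cm^2/g, coherent anchor for water at 60 keV

#' Klein-Nishina total cross section per electron
#'
#' @param energy_keV Photon energy in keV.
#' @return Cross section in cm^2 per electron.
#' @export
kn_cross_section <- function(energy_keV) {
  stopifnot(all(energy_keV > 0))
  eps <- energy_keV * 1000 / ELECTRON_REST_EV
  l <- log(1 + 2 * eps)
  2 * pi * ELECTRON_RADIUS_CM^2 *
    ((1 + eps) / eps^2 * (2 * (1 + eps) / (1 + 2 * eps) - l / eps) +
       l / (2 * eps) - (1 + 3 * eps) / (1 + 2 * eps)^2)
}

# Amplitudes C_pe, C_coh of the parametric cross-section model, anchored
# once to the water values above.
attenuation_amplitudes <- function() {
  if (is.null(.porospr_cache$atten_amp)) {
    w <- get_material("water")$composition
    lam <- electron_fractions(w)
    ne_per_g <- AVOGADRO * electron_sum(w)
    z1 <- sum(lam * w$Z^PE_EXPONENT_Z)
    z2 <- sum(lam * w$Z^COH_EXPONENT_Z)
    .porospr_cache$atten_amp <- list(
      C_pe = (PE_WATER_60KEV / ne_per_g) * 60^PE_EXPONENT_E / z1,
      C_coh = (COH_WATER_60KEV / ne_per_g) * 60^COH_EXPONENT_E / z2)
  }
  .porospr_cache$atten_amp
}

#' Elemental mass attenuation coefficient (synthetic model)
#'
#' @param Z Atomic number(s).
#' @param A Relative atomic mass(es), g/mol.
#' @param energy_keV Photon energy in keV (scalar).
#' @return Mass attenuation coefficient(s) in cm^2/g.
#' @export
mass_attenuation <- function(Z, A, energy_keV) {
  stopifnot(length(energy_keV) == 1, energy_keV > 0)
  amp <- attenuation_amplitudes()
  sigma <- kn_cross_section(energy_keV) +
    amp$C_pe * Z^PE_EXPONENT_Z / energy_keV^PE_EXPONENT_E +
    amp$C_coh * Z^COH_EXPONENT_Z / energy_keV^COH_EXPONENT_E
  AVOGADRO * (Z / A) * sigma
}

# Linear attenuation coefficient of a material, 1/cm.
material_attenuation <- function(mat, energy_keV) {
  comp <- mat$composition
  mat$density * sum(comp$w * mass_attenuation(comp$Z, comp$A, energy_keV))
}

#' CT scan model (tube, effective energy, noise)
#'
#' A monoenergetic stand-in for one tube setting of the scanner.  Default
#' effective energies are 52 keV (80 kV), 63 keV (120 kV) and 68 keV
#' (135 kV) with additive Gaussian HU noise sigma of 7, 5 and 7 HU
#' respectively.  Water evaluates to exactly 0 HU under the model by
#' construction.
#'
#' @param tube One of `"80kV"`, `"120kV"`, `"135kV"`.
#' @param energy_keV Effective energy override, keV.
#' @param noise_sigma Noise standard deviation override, HU.
#' @return An object of class `scan_model` with fields `tube`,
#'   `energy_keV`, `noise_sigma`, `mu_water` (1/cm).
#' @export
scan_model <- function(tube = c("80kV", "120kV", "135kV"),
                       energy_keV = NULL, noise_sigma = NULL) {
  tube <- match.arg(tube)
  defaults <- list(`80kV` = c(52, 7), `120kV` = c(63, 5), `135kV` = c(68, 7))
  d <- defaults[[tube]]
  energy_keV <- if (is.null(energy_keV)) d[1] else energy_keV
  noise_sigma <- if (is.null(noise_sigma)) d[2] else noise_sigma
  stopifnot(energy_keV > 0, noise_sigma >= 0)
  structure(list(tube = tube, energy_keV = energy_keV,
                 noise_sigma = noise_sigma,
                 mu_water = material_attenuation(get_material("water"),
                                                 energy_keV)),
            class = "scan_model")
}

#' Noiseless CT number of a material under a scan model
#'
#' @param mat A [material()] object.
#' @param scan A [scan_model()].
#' @return CT number in HU: `1000 * (mu / mu_water - 1)`.
#' @export
material_hu <- function(mat, scan) {
  1000 * (material_attenuation(mat, scan$energy_keV) / scan$mu_water - 1)
}
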