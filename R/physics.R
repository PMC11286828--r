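# Closed-form radiological and stopping-power physics.

AVOGADRO <- 6.02214076e23        # 1/mol
ELECTRON_REST_EV <- 510998.95    # electron rest energy, eV
NUCLEON_REST_MEV <- 931.494      # atomic mass unit rest energy, MeV

#' Physics constants for SPR conversion
#'
#' Bundles the constants of the Bethe SPR expression and of the effective
#' atomic number model: electron rest energy, the mean excitation energy of
#' water `Iw`, the Mayneord exponent `m`, and water's effective atomic
#' number `Zeff_w`.  Both `Iw` and `Zeff_w` default to values computed
#' from the packaged water composition (Bragg additivity gives
#' 75.32 eV, matching the adopted 75.3 eV; the Mayneord mean at
#' `m = 3.3` gives 7.478), so the model is exactly self-consistent at
#' water rather than relying on rounded literature values.
#'
#' @param Iw Water mean excitation energy in eV; `NULL` (default)
#'   computes it from the packaged water composition.
#' @param m Mayneord power-mean exponent (default 3.3).
#' @param me_c2 Electron rest energy in eV.
#' @return An object of class `physics_constants` with fields `me_c2`,
#'   `Iw`, `m`, `Zeff_w`.
#' @export
physics_constants <- function(Iw = NULL, m = 3.3, me_c2 = ELECTRON_REST_EV) {
  if (is.null(Iw)) {
    Iw <- mean_excitation_energy(get_material("water")$composition)
  }
  stopifnot(Iw > 0, m > 0, me_c2 > 0)
  zw <- effective_atomic_number(get_material("water")$composition, m)
  structure(list(me_c2 = me_c2, Iw = Iw, m = m, Zeff_w = zw),
            class = "physics_constants")
}

#' Beam specification for a charged-particle beam
#'
#' @param kinetic_energy Kinetic energy in MeV per nucleon (>= 0).
#' @param water_range Optional reference range in water, mm.
#' @return An object of class `beam_spec` with fields `kinetic_energy`,
#'   `beta` (computed relativistically) and `water_range`.
#' @examples
#' beam_spec(131.0)$beta  # 0.481 to three decimals
#' @export
beam_spec <- function(kinetic_energy, water_range = NULL) {
  structure(list(kinetic_energy = kinetic_energy,
                 beta = beta_from_kinetic_energy(kinetic_energy),
                 water_range = water_range),
            class = "beam_spec")
}

#' Relativistic speed from kinetic energy per nucleon
#'
#' beta = sqrt(1 - 1/gamma^2) with gamma = 1 + E/u, u = 931.494 MeV.
#'
#' @param energy Kinetic energy in MeV per nucleon (>= 0).
#' @return beta, the speed as a fraction of c.
#' @export
beta_from_kinetic_energy <- function(energy) {
  if (any(energy < 0)) stop("kinetic energy must be non-negative")
  gamma <- 1 + energy / NUCLEON_REST_MEV
  sqrt(1 - 1 / gamma^2)
}

#' Relative electron density of a material
#'
#' Electrons per unit volume relative to liquid water at 1.0 g/cm^3:
#' `rho * sum(w_i Z_i / A_i)` over the same sum for water.
#'
#' @param mat A [material()] object.
#' @return Dimensionless relative electron density.
#' @export
relative_electron_density <- function(mat) {
  if (!inherits(mat, "material_spec")) stop("mat must be a material_spec")
  water <- get_material("water")
  mat$density * electron_sum(mat$composition) /
    (water$density * electron_sum(water$composition))
}

#' Effective atomic number (Mayneord power mean)
#'
#' `Zeff = (sum(lambda_i Z_i^m) / sum(lambda_i))^(1/m)` with
#' electron-fraction weights `lambda_i = w_i Z_i / A_i`.
#'
#' @param comp An [composition()] object.
#' @param m Power-mean exponent (> 0); 3.3 is the conventional choice for
#'   diagnostic-energy photon interactions.
#' @return Dimensionless effective atomic number, within
#'   `[min(Z), max(Z)]` of the composition.
#' @export
effective_atomic_number <- function(comp, m = 3.3) {
  if (!is_composition(comp)) stop("comp must be an elemental_composition")
  stopifnot(m > 0)
  lam <- electron_fractions(comp)
  sum(lam * comp$Z^m)^(1 / m)
}

#' Mean excitation energy by the Bragg additivity rule
#'
#' `ln I = sum(lambda_i ln I_i) / sum(lambda_i)` with electron-fraction
#' weights; elemental `I_i` come from the packaged element table unless
#' already attached to the composition.
#'
#' @param comp An [composition()] object.
#' @return Mean excitation energy in eV.
#' @export
mean_excitation_energy <- function(comp) {
  if (!is_composition(comp)) stop("comp must be an elemental_composition")
  if (anyNA(comp$I_eV) || any(comp$I_eV <= 0)) {
    bad <- comp$element[is.na(comp$I_eV) | comp$I_eV <= 0]
    stop("missing elemental I value for: ", paste(bad, collapse = ", "))
  }
  lam <- electron_fractions(comp)
  exp(sum(lam * log(comp$I_eV)))
}

#' Stopping power ratio by the Bethe formula
#'
#' `SPR = rho_e * (1 - ln(I/Iw) / (ln(2 me c^2 beta^2 / (Iw (1 - beta^2)))
#' - beta^2))`.  Shell corrections, density effect and nuclear interactions
#' are outside this model.
#'
#' @param rho_e Relative electron density (>= 0); vectorized.
#' @param I Mean excitation energy in eV (> 0); vectorized.
#' @param beam A [beam_spec()] (its `beta` is used).
#' @param constants A [physics_constants()].
#' @return Dimensionless stopping power ratio.
#' @export
spr_bethe <- function(rho_e, I, beam, constants = physics_constants()) {
  beta <- beam$beta
  if (any(rho_e < 0)) stop("rho_e must be non-negative")
  if (any(I <= 0)) stop("I must be positive")
  if (beta <= 0 || beta >= 1) stop("beta must lie in (0, 1)")
  denom <- bethe_denominator(beam, constants)
  if (denom <= 0) stop("Bethe logarithm non-positive: beta too low for Iw")
  rho_e * (1 - log(I / constants$Iw) / denom)
}

# The shared denominator of the Bethe SPR ratio:
# ln(2 me c^2 beta^2 / (Iw (1 - beta^2))) - beta^2.
bethe_denominator <- function(beam, constants) {
  b2 <- beam$beta^2
  log(2 * constants$me_c2 * b2 / (constants$Iw * (1 - b2))) - b2
}

#' Bethe SPR of a material specification
#'
#' Convenience wrapper: relative electron density and Bragg-additivity mean
#' excitation energy from the material, then [spr_bethe()].
#'
#' @inheritParams spr_bethe
#' @param mat A [material()] object.
#' @return Dimensionless stopping power ratio.
#' @export
material_spr <- function(mat, beam, constants = physics_constants()) {
  spr_bethe(relative_electron_density(mat),
            mean_excitation_energy(mat$composition), beam, constants)
}
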