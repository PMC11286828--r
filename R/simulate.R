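# Synthetic CT acquisition and ground-truth SPR volumes.

#' Construct a voxel volume of CT numbers
#'
#' @param data 3-D numeric array of HU values.
#' @param spacing Voxel spacing, mm per axis.
#' @param origin Physical position (mm) of the first voxel center.
#' @param tube Tube label (`"80kV"`, `"120kV"`, `"135kV"`).
#' @param hypothetical `TRUE` for volumes synthesized from an SPR map
#'   rather than simulated from a phantom.
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(data, spacing, origin, tube,
                         hypothetical = FALSE) {
  stopifnot(length(dim(data)) == 3, length(spacing) == 3, all(spacing > 0))
  if (any(data < -1000 - 1e-9)) stop("HU below -1000 after clamping")
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), tube = tube,
                 hypothetical = hypothetical),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat(sprintf("<voxel_volume> %s%s %dx%dx%d, HU range [%.1f, %.1f]\n",
              x$tube, if (isTRUE(x$hypothetical)) " (hypothetical)" else "",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              min(x$data), max(x$data)))
  invisible(x)
}

#' Construct an SPR volume
#'
#' @param data 3-D numeric array of stopping power ratios (>= 0).
#' @param spacing,origin Grid geometry, mm.
#' @param provenance `"DECT"`, `"SECT"` or `"truth"`.
#' @return An object of class `spr_volume`.
#' @export
spr_volume <- function(data, spacing, origin,
                       provenance = c("truth", "DECT", "SECT")) {
  provenance <- match.arg(provenance)
  stopifnot(length(dim(data)) == 3, all(data >= 0))
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), provenance = provenance),
            class = "spr_volume")
}

#' @export
print.spr_volume <- function(x, ...) {
  cat(sprintf("<spr_volume> %s %dx%dx%d, range [%.4f, %.4f]\n",
              x$provenance, dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              min(x$data), max(x$data)))
  invisible(x)
}

same_grid <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$spacing - b$spacing)) < 1e-9 &&
    max(abs(a$origin - b$origin)) < 1e-9
}

#' Simulate a CT acquisition of a phantom
#'
#' Per voxel the linear attenuation is the volume-fraction-weighted sum of
#' the component materials' attenuation at the scan's effective energy;
#' the CT number is `1000 * (mu / mu_water - 1)` plus additive Gaussian
#' noise of the scan's `noise_sigma`, clamped at -1000 HU.  With
#' `noise_sigma = 0` the result is deterministic and seed-independent.
#'
#' @param phantom A [phantom_definition()].
#' @param scan A [scan_model()].
#' @param seed Integer seed for the noise draw.
#' @return A [voxel_volume()].
#' @export
simulate_ct <- function(phantom, scan, seed = 1) {
  mu <- array(0, phantom$dim)
  for (nm in names(phantom$materials)) {
    mu_m <- material_attenuation(phantom$materials[[nm]], scan$energy_keV)
    mu <- mu + phantom$fractions[[nm]] * mu_m
  }
  hu <- 1000 * (mu / scan$mu_water - 1)
  if (scan$noise_sigma > 0) {
    set.seed(seed)
    hu <- hu + array(stats::rnorm(length(hu), 0, scan$noise_sigma),
                     phantom$dim)
  }
  hu[hu < -1000] <- -1000
  voxel_volume(hu, phantom$spacing, phantom$origin, scan$tube)
}

#' Ground-truth SPR volume of a phantom
#'
#' Pools each voxel's mixture by mass, computes relative electron density
#' and Bragg-additivity mean excitation energy from the pooled
#' composition, and evaluates the Bethe SPR.  Voxels with (near-)zero mass
#' get SPR 0.
#'
#' @param phantom A [phantom_definition()].
#' @param beam A [beam_spec()].
#' @param constants A [physics_constants()].
#' @return An [spr_volume()] with provenance `"truth"`.
#' @export
ground_truth_spr_volume <- function(phantom, beam,
                                    constants = physics_constants()) {
  e_sum <- array(0, phantom$dim)    # sum f rho sum(w Z/A): electron moles/cm3
  ln_sum <- array(0, phantom$dim)   # same, weighted by ln I_i
  for (nm in names(phantom$materials)) {
    m <- phantom$materials[[nm]]
    lam <- m$composition$w * m$composition$Z / m$composition$A
    s_e <- sum(lam)
    s_ln <- sum(lam * log(m$composition$I_eV))
    e_sum <- e_sum + phantom$fractions[[nm]] * m$density * s_e
    ln_sum <- ln_sum + phantom$fractions[[nm]] * m$density * s_ln
  }
  water <- get_material("water")
  rho_e <- e_sum / (water$density * electron_sum(water$composition))
  ln_i <- array(log(constants$Iw), phantom$dim)
  pos <- e_sum > 0
  ln_i[pos] <- ln_sum[pos] / e_sum[pos]
  denom <- bethe_denominator(beam, constants)
  spr <- rho_e * (1 - (ln_i - log(constants$Iw)) / denom)
  spr[spr < 0] <- 0
  spr_volume(spr, phantom$spacing, phantom$origin, "truth")
}
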