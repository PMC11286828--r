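# Voxelwise SPR map production and comparison statistics.

#' Dual-energy SPR conversion of a paired low/high-kV acquisition
#'
#' Chains the energy-subtraction relations per voxel: relative electron
#' density from the HU pair, reduced CT number `mu_L = HU_L/1000 + 1`,
#' atomic-number term `x = gamma_L (mu_L / rho_e - 1)` (floored at
#' `-1 + 1e-9`), a soft/bone branch split at
#' `x* = (ean_split / Zeff_w)^m - 1`, the branch's `ln(I/Iw) = c1 x - c0`,
#' and finally the Bethe SPR.  Voxels with electron density below
#' `air_threshold` are classed as air and get SPR 0.
#'
#' @param vol_L,vol_H Low- and high-kV [voxel_volume()]s on one grid.
#' @param params A [dect_params()].
#' @param beam A [beam_spec()].
#' @param constants A [physics_constants()].
#' @param air_threshold Electron-density floor below which a voxel is
#'   treated as air (default 0.01).
#' @return List with `spr` (an [spr_volume()], provenance `"DECT"`) and
#'   `intermediates`: arrays `rho_e`, `mu_L`, `x`, `ln_i_ratio`, and
#'   `branch` (integer array, 0 = air, 1 = soft, 2 = bone).
#' @export
deedz_spr_map <- function(vol_L, vol_H, params, beam,
                          constants = physics_constants(),
                          air_threshold = 0.01) {
  if (!same_grid(vol_L, vol_H)) stop("low- and high-kV volumes are on different grids")
  need <- c("a", "b", "alpha", "gamma_L", "c1_soft", "c0_soft", "c1_bone",
            "c0_bone", "m", "Iw", "ean_split")
  miss <- need[!vapply(need, function(f) is.numeric(params[[f]]) &&
                         is.finite(params[[f]]), TRUE)]
  if (length(miss)) stop("params missing constant(s): ",
                         paste(miss, collapse = ", "))
  hu_L <- vol_L$data; hu_H <- vol_H$data
  rho_e <- params$a * ((1 + params$alpha) * hu_H - params$alpha * hu_L) /
    1000 + params$b
  air <- rho_e < air_threshold
  rho_e_safe <- ifelse(air, 1, rho_e)
  mu_L <- hu_L / 1000 + 1
  x <- params$gamma_L * (mu_L / rho_e_safe - 1)
  x <- pmax(x, -1 + 1e-9)
  x_star <- (params$ean_split / constants$Zeff_w)^params$m - 1
  bone <- x >= x_star
  ln_i <- ifelse(bone, params$c1_bone * x - params$c0_bone,
                 params$c1_soft * x - params$c0_soft)
  # the denominator uses the parameter set's own Iw so a published
  # parameter set reproduces its pipeline exactly
  denom <- bethe_denominator(beam, list(me_c2 = constants$me_c2,
                                        Iw = params$Iw))
  spr <- rho_e * (1 - ln_i / denom)
  spr[air] <- 0
  spr[spr < 0] <- 0
  branch <- array(1L, dim(hu_L))
  branch[bone] <- 2L
  branch[air] <- 0L
  ln_i[air] <- 0
  list(spr = spr_volume(spr, vol_L$spacing, vol_L$origin, "DECT"),
       intermediates = list(rho_e = rho_e, mu_L = mu_L, x = x,
                            ln_i_ratio = ln_i, branch = branch))
}

#' Single-energy SPR conversion via the lookup table
#'
#' @param vol_120 A 120 kV [voxel_volume()].
#' @param lut A `sect_lut` from [build_hu_spr_lut()].
#' @return An [spr_volume()] with provenance `"SECT"`.
#' @export
sect_spr_map <- function(vol_120, lut) {
  spr_volume(lut_lookup(lut, vol_120$data), vol_120$spacing,
             vol_120$origin, "SECT")
}

#' Voxelwise SPR difference (dual-energy minus single-energy)
#'
#' @param spr_dect,spr_sect Aligned [spr_volume()]s.
#' @return 3-D array of `SPR_DECT - SPR_SECT`.
#' @export
delta_spr_map <- function(spr_dect, spr_sect) {
  if (!same_grid(spr_dect, spr_sect)) stop("SPR volumes are on different grids")
  spr_dect$data - spr_sect$data
}

#' Mean SPR over a cylindrical region of interest
#'
#' Unweighted mean over voxels whose centers lie inside a finite
#' cylinder (default 4 mm diameter, 9 mm length, matching the
#' sample-extraction region of interest).
#'
#' @param spr An [spr_volume()].
#' @param center Cylinder center, mm (length 3).
#' @param axis Cylinder axis direction (length 3; normalized internally).
#' @param diameter,length Cylinder dimensions, mm.
#' @return List with `mean` and `n_voxels`.
#' @export
roi_cylinder_mean <- function(spr, center, axis = c(0, 1, 0),
                              diameter = 4, length = 9) {
  stopifnot(diameter > 0, length > 0)
  axis <- axis / sqrt(sum(axis^2))
  ax <- voxel_axes(spr)
  d <- dim(spr$data)
  px <- array(rep(ax[[1]] - center[1], times = d[2] * d[3]), d)
  py <- array(rep(rep(ax[[2]] - center[2], each = d[1]), times = d[3]), d)
  pz <- array(rep(ax[[3]] - center[3], each = d[1] * d[2]), d)
  t <- px * axis[1] + py * axis[2] + pz * axis[3]
  r2 <- (px - t * axis[1])^2 + (py - t * axis[2])^2 + (pz - t * axis[3])^2
  inside <- abs(t) <= length / 2 & r2 <= (diameter / 2)^2
  if (!any(inside)) {
    stop(sprintf("empty ROI: cylinder center (%g, %g, %g), diameter %g, length %g contains no voxel centers",
                 center[1], center[2], center[3], diameter, length))
  }
  list(mean = mean(spr$data[inside]), n_voxels = sum(inside))
}

#' Histogram, median and mean of SPR inside a mask
#'
#' @param spr An [spr_volume()].
#' @param mask Logical array aligned with `spr` (non-empty).
#' @param breaks Histogram bin edges (default 0 to 2.5, width 0.05);
#'   values outside the edges are counted separately in `n_outside`.
#' @param reference Optional aligned [spr_volume()] (e.g. the
#'   single-energy map): when given, paired scatter samples
#'   `(reference SPR, SPR - reference SPR)` over the mask are returned.
#' @return List with `counts`, `breaks`, `median`, `mean`, `n`,
#'   `n_outside`, and optionally `scatter` (data frame `ref_spr`,
#'   `delta_spr`).
#' @export
mask_statistics <- function(spr, mask, breaks = seq(0, 2.5, by = 0.05),
                            reference = NULL) {
  if (!identical(dim(mask), dim(spr$data))) stop("mask shape mismatch")
  if (!any(mask)) stop("empty mask")
  v <- spr$data[mask]
  inside <- v >= breaks[1] & v <= breaks[length(breaks)]
  counts <- if (any(inside)) {
    graphics::hist(v[inside], breaks = breaks, plot = FALSE)$counts
  } else integer(length(breaks) - 1)
  out <- list(counts = counts, breaks = breaks, median = stats::median(v),
              mean = mean(v), n = length(v), n_outside = sum(!inside))
  if (!is.null(reference)) {
    if (!same_grid(spr, reference)) stop("reference volume grid mismatch")
    r <- reference$data[mask]
    out$scatter <- data.frame(ref_spr = r, delta_spr = v - r)
  }
  out
}

#' Override the SPR inside a mask
#'
#' Returns a copy with masked voxels set to a constant (the
#' soft-tissue-override step of the planning study: regions simulating
#' soft tissue are forced to SPR 1.0).
#'
#' @param spr An [spr_volume()].
#' @param mask Logical array aligned with `spr`.
#' @param value Replacement SPR (>= 0).
#' @return A new [spr_volume()]; the input is not modified.
#' @export
override_spr_region <- function(spr, mask, value = 1.0) {
  if (!identical(dim(mask), dim(spr$data))) stop("mask shape mismatch")
  if (value < 0) stop("override SPR must be non-negative")
  out <- spr
  out$data[mask] <- value
  out
}

#' Transform an SPR map into a hypothetical 120 kV CT volume
#'
#' Applies the inverse of the single-energy lookup table per voxel, so a
#' planning system holding that fixed table reproduces the intended SPR
#' exactly.  The result is labeled hypothetical.
#'
#' @param spr An [spr_volume()] (values >= 0).
#' @param lut A `sect_lut`.
#' @return A [voxel_volume()] with tube `"120kV"` and
#'   `hypothetical = TRUE`.
#' @export
spr_to_hypothetical_ct <- function(spr, lut) {
  hu <- invert_lut(lut, spr$data)
  voxel_volume(hu, spr$spacing, spr$origin, "120kV", hypothetical = TRUE)
}
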