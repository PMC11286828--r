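# Material specifications and the packaged material library.

#' Create a material specification
#'
#' A material couples a name, a bulk density and an elemental composition.
#' It is the unit of ground truth for every synthetic experiment: relative
#' electron density, effective atomic number, mean excitation energy, CT
#' attenuation and Bethe SPR are all derived from it.
#'
#' @param name Material name.
#' @param density Bulk density in g/cm^3 (> 0; air-like values allowed).
#' @param comp An [composition()] object.
#' @return An object of class `material_spec`.
#' @export
material <- function(name, density, comp) {
  stopifnot(is.character(name), length(name) == 1)
  if (!is_composition(comp)) stop("comp must be an elemental_composition")
  if (!is.numeric(density) || length(density) != 1 || density <= 0) {
    stop("density must be a single positive number (material '", name, "')")
  }
  structure(list(name = name, density = density, composition = comp),
            class = "material_spec")
}

#' @export
print.material_spec <- function(x, ...) {
  cat(sprintf("<material_spec> %s (%.4g g/cm^3, %d elements)\n",
              x$name, x$density, nrow(x$composition)))
  invisible(x)
}

#' Packaged material library
#'
#' Loads the full packaged material library (reference human tissues,
#' synthetic calibration-insert substitutes, hydroxyapatite, air, water)
#' from `inst/extdata/materials.csv`.
#'
#' @return A named list of [material()] objects.
#' @export
material_library <- function() {
  if (is.null(.porospr_cache$materials)) {
    path <- system.file("extdata", "materials.csv", package = "porospr",
                        mustWork = TRUE)
    tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
    .porospr_cache$materials <- lapply(split(tab, tab$material), function(d) {
      material(d$material[1], d$density_g_cm3[1],
               composition(d$element, d$mass_fraction))
    })
  }
  .porospr_cache$materials
}

#' Look up one packaged material by name
#'
#' @param name Material name, e.g. `"water"`, `"cortical_bone"`,
#'   `"hydroxyapatite"`.
#' @return A [material()] object.
#' @export
get_material <- function(name) {
  lib <- material_library()
  if (!name %in% names(lib)) {
    stop("unknown material '", name, "'; see names(material_library())")
  }
  lib[[name]]
}

#' Names of the default calibration insert set
#'
#' Nine tissue-substitute inserts spanning lung to dense bone, plus water.
#' These emulate a commercial electron-density calibration phantom's insert
#' set at nominal densities.
#'
#' @return Character vector of material names.
#' @export
calibration_insert_names <- function() {
  c("lung_inhale", "lung_exhale", "adipose_insert", "breast_insert",
    "muscle_insert", "liver_insert", "trabecular_bone_200",
    "dense_bone_800", "dense_bone_1250", "water")
}

#' Names of the reference human tissue set
#'
#' The reference-tissue list used to populate the single-energy
#' CT-number-to-SPR curve, spanning air to cortical bone.
#'
#' @return Character vector of material names.
#' @export
reference_tissue_names <- function() {
  c("air", "lung", "adipose", "yellow_marrow", "breast", "water", "brain",
    "red_marrow", "muscle", "liver", "blood", "eye_lens", "skin",
    "cartilage", "spongiosa", "cortical_bone")
}

#' Mix materials by volume fractions
#'
#' Pools a set of materials into a single equivalent material: bulk density
#' is the volume-fraction-weighted sum, and elemental mass fractions are
#' pooled by mass.  This is the partial-volume model of a CT voxel
#' containing several media.
#'
#' @param materials List of [material()] objects.
#' @param volume_fractions Numeric vector in `[0, 1]` summing to 1 (1e-9).
#' @param name Name for the mixture.
#' @return A [material()] object.
#' @export
mix_materials <- function(materials, volume_fractions, name = "mixture") {
  stopifnot(length(materials) == length(volume_fractions))
  f <- as.numeric(volume_fractions)
  if (any(f < 0) || any(f > 1) || abs(sum(f) - 1) > 1e-9) {
    stop("volume fractions must lie in [0,1] and sum to 1")
  }
  rho <- sum(f * vapply(materials, function(m) m$density, 0))
  els <- unique(unlist(lapply(materials, function(m) m$composition$element)))
  w <- setNames(numeric(length(els)), els)
  for (i in seq_along(materials)) {
    ci <- materials[[i]]$composition
    w[ci$element] <- w[ci$element] + f[i] * materials[[i]]$density * ci$w
  }
  w <- w / sum(w)
  material(name, rho, composition(names(w), unname(w)))
}
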