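# Digital phantoms: voxelized material mixtures with named region masks.

#' Construct a phantom definition
#'
#' A phantom is a voxel grid in which every voxel is a partial-volume
#' mixture of the phantom's materials.  Mixtures are stored as one 3-D
#' volume-fraction array per material; fractions must lie in `[0, 1]` and
#' sum to 1 per voxel (1e-9).  Named logical masks mark regions of
#' interest (inserts, bone, sample, ...).
#'
#' @param dim Integer grid shape `c(nx, ny, nz)`.
#' @param spacing Voxel spacing in mm per axis.
#' @param materials Named list of [material()] objects.
#' @param fractions Named list (same names) of arrays of shape `dim`.
#' @param masks Named list of logical arrays of shape `dim`.
#' @param origin Physical position (mm) of the first voxel's center;
#'   default centers the grid on the coordinate origin.
#' @return An object of class `ct_phantom`.
#' @export
phantom_definition <- function(dim, spacing, materials, fractions,
                               masks = list(), origin = NULL) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3, all(dim >= 1), length(spacing) == 3,
            all(spacing > 0))
  if (is.null(origin)) origin <- -(dim - 1) / 2 * spacing
  if (!identical(sort(names(materials)), sort(names(fractions)))) {
    stop("materials and fractions must share the same names")
  }
  total <- array(0, dim)
  for (nm in names(fractions)) {
    f <- fractions[[nm]]
    if (!identical(dim(f), dim)) stop("fraction array shape mismatch: ", nm)
    if (any(f < -1e-12) || any(f > 1 + 1e-12)) {
      stop("volume fractions outside [0,1] for material: ", nm)
    }
    total <- total + f
  }
  if (max(abs(total - 1)) > 1e-9) {
    stop("per-voxel volume fractions do not sum to 1 (max deviation ",
         format(max(abs(total - 1))), ")")
  }
  for (nm in names(masks)) {
    if (!identical(dim(masks[[nm]]), dim) || !is.logical(masks[[nm]])) {
      stop("mask must be a logical array of the grid shape: ", nm)
    }
  }
  structure(list(dim = dim, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), materials = materials,
                 fractions = fractions, masks = masks),
            class = "ct_phantom")
}

#' @export
print.ct_phantom <- function(x, ...) {
  cat(sprintf("<ct_phantom> %dx%dx%d @ %s mm; materials: %s; masks: %s\n",
              x$dim[1], x$dim[2], x$dim[3],
              paste(format(x$spacing), collapse = "x"),
              paste(names(x$materials), collapse = ", "),
              paste(names(x$masks), collapse = ", ")))
  invisible(x)
}

# Per-axis voxel-center coordinates (mm); works for phantoms and volumes.
voxel_axes <- function(obj) {
  d <- if (!is.null(obj$dim)) obj$dim else dim(obj$data)
  lapply(1:3, function(a) obj$origin[a] + (seq_len(d[a]) - 1) * obj$spacing[a])
}

# 3-D arrays of voxel-center x and y coordinates (z handled separately).
grid_xy <- function(obj) {
  ax <- voxel_axes(obj)
  list(x = array(rep(ax[[1]], times = obj$dim[2] * obj$dim[3]), obj$dim),
       y = array(rep(rep(ax[[2]], each = obj$dim[1]), times = obj$dim[3]),
                 obj$dim))
}

#' Build a calibration phantom
#'
#' Cylindrical tissue-substitute inserts arranged on a ring inside a
#' water-equivalent cylindrical background, emulating an electron-density
#' calibration phantom.  One mask is produced per insert
#' (`insert_<name>`), plus a `background` mask for the water bore.
#'
#' @param inserts Character vector of packaged material names (default
#'   [calibration_insert_names()]); may be empty for a pure-water phantom.
#' @param arrangement `"head"` (160 mm bore, ring radius 40 mm) or
#'   `"body"` (larger bore and ring).
#' @param dim,spacing Grid shape and spacing (mm).
#' @param insert_diameter Insert diameter in mm.
#' @return A [phantom_definition()] with disjoint insert masks.
#' @export
build_calibration_phantom <- function(inserts = calibration_insert_names(),
                                      arrangement = c("head", "body"),
                                      dim = c(128, 128, 16),
                                      spacing = c(1, 1, 2),
                                      insert_diameter = 12) {
  arrangement <- match.arg(arrangement)
  geom <- switch(arrangement,
                 head = list(bore = 60, ring = 40),
                 body = list(bore = 62, ring = 50))
  lib <- material_library()
  unknown <- setdiff(inserts, names(lib))
  if (length(unknown)) stop("unknown insert material(s): ",
                            paste(unknown, collapse = ", "))
  mats <- c(list(water = lib$water, air = lib$air),
            lib[setdiff(inserts, c("water", "air"))])

  ph_dim <- as.integer(dim)
  skel <- list(dim = ph_dim, spacing = spacing, origin = -(ph_dim - 1) / 2 * spacing)
  xy <- grid_xy(skel)
  r2 <- xy$x^2 + xy$y^2
  bore <- r2 <= geom$bore^2

  n <- length(inserts)
  masks <- list()
  occupied <- array(FALSE, ph_dim)
  if (n > 0) {
    ang <- 2 * pi * (seq_len(n) - 1) / n
    cx <- geom$ring * cos(ang)
    cy <- geom$ring * sin(ang)
    rad2 <- (insert_diameter / 2)^2
    for (i in seq_len(n)) {
      m <- (xy$x - cx[i])^2 + (xy$y - cy[i])^2 <= rad2
      if (any(m & occupied)) stop("overlapping inserts: reduce diameter or count")
      occupied <- occupied | m
      masks[[paste0("insert_", inserts[i])]] <- m
    }
  }
  masks$background <- bore & !occupied

  fractions <- setNames(vector("list", length(mats)), names(mats))
  for (nm in names(mats)) fractions[[nm]] <- array(0, ph_dim)
  fractions$air[!bore] <- 1
  fractions$water[masks$background] <- 1
  for (i in seq_len(n)) {
    fractions[[inserts[i]]][masks[[paste0("insert_", inserts[i])]]] <-
      fractions[[inserts[i]]][masks[[paste0("insert_", inserts[i])]]] + 1
  }
  # water insert voxels: the line above already set water where needed
  phantom_definition(ph_dim, spacing, mats, fractions, masks)
}

#' Build a porous-sample phantom
#'
#' A slab of porous material (base mineral plus pore filler, normally air)
#' immersed in water, emulating a porous bone substitute placed in a beam
#' path.  `pore_model = "uniform"` mixes every sample voxel at
#' `(1 - porosity) * base + porosity * filler` (partial volume: pores much
#' smaller than a voxel, e.g. the 150-micron pores of porous
#' hydroxyapatite ceramics).  `pore_model = "binary"` assigns whole voxels
#' to the filler with probability `porosity` (resolved pores; seeded).
#'
#' @param base [material()] for the solid matrix (default hydroxyapatite).
#' @param filler [material()] filling the pores (default air).
#' @param porosity Pore volume fraction in `[0, 1)`.
#' @param pore_model `"uniform"` or `"binary"`.
#' @param pore_diameter_mm Nominal pore diameter (metadata; default 0.15).
#' @param seed Integer seed used by the `"binary"` model.
#' @param dim,spacing Grid shape and spacing (mm).
#' @param slab_thickness Sample slab thickness along x, mm.
#' @return A [phantom_definition()] with `sample` and `background` masks
#'   and attribute `porosity`.
#' @export
build_porosity_phantom <- function(base = get_material("hydroxyapatite"),
                                   filler = get_material("air"),
                                   porosity = 0.75,
                                   pore_model = c("uniform", "binary"),
                                   pore_diameter_mm = 0.15, seed = 1,
                                   dim = c(64, 64, 16), spacing = c(1, 1, 1),
                                   slab_thickness = 20) {
  pore_model <- match.arg(pore_model)
  if (porosity < 0 || porosity >= 1) stop("porosity must lie in [0, 1)")
  ph_dim <- as.integer(dim)
  skel <- list(dim = ph_dim, spacing = spacing, origin = -(ph_dim - 1) / 2 * spacing)
  xy <- grid_xy(skel)
  sample_mask <- abs(xy$x) <= slab_thickness / 2

  mats <- list(water = get_material("water"))
  mats[[base$name]] <- base
  mats[[filler$name]] <- filler
  fr <- setNames(lapply(mats, function(m) array(0, ph_dim)), names(mats))
  fr$water[!sample_mask] <- 1
  if (pore_model == "uniform") {
    fr[[base$name]][sample_mask] <- 1 - porosity
    fr[[filler$name]][sample_mask] <- fr[[filler$name]][sample_mask] + porosity
  } else {
    set.seed(seed)
    pore <- array(FALSE, ph_dim)
    pore[sample_mask] <- stats::runif(sum(sample_mask)) < porosity
    fr[[filler$name]][sample_mask & pore] <- fr[[filler$name]][sample_mask & pore] + 1
    fr[[base$name]][sample_mask & !pore] <- fr[[base$name]][sample_mask & !pore] + 1
  }
  ph <- phantom_definition(ph_dim, spacing, mats, fr,
                           masks = list(sample = sample_mask,
                                        background = !sample_mask))
  attr(ph, "porosity") <- porosity
  attr(ph, "pore_model") <- pore_model
  attr(ph, "pore_diameter_mm") <- pore_diameter_mm
  ph
}

#' Build a head-like phantom with a porous bone cylinder
#'
#' Soft tissue everywhere, with a bone cylinder along z: a cortical shell
#' (default 2 mm) around a trabecular interior modeled as a
#' mineral/marrow/air partial-volume mixture.  This is the anthropomorphic
#' analog used for bone-region SPR statistics and range-shift analysis.
#'
#' @param dim,spacing Grid shape and spacing (mm).
#' @param bone_radius Outer bone radius, mm.
#' @param cortical_thickness Cortical shell thickness, mm.
#' @param trabecular_fractions Named volume fractions of the interior,
#'   summing to 1: `mineral` (cortical-bone material), `marrow`
#'   (yellow marrow) and `air`.
#' @param soft_tissue Packaged material name for the background.
#' @return A [phantom_definition()] with masks `bone`, `cortical`,
#'   `trabecular`, `soft_tissue`.
#' @export
build_head_phantom <- function(dim = c(128, 128, 32), spacing = c(1, 1, 1),
                               bone_radius = 14, cortical_thickness = 2,
                               trabecular_fractions = c(mineral = 0.30,
                                                        marrow = 0.20,
                                                        air = 0.50),
                               soft_tissue = "muscle") {
  stopifnot(abs(sum(trabecular_fractions) - 1) < 1e-9,
            all(trabecular_fractions >= 0))
  ph_dim <- as.integer(dim)
  skel <- list(dim = ph_dim, spacing = spacing, origin = -(ph_dim - 1) / 2 * spacing)
  xy <- grid_xy(skel)
  r2 <- xy$x^2 + xy$y^2
  bone <- r2 <= bone_radius^2
  trab <- r2 <= (bone_radius - cortical_thickness)^2
  cort <- bone & !trab

  mats <- list(soft = get_material(soft_tissue),
               cortical_bone = get_material("cortical_bone"),
               yellow_marrow = get_material("yellow_marrow"),
               air = get_material("air"))
  fr <- setNames(lapply(mats, function(m) array(0, ph_dim)), names(mats))
  fr$soft[!bone] <- 1
  fr$cortical_bone[cort] <- 1
  fr$cortical_bone[trab] <- trabecular_fractions[["mineral"]]
  fr$yellow_marrow[trab] <- trabecular_fractions[["marrow"]]
  fr$air[trab] <- trabecular_fractions[["air"]]
  phantom_definition(ph_dim, spacing, mats, fr,
                     masks = list(bone = bone, cortical = cort,
                                  trabecular = trab, soft_tissue = !bone))
}
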