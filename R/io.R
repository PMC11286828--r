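# Volume and parameter I/O: NIfTI with JSON sidecars, parameter JSON.

#' Write a volume as NIfTI with a JSON sidecar
#'
#' Works for [voxel_volume()] (HU) and [spr_volume()] objects; the
#' sidecar records grid geometry plus the tube or provenance label and
#' any extra metadata.
#'
#' @param vol A `voxel_volume` or `spr_volume`.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @param extra Named list of additional sidecar fields.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, extra = list()) {
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  meta <- c(list(spacing_mm = vol$spacing, origin_mm = vol$origin), extra)
  if (inherits(vol, "voxel_volume")) {
    meta$tube <- vol$tube
    meta$hypothetical <- isTRUE(vol$hypothetical)
  } else {
    meta$provenance <- vol$provenance
  }
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

sidecar_path <- function(path) {
  paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
}

#' Read a volume written by [write_volume()]
#'
#' @param path Path to the `.nii`/`.nii.gz` file (sidecar found beside it).
#' @return A `voxel_volume` or `spr_volume`, according to the sidecar.
#' @export
read_volume <- function(path) {
  data <- array(as.numeric(RNifti::readNifti(path)),
                dim = dim(RNifti::readNifti(path)))
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  if (!is.null(meta$tube)) {
    voxel_volume(data, meta$spacing_mm, meta$origin_mm, meta$tube,
                 hypothetical = isTRUE(meta$hypothetical))
  } else {
    spr_volume(data, meta$spacing_mm, meta$origin_mm, meta$provenance)
  }
}

#' Write / read dual-energy parameters as JSON
#'
#' @param params A [dect_params()].
#' @param path File path.
#' @return `write_dect_params`: `path`, invisibly; `read_dect_params`:
#'   a [dect_params()].
#' @export
write_dect_params <- function(params, path) {
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dect_params
#' @export
read_dect_params <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  dect_params(a = p$a, b = p$b, alpha = p$alpha, gamma_L = p$gamma_L,
              c1_soft = p$c1_soft, c0_soft = p$c0_soft,
              c1_bone = p$c1_bone, c0_bone = p$c0_bone, m = p$m,
              Iw = p$Iw, ean_split = p$ean_split,
              r_squared = as.list(p$r_squared))
}
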