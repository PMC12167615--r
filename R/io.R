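#' Read a PET volume from NIfTI
#'
#' Reads a NIfTI-1 file, honoring its pixel dimensions and xform affine.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @param kind `"activity"` (kBq/mL) or `"suv"`.
#' @return A [pet_volume()].
#' @export
read_pet_volume <- function(path, kind = c("activity", "suv")) {
  kind <- match.arg(kind)
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img), dim(img)[1:3])
  spacing <- abs(RNifti::pixdim(img))[1:3]
  affine <- tryCatch(unclass(RNifti::xform(img)), error = function(e) NULL)
  pet_volume(vals, spacing, kind = kind, affine = affine)
}

#' Write a PET volume to NIfTI
#'
#' @param vol A [pet_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_pet_volume <- function(vol, path) {
  stopifnot(inherits(vol, "pet_volume"))
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read organ masks from a labelled NIfTI
#'
#' @param path Path to an integer-labelled NIfTI volume.
#' @param labels Named list/vector mapping organ name to label value(s);
#'   paired organs may map to several labels, which are pooled.
#' @return Named list of logical 3D arrays.
#' @export
read_organ_masks <- function(path, labels) {
  img <- RNifti::readNifti(path)
  lab <- array(as.integer(round(as.numeric(img))), dim(img)[1:3])
  out <- lapply(labels, function(v) array(lab %in% v, dim(lab)))
  names(out) <- names(labels)
  out
}

#' Read scan metadata from a YAML sidecar
#'
#' Expected keys: `injected_activity_MBq`, `injection_time`, `scan_time`
#' (ISO-8601 timestamps or numeric minutes), `weight_kg`, optional
#' `half_life_min`.
#'
#' @param path Path to a YAML file.
#' @return A [scan_meta()].
#' @export
read_scan_meta <- function(path) {
  y <- yaml::read_yaml(path)
  scan_meta(injected_activity_MBq = y$injected_activity_MBq,
            injection_time = y$injection_time,
            scan_time = y$scan_time,
            weight_kg = y$weight_kg,
            half_life_min = if (is.null(y$half_life_min)) 109.77
                            else y$half_life_min)
}
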