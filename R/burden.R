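#' Lesion set
#'
#' Tumour lesions on the PET grid, stored as one labelled integer array
#' (0 = background, 1..K = lesions).  A logical array or a list of disjoint
#' logical masks is also accepted and converted.
#'
#' @param x Labelled integer array, logical array, or list of logical arrays.
#' @param sites Optional character vector of site labels per lesion
#'   (e.g. `"prostate"`, `"node"`, `"bone"`).
#' @return An object of class `lesion_set` (`labels` array, `sites`).
#' @export
lesion_set <- function(x, sites = NULL) {
  if (is.list(x) && !is.array(x)) {
    if (length(x) == 0L) stop("empty list of lesion masks")
    lab <- array(0L, dim(x[[1L]]))
    for (k in seq_along(x)) {
      m <- .check_mask(x[[k]], dim(lab))
      if (any(lab[m] != 0L)) stop("lesion masks overlap")
      lab[m] <- k
    }
  } else if (is.logical(x)) {
    lab <- array(as.integer(x), dim(x))
  } else {
    if (!is.array(x) || any(x < 0) || any(x != round(x)))
      stop("lesion labels must be a non-negative integer array")
    lab <- array(as.integer(x), dim(x))
  }
  structure(list(labels = lab, sites = sites), class = "lesion_set")
}

#' Total lesion volume (TLV)
#'
#' Summed volume of all segmented lesions: voxel count times voxel volume,
#' reported in cm3.
#'
#' @param lesions A [lesion_set()] (or logical/labelled array).
#' @param spacing Voxel spacing in mm.
#' @return TLV in cm3.
#' @export
compute_tlv <- function(lesions, spacing) {
  if (!inherits(lesions, "lesion_set")) lesions <- lesion_set(lesions)
  sum(lesions$labels > 0L) * prod(spacing) / 1000
}

#' Total lesion uptake (TLU)
#'
#' TLV multiplied by the SUVmean over the union of all lesion voxels
#' (one global mean), which equals the voxelwise sum of SUV times voxel
#' volume.  Reported in SUV.cm3.  Zero when there are no lesions.
#'
#' @param vol A [pet_volume()] in SUV units.
#' @param lesions A [lesion_set()] on the same grid.
#' @return TLU in SUV.cm3.
#' @export
compute_tlu <- function(vol, lesions) {
  stopifnot(inherits(vol, "pet_volume"))
  if (vol$kind != "suv") stop("TLU requires an SUV volume")
  if (!inherits(lesions, "lesion_set")) lesions <- lesion_set(lesions)
  if (!identical(dim(lesions$labels), dim(vol$values)))
    stop("lesion and volume grids differ")
  sel <- lesions$labels > 0L
  if (!any(sel)) return(0)
  tlv <- sum(sel) * prod(vol$spacing) / 1000
  tlv * mean(vol$values[sel])
}

#' Percentage of injected activity in tumour
#'
#' From the SUV definition with tissue density 1 g/cm3, the fraction of the
#' decay-corrected administered activity residing in tumour is
#' TLU / (weight in g); reported as a percentage.
#'
#' @param tlu TLU in SUV.cm3.
#' @param meta A [scan_meta()] object (its weight is used).
#' @return Percentage in `[0, 100]`.
#' @export
pct_injected_activity <- function(tlu, meta) {
  stopifnot(inherits(meta, "scan_meta"))
  100 * tlu / (meta$weight_kg * 1000)
}

#' Per-patient burden metrics
#'
#' Convenience wrapper computing TLV, TLU and the percentage of injected
#' activity in one call.
#'
#' @inheritParams compute_tlu
#' @param meta A [scan_meta()] object.
#' @return List of class `burden_metrics`: `tlv` (cm3), `tlu` (SUV.cm3),
#'   `pct_injected` (%).
#' @export
burden_metrics <- function(vol, lesions, meta) {
  tlv <- compute_tlv(lesions, vol$spacing)
  tlu <- compute_tlu(vol, lesions)
  structure(list(tlv = tlv, tlu = tlu,
                 pct_injected = pct_injected_activity(tlu, meta)),
            class = "burden_metrics")
}

#' @export
print.burden_metrics <- function(x, ...) {
  cat(sprintf("Tumour burden: TLV = %.3g cm3, TLU = %.3g SUV.cm3, %.3g%% of injected activity\n",
              x$tlv, x$tlu, x$pct_injected))
  invisible(x)
}
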