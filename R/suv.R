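#' PET volume container
#'
#' A 3D scalar grid together with its voxel spacing and (optionally) a
#' voxel-to-world affine.  Values are either an activity concentration in
#' kBq/mL (`kind = "activity"`) or unitless standardized uptake values
#' (`kind = "suv"`).
#'
#' @param values Numeric 3D array. All values must be finite.
#' @param spacing Numeric length-3 vector, voxel edge lengths in mm
#'   `(dx, dy, dz)`; all components must be positive.
#' @param kind `"activity"` (kBq/mL) or `"suv"` (unitless).
#' @param affine Optional 4x4 voxel-to-world matrix (0-based voxel indices,
#'   NIfTI convention). When absent, world coordinates are taken as
#'   `(index - 0.5) * spacing`.
#' @return An object of class `pet_volume`.
#' @export
pet_volume <- function(values, spacing, kind = c("activity", "suv"),
                       affine = NULL) {
  kind <- match.arg(kind)
  if (!is.array(values) || length(dim(values)) != 3L || length(values) == 0L)
    stop("'values' must be a non-empty 3D array")
  if (!all(is.finite(values)))
    stop("'values' must be finite everywhere")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be three positive finite numbers (mm)")
  if (!is.null(affine)) {
    affine <- as.matrix(affine)
    if (!identical(dim(affine), c(4L, 4L))) stop("'affine' must be 4x4")
  }
  structure(list(values = values, spacing = spacing, kind = kind,
                 affine = affine),
            class = "pet_volume")
}

#' @export
print.pet_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("PET volume (%s): %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              x$kind, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  value range [%.4g, %.4g]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' Scan metadata for SUV conversion
#'
#' Holds the administered activity, injection and scan times, and patient
#' weight needed to convert an activity-concentration image into SUV.
#' Times may be given as `POSIXct` timestamps or directly as minutes on a
#' common clock.
#'
#' @param injected_activity_MBq Administered activity in MBq, assayed at
#'   injection time. Must be positive.
#' @param injection_time,scan_time `POSIXct` (or anything `as.POSIXct`
#'   accepts) or numeric minutes. The scan must not precede the injection.
#' @param weight_kg Patient weight in kg, positive.
#' @param half_life_min Isotope half-life in minutes; default 109.77 (F-18).
#' @return An object of class `scan_meta` with the uptake interval
#'   `dt_min` (minutes) precomputed.
#' @export
scan_meta <- function(injected_activity_MBq, injection_time, scan_time,
                      weight_kg, half_life_min = 109.77) {
  if (!is.numeric(injected_activity_MBq) || injected_activity_MBq <= 0)
    stop("'injected_activity_MBq' must be positive")
  if (!is.numeric(weight_kg) || weight_kg <= 0)
    stop("'weight_kg' must be positive")
  if (!is.numeric(half_life_min) || half_life_min <= 0)
    stop("'half_life_min' must be positive")
  dt_min <- .elapsed_minutes(injection_time, scan_time)
  if (dt_min < 0) stop("scan precedes injection")
  structure(list(injected_activity_MBq = injected_activity_MBq,
                 injection_time = injection_time,
                 scan_time = scan_time,
                 weight_kg = weight_kg,
                 half_life_min = half_life_min,
                 dt_min = dt_min),
            class = "scan_meta")
}

.elapsed_minutes <- function(t0, t1) {
  if (is.numeric(t0) && is.numeric(t1)) return(t1 - t0)
  fmts <- c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d")
  t0 <- as.POSIXct(t0, tz = "UTC", tryFormats = fmts)
  t1 <- as.POSIXct(t1, tz = "UTC", tryFormats = fmts)
  as.numeric(difftime(t1, t0, units = "mins"))
}

#' @export
print.scan_meta <- function(x, ...) {
  cat(sprintf("Scan metadata: %.1f MBq injected, %.1f kg, uptake %.1f min (T1/2 = %.2f min)\n",
              x$injected_activity_MBq, x$weight_kg, x$dt_min, x$half_life_min))
  invisible(x)
}

#' Decay-correct the administered activity to scan time
#'
#' Applies exponential radioactive decay over the uptake interval:
#' `Ai' = Ai * 2^(-dt / T_half)` with `dt` in minutes.  The result is the
#' administered activity expressed at the start of imaging, the `Ai` entering
#' the SUV denominator.
#'
#' @param meta A [scan_meta()] object.
#' @return Decay-corrected activity in MBq (`<= injected_activity_MBq`).
#' @export
decay_correct <- function(meta) {
  stopifnot(inherits(meta, "scan_meta"))
  meta$injected_activity_MBq * 2^(-meta$dt_min / meta$half_life_min)
}

#' Convert an activity-concentration volume to SUV
#'
#' SUV = Ac / (Ai / w), with the activity concentration Ac in kBq/mL, the
#' decay-corrected administered activity Ai in kBq and the body weight w in
#' grams.  Assuming a tissue density of 1 g/cm3 the result is unitless.
#' The map is linear in Ac.
#'
#' @param vol A [pet_volume()] with `kind = "activity"`.
#' @param meta A [scan_meta()] object.
#' @return A [pet_volume()] with `kind = "suv"` on the same grid.
#' @export
to_suv <- function(vol, meta) {
  stopifnot(inherits(vol, "pet_volume"), inherits(meta, "scan_meta"))
  if (vol$kind != "activity")
    stop("input volume is already in SUV units")
  ai_kBq <- decay_correct(meta) * 1000         # MBq -> kBq
  w_g <- meta$weight_kg * 1000                 # kg  -> g
  pet_volume(vol$values / (ai_kBq / w_g), vol$spacing, kind = "suv",
             affine = vol$affine)
}

#' Inverse SUV conversion (SUV to activity concentration)
#'
#' Used by the phantom generator to express a known-SUV field as the
#' activity concentration (kBq/mL) a scanner would report, so the forward
#' conversion round-trips.
#'
#' @inheritParams to_suv
#' @param vol A [pet_volume()] with `kind = "suv"`.
#' @return A [pet_volume()] with `kind = "activity"`.
#' @export
from_suv <- function(vol, meta) {
  stopifnot(inherits(vol, "pet_volume"), inherits(meta, "scan_meta"))
  if (vol$kind != "suv") stop("input volume is not in SUV units")
  ai_kBq <- decay_correct(meta) * 1000
  w_g <- meta$weight_kg * 1000
  pet_volume(vol$values * (ai_kBq / w_g), vol$spacing, kind = "activity",
             affine = vol$affine)
}
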