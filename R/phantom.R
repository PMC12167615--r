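#' Configuration for a single-patient digital phantom
#'
#' Describes a voxel grid carrying ellipsoidal organs at risk (kidneys and
#' parotid glands as bilateral pairs), spherical lesions, and a uniform
#' background.  Default baseline organ SUVmean values are the cohort medians
#' of [18F]PSMA-1007 uptake (kidneys 13.1, liver 11.8, parotid glands 18.6,
#' spleen 11.3); the default geometry fits all six components disjointly in
#' a 128 mm cube at 2 mm isotropic spacing, with every organ large enough to
#' admit its measurement sphere plus the 5 mm edge margin.
#'
#' @param grid_dim Integer length-3 grid dimensions.
#' @param spacing Voxel spacing in mm.
#' @param organs List of components, each
#'   `list(organ = <name>, center = <mm xyz>, semiaxes = <mm xyz>)`.
#' @param baseline_suv Named numeric, target SUVmean per organ.
#' @param background_suv Background SUV outside organs and lesions.
#' @param lesions List of `list(center = <mm>, radius = <mm>, suv = <SUV>)`.
#' @param noise_sd_frac Gaussian voxel-noise SD as a fraction of the local
#'   noiseless value (0 disables noise).
#' @param smooth_fwhm_mm FWHM of optional isotropic Gaussian smoothing
#'   applied before noise (0 disables).
#' @param weight_kg,act_per_kg_MBq,uptake_min Scan metadata: body weight,
#'   injected activity per kg, and injection-to-scan interval.
#' @param allow_overlap Permit lesions to overlap organs (lesion-in-organ
#'   fixtures); organ-organ overlap is always an error.
#' @param seed Integer seed recorded in the output and used for the noise.
#' @return List of class `phantom_config`.
#' @export
phantom_config <- function(grid_dim = c(64L, 64L, 64L),
                           spacing = c(2, 2, 2),
                           organs = default_organ_geometry(),
                           baseline_suv = c(kidneys = 13.1, liver = 11.8,
                                            parotids = 18.6, spleen = 11.3),
                           background_suv = 0.5,
                           lesions = list(),
                           noise_sd_frac = 0,
                           smooth_fwhm_mm = 0,
                           weight_kg = 87,
                           act_per_kg_MBq = 4.0,
                           uptake_min = 120,
                           allow_overlap = FALSE,
                           seed = 1L) {
  stopifnot(length(grid_dim) == 3L, all(grid_dim >= 1L),
            length(spacing) == 3L, all(spacing > 0),
            noise_sd_frac >= 0, smooth_fwhm_mm >= 0,
            weight_kg > 0, act_per_kg_MBq > 0, uptake_min >= 0)
  for (l in lesions) stopifnot(l$radius > 0, l$suv >= 0)
  structure(list(grid_dim = as.integer(grid_dim), spacing = spacing,
                 organs = organs, baseline_suv = baseline_suv,
                 background_suv = background_suv, lesions = lesions,
                 noise_sd_frac = noise_sd_frac,
                 smooth_fwhm_mm = smooth_fwhm_mm,
                 weight_kg = weight_kg, act_per_kg_MBq = act_per_kg_MBq,
                 uptake_min = uptake_min, allow_overlap = allow_overlap,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

#' Default phantom organ geometry
#'
#' Six ellipsoidal components (liver, spleen, two kidneys, two parotid
#' glands) placed disjointly in a 128 mm cube, in mm world coordinates.
#'
#' @return List of components for [phantom_config()].
#' @export
default_organ_geometry <- function() {
  # centers on odd mm so they coincide with voxel centers at 2 mm spacing,
  # maximizing the discrete inscribed radius of the smaller organs
  list(
    list(organ = "liver",    center = c(43, 43, 45), semiaxes = c(26, 24, 22)),
    list(organ = "spleen",   center = c(99, 41, 45), semiaxes = c(18, 16, 15)),
    list(organ = "kidneys",  center = c(37, 95, 39), semiaxes = c(16, 15, 14)),
    list(organ = "kidneys",  center = c(95, 95, 39), semiaxes = c(16, 15, 14)),
    list(organ = "parotids", center = c(33, 33, 99), semiaxes = c(16, 15, 14)),
    list(organ = "parotids", center = c(95, 33, 99), semiaxes = c(16, 15, 14))
  )
}

# voxel-center world coordinates along one axis
.axis_centers <- function(n, d) (seq_len(n) - 0.5) * d

.rasterize_ellipsoid <- function(grid_dim, spacing, center, semiaxes) {
  x <- .axis_centers(grid_dim[1], spacing[1])
  y <- .axis_centers(grid_dim[2], spacing[2])
  z <- .axis_centers(grid_dim[3], spacing[3])
  qx <- ((x - center[1]) / semiaxes[1])^2
  qy <- ((y - center[2]) / semiaxes[2])^2
  qz <- ((z - center[3]) / semiaxes[3])^2
  array(outer(outer(qx, qy, "+"), qz, "+") <= 1, grid_dim)
}

.rasterize_sphere <- function(grid_dim, spacing, center, radius) {
  .rasterize_ellipsoid(grid_dim, spacing, center, rep(radius, 3))
}

.gauss_smooth <- function(a, fwhm, spacing) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  for (ax in 1:3) {
    s <- sigma / spacing[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(-r:r, sd = s)
    k <- k / sum(k)
    a <- .conv_axis(a, k, ax)
  }
  a
}

# 1D convolution along one axis with replicate-edge padding
.conv_axis <- function(a, k, ax) {
  d <- dim(a)
  perm <- c(ax, setdiff(1:3, ax))
  b <- aperm(a, perm)
  m <- matrix(b, nrow = d[ax])
  r <- (length(k) - 1L) / 2L
  pad <- rbind(m[rep(1L, r), , drop = FALSE], m,
               m[rep(nrow(m), r), , drop = FALSE])
  out <- apply(pad, 2L, function(col) stats::filter(col, k, sides = 2))
  out <- out[(r + 1L):(r + nrow(m)), , drop = FALSE]
  aperm(array(out, d[perm]), order(perm))
}

#' Generate a single-patient digital phantom
#'
#' Rasterizes the configured organs and lesions on the voxel grid, fills the
#' target SUV values, optionally smooths and adds Gaussian voxel noise (SD
#' proportional to the local noiseless value), then converts the SUV field
#' to an activity-concentration volume via the inverse SUV relation so that
#' the quantification pipeline's own conversion round-trips.  The truth
#' record holds the exact per-organ SUVmean (target and realized), TLV, TLU
#' and the percentage of injected activity.
#'
#' @param cfg A [phantom_config()].
#' @return List of class `phantom_patient`: `pet` (activity-concentration
#'   [pet_volume()]), `suv` (the ground-truth SUV volume), `organ_masks`
#'   (named list of pooled logical masks), `lesions` ([lesion_set()] or
#'   `NULL`), `meta` ([scan_meta()]), `truth`, `config`.
#' @export
generate_patient <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  gd <- cfg$grid_dim; sp <- cfg$spacing

  comp_masks <- lapply(cfg$organs, function(o)
    .rasterize_ellipsoid(gd, sp, o$center, o$semiaxes))
  occupied <- array(FALSE, gd)
  for (m in comp_masks) {
    if (any(occupied & m)) stop("overlapping organs in phantom config")
    occupied <- occupied | m
  }
  organ_names <- vapply(cfg$organs, `[[`, character(1), "organ")
  organ_masks <- lapply(unique(organ_names), function(nm) {
    pooled <- array(FALSE, gd)
    for (i in which(organ_names == nm)) pooled <- pooled | comp_masks[[i]]
    pooled
  })
  names(organ_masks) <- unique(organ_names)

  suv <- array(cfg$background_suv, gd)
  for (i in seq_along(comp_masks)) {
    b <- cfg$baseline_suv[[organ_names[i]]]
    if (is.null(b) || is.na(b)) stop("no baseline SUV for organ ", organ_names[i])
    suv[comp_masks[[i]]] <- b
  }

  lesions <- NULL
  if (length(cfg$lesions) > 0L) {
    les_masks <- lapply(cfg$lesions, function(l)
      .rasterize_sphere(gd, sp, l$center, l$radius))
    for (i in seq_along(les_masks)) {
      if (!cfg$allow_overlap && any(occupied & les_masks[[i]]))
        stop("lesion overlaps an organ (set allow_overlap for fixtures)")
      suv[les_masks[[i]]] <- cfg$lesions[[i]]$suv
    }
    lesions <- lesion_set(les_masks)
  }

  if (cfg$smooth_fwhm_mm > 0)
    suv <- .gauss_smooth(suv, cfg$smooth_fwhm_mm, sp)
  if (cfg$noise_sd_frac > 0) {
    set.seed(cfg$seed)
    suv <- suv + stats::rnorm(length(suv), 0, cfg$noise_sd_frac * abs(suv))
  }

  meta <- scan_meta(injected_activity_MBq = cfg$act_per_kg_MBq * cfg$weight_kg,
                    injection_time = 0, scan_time = cfg$uptake_min,
                    weight_kg = cfg$weight_kg)
  suv_vol <- pet_volume(suv, sp, kind = "suv")
  pet <- from_suv(suv_vol, meta)

  realized <- vapply(organ_masks, function(m) mean(suv[m]), numeric(1))
  tlv <- if (is.null(lesions)) 0 else compute_tlv(lesions, sp)
  tlu <- if (is.null(lesions)) 0 else compute_tlu(suv_vol, lesions)
  truth <- list(baseline_suv = cfg$baseline_suv,
                realized_suv_mean = realized,
                tlv = tlv, tlu = tlu,
                pct_injected = pct_injected_activity(tlu, meta),
                seed = cfg$seed)

  structure(list(pet = pet, suv = suv_vol, organ_masks = organ_masks,
                 lesions = lesions, meta = meta, truth = truth, config = cfg),
            class = "phantom_patient")
}

#' Configuration for a synthetic cohort
#'
#' Parameterizes the image-free cohort generator.  Defaults emulate the
#' study population: zero-inflated lognormal tumour burden (point mass
#' 157/1086 at TLV = 0; median 3.8 cm3 among tumour-bearing patients with a
#' heavy upper tail reaching ~2000 cm3), lognormal lesion SUVmean so that
#' median TLU is ~31 SUV.cm3, per-organ multiplicative lognormal
#' inter-patient variability matched to the reported median/IQR of each
#' organ, body weight 87 +/- 14 kg (truncated to 48-146), injected activity
#' 4.0 +/- 0.2 MBq/kg, and an optional saturating tumour-sink coupling
#' `SUVmean_o = B_o * (1 - beta * TLU / (TLU + K)) * eps_o`.
#'
#' @param n Number of patients.
#' @param tlv_median,tlv_sdlog Lognormal TLV among tumour-bearing patients.
#' @param zero_prob Probability of TLV = 0.
#' @param lesion_suv_median,lesion_suv_sdlog Lognormal lesion SUVmean.
#' @param organ_median,organ_iqr Named per-organ cohort median and IQR of
#'   baseline SUVmean; the lognormal sdlog per organ is derived from the
#'   IQR-to-median ratio.
#' @param beta Sink strength in `[0, 1)`: maximal fractional uptake
#'   suppression at infinite burden.
#' @param K Half-saturation burden in SUV.cm3 (suppression reaches beta/2 at
#'   TLU = K).
#' @param weight_mean,weight_sd,weight_range Body-weight distribution (kg).
#' @param act_per_kg_mean,act_per_kg_sd Injected activity per kg (MBq/kg).
#' @param seed Integer seed.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n = 500L,
                          tlv_median = 3.8, tlv_sdlog = 2.0,
                          zero_prob = 157 / 1086,
                          lesion_suv_median = 8.2, lesion_suv_sdlog = 0.4,
                          organ_median = c(kidneys = 13.1, liver = 11.8,
                                           parotids = 18.6, spleen = 11.3),
                          organ_iqr = c(kidneys = 4.6, liver = 4.4,
                                        parotids = 6.8, spleen = 5.8),
                          beta = 0, K = 500,
                          weight_mean = 87, weight_sd = 14,
                          weight_range = c(48, 146),
                          act_per_kg_mean = 4.0, act_per_kg_sd = 0.2,
                          seed = 1L) {
  stopifnot(n >= 1L, tlv_median > 0, tlv_sdlog > 0,
            zero_prob >= 0, zero_prob < 1,
            beta >= 0, beta < 1, K > 0,
            all(names(organ_iqr) == names(organ_median)))
  structure(list(n = as.integer(n), tlv_median = tlv_median,
                 tlv_sdlog = tlv_sdlog, zero_prob = zero_prob,
                 lesion_suv_median = lesion_suv_median,
                 lesion_suv_sdlog = lesion_suv_sdlog,
                 organ_median = organ_median, organ_iqr = organ_iqr,
                 beta = beta, K = K,
                 weight_mean = weight_mean, weight_sd = weight_sd,
                 weight_range = weight_range,
                 act_per_kg_mean = act_per_kg_mean,
                 act_per_kg_sd = act_per_kg_sd,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# lognormal sdlog from a target median/IQR: median * 2*sinh(z75*s) = IQR
.sdlog_from_iqr <- function(median, iqr) {
  asinh(iqr / (2 * median)) / stats::qnorm(0.75)
}

#' Generate a synthetic cohort (image-free fast path)
#'
#' Draws per-patient tumour burden, lesion uptake, body weight and injected
#' activity, applies the tumour-sink coupling to the organ baselines, and
#' returns the per-patient cohort table together with the generating truth
#' (latent burden, suppression factors, parameters).  No images are
#' rasterized; [generate_patient()] materializes full phantoms when the
#' image pipeline itself is under test.
#'
#' @param cfg A [cohort_config()].
#' @return Data frame (one row per patient: `patient_id`, per-organ SUVmean,
#'   `tlv`, `tlu`, `pct_injected`, `tlv_group`, `weight_kg`,
#'   `injected_MBq`) with the truth record in `attr(, "truth")`.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(cfg$seed)
  n <- cfg$n
  has_tumour <- stats::runif(n) >= cfg$zero_prob
  tlv_draw <- stats::rlnorm(n, log(cfg$tlv_median), cfg$tlv_sdlog)
  tlv <- ifelse(has_tumour, tlv_draw, 0)
  lesion_suv <- stats::rlnorm(n, log(cfg$lesion_suv_median),
                              cfg$lesion_suv_sdlog)
  tlu <- tlv * lesion_suv

  weight <- stats::rnorm(n, cfg$weight_mean, cfg$weight_sd)
  weight <- pmin(pmax(weight, cfg$weight_range[1]), cfg$weight_range[2])
  injected <- weight * stats::rnorm(n, cfg$act_per_kg_mean, cfg$act_per_kg_sd)

  suppression <- 1 - cfg$beta * tlu / (tlu + cfg$K)
  organs <- names(cfg$organ_median)
  tab <- data.frame(patient_id = sprintf("P%04d", seq_len(n)))
  eps <- list()
  for (o in organs) {
    s <- .sdlog_from_iqr(cfg$organ_median[[o]], cfg$organ_iqr[[o]])
    eps[[o]] <- stats::rlnorm(n, 0, s)
    tab[[o]] <- cfg$organ_median[[o]] * suppression * eps[[o]]
  }
  tab$tlv <- tlv
  tab$tlu <- tlu
  tab$pct_injected <- 100 * tlu / (weight * 1000)
  tab$tlv_group <- stratify_tlv(tlv)
  tab$weight_kg <- weight
  tab$injected_MBq <- injected

  attr(tab, "truth") <- list(beta = cfg$beta, K = cfg$K,
                             suppression = suppression,
                             lesion_suv = lesion_suv, eps = eps,
                             seed = cfg$seed, config = cfg)
  tab
}
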