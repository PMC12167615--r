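#' Organ-at-risk region
#'
#' Binds an organ name, its binary mask and the measurement-sphere diameter
#' used for that organ (30 mm for the liver, 15 mm for kidneys, parotid
#' glands and spleen), plus the edge-exclusion margin (5 mm by default).
#' Paired organs (kidneys, parotid glands) are represented by one pooled
#' mask; see [place_and_measure()] for per-component placement.
#'
#' @param name One of `"kidneys"`, `"liver"`, `"parotids"`, `"spleen"` (other
#'   names are allowed for fixtures; they default to a 15 mm sphere).
#' @param mask Logical (or 0/1) 3D array, non-empty.
#' @param diameter_mm Measurement-sphere diameter; defaults by organ.
#' @param edge_margin_mm Minimum distance between any part of the sphere and
#'   the organ edge, in mm.
#' @return An object of class `organ_region`.
#' @export
organ_region <- function(name, mask, diameter_mm = NULL, edge_margin_mm = 5) {
  if (is.null(diameter_mm))
    diameter_mm <- if (identical(name, "liver")) 30 else 15
  if (!is.array(mask)) stop("mask must be a 3D array")
  mask <- .check_mask(mask, dim(mask))
  if (!any(mask)) stop("empty organ mask")
  if (edge_margin_mm < 0) stop("'edge_margin_mm' must be >= 0")
  structure(list(name = name, mask = mask,
                 measurement_sphere = sphere_spec(diameter_mm, "measurement"),
                 edge_margin = edge_margin_mm),
            class = "organ_region")
}

#' Candidate sphere centers respecting the edge margin
#'
#' A mask voxel is a valid center when no part of the measurement sphere
#' comes within `edge_margin` mm of the organ edge, i.e. when the distance
#' from the voxel center to the nearest background voxel center (voxels
#' outside the image grid count as background) is at least
#' `radius + margin`.  Implemented as erosion of the mask by the open ball
#' of that radius, which is exactly the distance-transform threshold on
#' voxel centers.
#'
#' @param organ An [organ_region()].
#' @param spacing Voxel spacing in mm.
#' @param edge_margin_mm Override of the region's margin (e.g. 0 to disable).
#' @return Integer matrix of candidate voxel indices (one `(i,j,k)` row per
#'   candidate). Errors with "organ too small for measurement sphere" when
#'   no voxel qualifies.
#' @export
valid_candidates <- function(organ, spacing,
                             edge_margin_mm = organ$edge_margin) {
  stopifnot(inherits(organ, "organ_region"))
  thr <- organ$measurement_sphere$diameter / 2 + edge_margin_mm
  off <- .ball_offsets(thr, spacing, strict = TRUE)
  # cheap prefilter: erosion by the axis-aligned cross inscribed in the open
  # ball keeps a superset of the true candidates
  pre <- organ$mask
  for (ax in 1:3) {
    k <- max(0L, ceiling(thr / spacing[ax]) - 1L)  # offsets with |o|*d < thr
    pre <- pre & .erode_axis(organ$mask, k, ax)
  }
  centers <- which(pre, arr.ind = TRUE)
  n <- nrow(centers)
  ok <- logical(n)
  if (n > 0L) {
    chunk <- max(1L, floor(4e6 / nrow(off)))
    for (s in seq(1L, n, by = chunk)) {
      e <- min(n, s + chunk - 1L)
      lin <- .neighbor_lin(dim(organ$mask), centers[s:e, , drop = FALSE], off)
      inmask <- matrix(organ$mask[lin], nrow = e - s + 1L)  # NA off-grid
      ok[s:e] <- rowSums(!inmask | is.na(inmask)) == 0L
    }
  }
  if (!any(ok)) stop("organ too small for measurement sphere")
  centers[ok, , drop = FALSE]
}

# erosion of a logical array by a centered segment of half-length k voxels
# along one axis; out-of-grid counts as background
.erode_axis <- function(mask, k, ax) {
  if (k <= 0L) return(mask)
  d <- dim(mask)
  n <- d[ax]
  out <- mask
  idx <- function(a, take) {
    if (ax == 1L) a[take, , , drop = FALSE]
    else if (ax == 2L) a[, take, , drop = FALSE]
    else a[, , take, drop = FALSE]
  }
  asn <- function(a, take, v) {
    if (ax == 1L) a[take, , ] <- v
    else if (ax == 2L) a[, take, ] <- v
    else a[, , take] <- v
    a
  }
  for (step in seq_len(k)) {
    prev <- out
    out <- asn(out, 1:(n - 1), idx(prev, 1:(n - 1)) & idx(prev, 2:n))
    out <- asn(out, 2:n, idx(out, 2:n) & idx(prev, 1:(n - 1)))
    out <- asn(out, c(1L, n), FALSE)
  }
  out
}

#' Score candidate centers by max + SD of SUVpeak in the sphere
#'
#' For each candidate, the measurement sphere is centered there and the
#' maximum plus the population standard deviation of the SUVpeak values it
#' covers is computed.  Only SUVpeak values defined on the organ mask
#' contribute (the peak map is `NA` elsewhere); a candidate whose sphere
#' covers no in-mask voxel is dropped with a warning.
#'
#' @param peaks A `peak_map` from [suv_peak_map()].
#' @param candidates Integer matrix of voxel indices from [valid_candidates()].
#' @param sphere A [sphere_spec()] measurement sphere.
#' @param spacing Voxel spacing in mm.
#' @return List with `centers` (matrix) and `scores` (numeric vector).
#' @export
score_candidates <- function(peaks, candidates, sphere, spacing) {
  stopifnot(inherits(peaks, "peak_map"), nrow(candidates) >= 1L)
  off <- sphere_offsets(sphere$diameter, spacing)
  n <- nrow(candidates)
  scores <- numeric(n)
  valid <- logical(n)
  chunk <- max(1L, floor(4e6 / nrow(off)))
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    lin <- .neighbor_lin(dim(peaks$values), candidates[s:e, , drop = FALSE], off)
    v <- matrix(peaks$values[lin], nrow = e - s + 1L)
    cnt <- rowSums(!is.na(v))
    mx <- apply(v, 1L, max, na.rm = TRUE)
    mu <- rowSums(v, na.rm = TRUE) / cnt
    sdv <- sqrt(rowSums((v - mu)^2, na.rm = TRUE) / cnt)
    scores[s:e] <- mx + sdv
    valid[s:e] <- cnt > 0L
  }
  if (!all(valid)) {
    warning(sprintf("%d candidate(s) covered no in-mask SUVpeak voxel; excluded",
                    sum(!valid)))
    candidates <- candidates[valid, , drop = FALSE]
    scores <- scores[valid]
  }
  list(centers = candidates, scores = scores)
}

#' Select the candidate whose score is closest to the median score
#'
#' Computes the median of all candidate scores (mean of the two central
#' values for an even count) and returns the candidate minimizing
#' `|score - median|`.  Ties are broken deterministically by the smallest
#' `(z, y, x)`-lexicographic voxel index; candidates whose distances agree
#' within a 1e-9 relative tolerance count as tied, so the selection is
#' stable under reordering of floating-point sums (for an even candidate
#' count the two central candidates are equidistant from the median up to
#' rounding, making an exact comparison platform-dependent).
#'
#' @param scores Numeric vector of candidate scores.
#' @param centers Integer matrix of candidate voxel indices, same order.
#' @return List `index` (length-3 voxel index), `score`, `median_score`.
#' @export
select_center <- function(scores, centers) {
  if (length(scores) == 0L) stop("no candidate scores")
  stopifnot(nrow(centers) == length(scores))
  med <- stats::median(scores)
  d <- abs(scores - med)
  tol <- 1e-9 * max(1, abs(med))
  tie <- which(d <= min(d) + tol)
  tie <- tie[order(centers[tie, 3], centers[tie, 2], centers[tie, 1])]
  i <- tie[1L]
  list(index = as.integer(centers[i, ]), score = scores[i], median_score = med)
}

#' Place the measurement sphere in an organ and measure SUVmean
#'
#' Runs the full automated placement: (1) SUVpeak map over the organ mask;
#' (2) candidate filtering by the edge margin and scoring of each candidate
#' by max + SD of SUVpeak within the measurement sphere; (3) median of the
#' scores; (4) center chosen as the candidate with score closest to the
#' median.  SUVmean is then measured on the SUV volume (not the peak map)
#' over the measurement sphere at the chosen center.  The median-targeting
#' rule avoids both metastasis-adjacent hot spots (extreme scores) and edge
#' effects, and is fully deterministic for fixed inputs.
#'
#' Paired organs can be measured per connected component
#' (`per_component = TRUE`): one sphere is placed in every component and the
#' reported SUVmean is the average; by default the pooled mask receives a
#' single sphere.
#'
#' Placements whose sphere maximum exceeds `hot_mult` times the organ's
#' median SUV are flagged (`flagged_hot`), replacing a manual check for
#' tumour inclusion in high-burden patients.
#'
#' @param vol A [pet_volume()] in SUV units.
#' @param organ An [organ_region()] on the same grid.
#' @param per_component Place one sphere per connected component and average.
#' @param hot_mult Multiple of the organ median SUV above which the sphere
#'   maximum triggers the `flagged_hot` report flag.
#' @return An object of class `placement_result`: `organ`, `suv_mean`,
#'   `center` (voxel index), `center_world_mm`, `score`, `median_score`,
#'   `n_candidates`, `sphere_max`, `flagged_hot`; with `per_component`, the
#'   per-component results in `$components` and `suv_mean` their average.
#' @export
place_and_measure <- function(vol, organ, per_component = FALSE,
                              hot_mult = 2) {
  stopifnot(inherits(vol, "pet_volume"), inherits(organ, "organ_region"))
  if (vol$kind != "suv") stop("placement requires an SUV volume")
  .check_mask(organ$mask, dim(vol$values))
  if (per_component) {
    lab <- label_components(organ$mask)
    ks <- seq_len(max(lab))
    comps <- lapply(ks, function(k) {
      sub <- organ_region(organ$name, lab == k,
                          diameter_mm = organ$measurement_sphere$diameter,
                          edge_margin_mm = organ$edge_margin)
      place_and_measure(vol, sub, per_component = FALSE, hot_mult = hot_mult)
    })
    out <- comps[[1L]]
    out$suv_mean <- mean(vapply(comps, `[[`, numeric(1), "suv_mean"))
    out$components <- comps
    out$n_candidates <- sum(vapply(comps, `[[`, numeric(1), "n_candidates"))
    return(out)
  }
  pm <- suv_peak_map(vol, organ$mask)
  cand <- valid_candidates(organ, vol$spacing)
  sc <- score_candidates(pm, cand, organ$measurement_sphere, vol$spacing)
  sel <- select_center(sc$scores, sc$centers)

  # post-hoc invariant: the chosen center honors the edge margin
  d_edge <- edge_distance_mm(organ$mask, vol$spacing,
                             matrix(sel$index, nrow = 1L))
  thr <- organ$measurement_sphere$diameter / 2 + organ$edge_margin
  if (d_edge < thr)
    stop("internal error: chosen center violates the edge margin")

  off <- sphere_offsets(organ$measurement_sphere$diameter, vol$spacing)
  lin <- .neighbor_lin(dim(vol$values), matrix(sel$index, nrow = 1L), off)
  v <- vol$values[as.vector(lin)]
  v <- v[!is.na(v)]
  med_organ <- stats::median(vol$values[organ$mask])
  structure(list(organ = organ$name,
                 suv_mean = mean(v),
                 center = sel$index,
                 center_world_mm = .voxel_world(sel$index, vol),
                 score = sel$score,
                 median_score = sel$median_score,
                 n_candidates = length(sc$scores),
                 sphere_max = max(v),
                 edge_distance_mm = d_edge,
                 flagged_hot = max(v) > hot_mult * med_organ),
            class = "placement_result")
}

#' @export
print.placement_result <- function(x, ...) {
  cat(sprintf("VOI placement in %s: SUVmean = %.4g\n", x$organ, x$suv_mean))
  cat(sprintf("  center voxel (%d,%d,%d), world (%.1f, %.1f, %.1f) mm\n",
              x$center[1], x$center[2], x$center[3],
              x$center_world_mm[1], x$center_world_mm[2], x$center_world_mm[3]))
  cat(sprintf("  score %.4g (median %.4g) over %d candidates%s\n",
              x$score, x$median_score, x$n_candidates,
              if (isTRUE(x$flagged_hot)) " [FLAGGED: hot sphere]" else ""))
  invisible(x)
}

.voxel_world <- function(index, vol) {
  if (is.null(vol$affine)) {
    (as.numeric(index) - 0.5) * vol$spacing
  } else {
    as.numeric(vol$affine %*% c(as.numeric(index) - 1, 1))[1:3]
  }
}

#' Exact distance from voxel centers to the organ edge
#'
#' Brute-force Euclidean distance (world mm) from the given foreground
#' voxel centers to the nearest background voxel center; voxels outside the
#' image grid count as background.  Used for post-hoc verification of the
#' edge-margin rule.
#'
#' @param mask Logical 3D array.
#' @param spacing Voxel spacing in mm.
#' @param centers Integer matrix of voxel indices (rows).
#' @return Numeric vector of distances in mm.
#' @export
edge_distance_mm <- function(mask, spacing, centers) {
  dim3 <- dim(mask)
  bg <- which(!mask, arr.ind = TRUE)
  out <- numeric(nrow(centers))
  for (q in seq_len(nrow(centers))) {
    c0 <- as.numeric(centers[q, ])
    # nearest out-of-grid voxel center along each face
    d_face <- min(c0 * spacing, (dim3 + 1 - c0) * spacing)
    if (nrow(bg) > 0L) {
      d2 <- (spacing[1] * (bg[, 1] - c0[1]))^2 +
        (spacing[2] * (bg[, 2] - c0[2]))^2 +
        (spacing[3] * (bg[, 3] - c0[3]))^2
      out[q] <- min(d_face, sqrt(min(d2)))
    } else out[q] <- d_face
  }
  out
}

#' Label 6-connected components of a binary mask
#'
#' @param mask Logical 3D array.
#' @return Integer array of the same shape: 0 background, 1..K components.
#' @export
label_components <- function(mask) {
  dim3 <- dim(mask)
  lab <- array(0L, dim3)
  todo <- which(mask)
  nxy <- dim3[1] * dim3[2]
  cur <- 0L
  for (s in todo) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    lab[s] <- cur
    frontier <- s
    while (length(frontier)) {
      ai <- arrayInd(frontier, dim3)
      nb <- rbind(ai + rep(c(1L, 0L, 0L), each = nrow(ai)),
                  ai - rep(c(1L, 0L, 0L), each = nrow(ai)),
                  ai + rep(c(0L, 1L, 0L), each = nrow(ai)),
                  ai - rep(c(0L, 1L, 0L), each = nrow(ai)),
                  ai + rep(c(0L, 0L, 1L), each = nrow(ai)),
                  ai - rep(c(0L, 0L, 1L), each = nrow(ai)))
      inb <- nb[, 1] >= 1L & nb[, 1] <= dim3[1] &
        nb[, 2] >= 1L & nb[, 2] <= dim3[2] &
        nb[, 3] >= 1L & nb[, 3] <= dim3[3]
      nb <- nb[inb, , drop = FALSE]
      lin <- unique(nb[, 1] + (nb[, 2] - 1L) * dim3[1] + (nb[, 3] - 1L) * nxy)
      lin <- lin[mask[lin] & lab[lin] == 0L]
      lab[lin] <- cur
      frontier <- lin
    }
  }
  lab
}
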