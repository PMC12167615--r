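#' Diameter of the 1 cm3 SUVpeak sphere
#'
#' The SUVpeak kernel is a sphere of volume exactly 1 cm3, i.e. diameter
#' `2 * (3/(4*pi) * 1000)^(1/3)` mm (about 12.407 mm).
#'
#' @return Diameter in mm.
#' @export
peak_sphere_diameter <- function() 2 * (3 / (4 * pi) * 1000)^(1 / 3)

#' Sphere specification
#'
#' @param diameter_mm Sphere diameter in mm, positive.
#' @param purpose `"peak_kernel"` for the 1 cm3 SUVpeak kernel or
#'   `"measurement"` for an organ measurement sphere (30 mm liver,
#'   15 mm kidneys/parotids/spleen).
#' @return An object of class `sphere_spec`.
#' @export
sphere_spec <- function(diameter_mm, purpose = c("measurement", "peak_kernel")) {
  purpose <- match.arg(purpose)
  if (!is.numeric(diameter_mm) || diameter_mm <= 0)
    stop("'diameter_mm' must be positive")
  structure(list(diameter = diameter_mm, purpose = purpose),
            class = "sphere_spec")
}

# Integer voxel offsets whose voxel-center displacement lies in a ball of
# the given radius.  `strict` uses `<` instead of `<=` on the radius: the
# edge-exclusion rule needs "no background voxel closer than r + margin",
# i.e. the open ball.
.ball_offsets <- function(radius, spacing, strict = FALSE) {
  nmax <- floor(radius / spacing)
  g <- expand.grid(i = -nmax[1]:nmax[1],
                   j = -nmax[2]:nmax[2],
                   k = -nmax[3]:nmax[3])
  d2 <- (g$i * spacing[1])^2 + (g$j * spacing[2])^2 + (g$k * spacing[3])^2
  keep <- if (strict) d2 < radius^2 else d2 <= radius^2
  m <- as.matrix(g[keep, , drop = FALSE])
  storage.mode(m) <- "integer"
  dimnames(m) <- NULL
  m
}

#' Discretize a sphere as voxel offsets
#'
#' Returns the set of integer voxel offsets whose voxel-center world
#' displacement from the sphere center has Euclidean norm at most
#' `diameter/2` (voxel-center membership rule).  The set is symmetric under
#' negation and always contains `(0,0,0)`.
#'
#' @param diameter Sphere diameter in mm.
#' @param spacing Voxel spacing in mm, length 3.
#' @return Integer matrix with one `(di, dj, dk)` offset per row.
#' @export
sphere_offsets <- function(diameter, spacing) {
  if (!is.numeric(diameter) || diameter <= 0) stop("'diameter' must be positive")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("'spacing' must be three positive numbers")
  .ball_offsets(diameter / 2, spacing, strict = FALSE)
}

# Linear indices of centers + offsets; NA where the neighbor falls outside
# the grid.  centers: n x 3 integer matrix; offsets: m x 3.  Returns n x m.
.neighbor_lin <- function(dim3, centers, offsets) {
  ii <- outer(centers[, 1], offsets[, 1], "+")
  jj <- outer(centers[, 2], offsets[, 2], "+")
  kk <- outer(centers[, 3], offsets[, 3], "+")
  ok <- ii >= 1L & ii <= dim3[1] & jj >= 1L & jj <= dim3[2] &
    kk >= 1L & kk <= dim3[3]
  lin <- ii + (jj - 1L) * dim3[1] + (kk - 1L) * (dim3[1] * dim3[2])
  lin[!ok] <- NA_integer_
  lin
}

#' SUVpeak map over an organ mask
#'
#' For every voxel of the mask, the mean SUV over the 1 cm3 spherical
#' neighborhood centered at that voxel (voxel-center membership).  Kernel
#' voxels falling outside the image grid are excluded from the mean; the
#' kernel is *not* restricted to the mask, matching the local-peak
#' convention in which SUVpeak samples the image, not the segmentation.
#'
#' @param vol A [pet_volume()] in SUV units.
#' @param mask Logical 3D array on the same grid; must be non-empty.
#' @return An object of class `peak_map`: list with `values` (3D array,
#'   `NA` outside the mask) and `mask`.
#' @export
suv_peak_map <- function(vol, mask) {
  stopifnot(inherits(vol, "pet_volume"))
  if (vol$kind != "suv") stop("SUVpeak requires an SUV volume; call to_suv() first")
  mask <- .check_mask(mask, dim(vol$values))
  if (!any(mask)) stop("empty organ mask")
  off <- sphere_offsets(peak_sphere_diameter(), vol$spacing)
  centers <- which(mask, arr.ind = TRUE)
  vals <- array(NA_real_, dim(mask))
  n <- nrow(centers)
  chunk <- max(1L, floor(4e6 / nrow(off)))
  means <- numeric(n)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    lin <- .neighbor_lin(dim(mask), centers[s:e, , drop = FALSE], off)
    v <- matrix(vol$values[lin], nrow = e - s + 1L)
    means[s:e] <- rowMeans(v, na.rm = TRUE)
  }
  vals[mask] <- means
  structure(list(values = vals, mask = mask), class = "peak_map")
}

#' Statistics of a field over a sphere
#'
#' Mean, maximum and population standard deviation (divide by N) of a
#' scalar field over a sphere centered at a voxel.  The sphere must lie
#' fully inside the grid.
#'
#' @param field Numeric 3D array.
#' @param center Integer length-3 voxel index.
#' @param sphere A [sphere_spec()] (its diameter is used).
#' @param spacing Voxel spacing in mm.
#' @return Named list `mean`, `max`, `sd`, `n` (voxel count).
#' @export
sphere_stats <- function(field, center, sphere, spacing) {
  stopifnot(is.array(field), length(dim(field)) == 3L)
  diam <- if (inherits(sphere, "sphere_spec")) sphere$diameter else sphere
  off <- sphere_offsets(diam, spacing)
  lin <- .neighbor_lin(dim(field), matrix(as.integer(center), nrow = 1L), off)
  if (anyNA(lin)) stop("sphere exits the image grid")
  v <- field[as.vector(lin)]
  m <- mean(v)
  list(mean = m, max = max(v), sd = sqrt(mean((v - m)^2)), n = length(v))
}

.check_mask <- function(mask, dim3) {
  if (is.array(mask) && !is.logical(mask)) {
    if (!all(mask %in% c(0, 1))) stop("mask values must be 0/1")
    mask <- array(mask != 0, dim(mask))
  }
  if (!is.array(mask) || !is.logical(mask))
    stop("mask must be a logical (or 0/1) 3D array")
  if (!identical(dim(mask), as.integer(dim3)) &&
      !identical(as.integer(dim(mask)), as.integer(dim3)))
    stop("mask and volume grids differ")
  mask
}
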