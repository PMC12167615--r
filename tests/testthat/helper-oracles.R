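# Independent brute-force oracles, deliberately written as straightforward
# enumerations separate from the package internals.

# all integer offsets in the bounding box whose center displacement is <= r
oracle_offsets <- function(diameter, spacing) {
  r <- diameter / 2
  lim <- ceiling(r / spacing) + 1L
  out <- NULL
  for (i in -lim[1]:lim[1]) for (j in -lim[2]:lim[2]) for (k in -lim[3]:lim[3]) {
    d2 <- (i * spacing[1])^2 + (j * spacing[2])^2 + (k * spacing[3])^2
    if (d2 <= r^2) out <- rbind(out, c(i, j, k))
  }
  out
}

# per-voxel mean over the 1 cm3 kernel, neighbors outside the grid dropped;
# computed by shift-and-accumulate over the whole grid (a different algorithm
# from the package's per-voxel neighbor gather)
oracle_peak_map <- function(values, mask, spacing) {
  dm <- dim(values)
  off <- oracle_offsets(2 * (3 / (4 * pi) * 1000)^(1 / 3), spacing)
  acc <- array(0, dm)
  cnt <- array(0, dm)
  for (t in seq_len(nrow(off))) {
    o <- off[t, ]
    xs <- max(1, 1 - o[1]):min(dm[1], dm[1] - o[1])
    ys <- max(1, 1 - o[2]):min(dm[2], dm[2] - o[2])
    zs <- max(1, 1 - o[3]):min(dm[3], dm[3] - o[3])
    acc[xs, ys, zs] <- acc[xs, ys, zs] +
      values[xs + o[1], ys + o[2], zs + o[3]]
    cnt[xs, ys, zs] <- cnt[xs, ys, zs] + 1
  }
  pm <- acc / cnt
  pm[!mask] <- NA_real_
  pm
}

# min squared distance (mm) from each query voxel center to any background
# voxel center; out-of-grid voxels count as background
oracle_min_bg_dist2 <- function(mask, spacing, queries) {
  dm <- dim(mask)
  bg <- which(!mask, arr.ind = TRUE)
  out <- numeric(nrow(queries))
  for (q in seq_len(nrow(queries))) {
    c0 <- queries[q, ]
    best <- min((c0 * spacing)^2, ((dm + 1 - c0) * spacing)^2)
    if (nrow(bg) > 0) {
      d2 <- (spacing[1] * (bg[, 1] - c0[1]))^2 +
        (spacing[2] * (bg[, 2] - c0[2]))^2 +
        (spacing[3] * (bg[, 3] - c0[3]))^2
      best <- min(best, min(d2))
    }
    out[q] <- best
  }
  out
}

# monolithic reference implementation of the four placement steps
oracle_placement <- function(suv_values, mask, spacing, diameter, margin = 5) {
  dm <- dim(suv_values)
  pm <- oracle_peak_map(suv_values, mask, spacing)
  fg <- which(mask, arr.ind = TRUE)
  thr2 <- (diameter / 2 + margin)^2
  d2 <- oracle_min_bg_dist2(mask, spacing, fg)
  cand <- fg[d2 >= thr2, , drop = FALSE]
  if (nrow(cand) == 0) stop("no candidates")
  off <- oracle_offsets(diameter, spacing)
  scores <- numeric(nrow(cand))
  for (q in seq_len(nrow(cand))) {
    acc <- c()
    for (t in seq_len(nrow(off))) {
      p <- cand[q, ] + off[t, ]
      if (all(p >= 1) && all(p <= dm)) {
        v <- pm[p[1], p[2], p[3]]
        if (!is.na(v)) acc <- c(acc, v)
      }
    }
    mu <- sum(acc) / length(acc)
    scores[q] <- max(acc) + sqrt(sum((acc - mu)^2) / length(acc))
  }
  srt <- sort(scores)
  n <- length(srt)
  med <- if (n %% 2 == 1) srt[(n + 1) / 2] else (srt[n / 2] + srt[n / 2 + 1]) / 2
  dd <- abs(scores - med)
  tie <- which(dd <= min(dd) + 1e-9 * max(1, abs(med)))
  tie <- tie[order(cand[tie, 3], cand[tie, 2], cand[tie, 1])]
  ctr <- cand[tie[1], ]
  acc <- c()
  for (t in seq_len(nrow(off))) {
    p <- ctr + off[t, ]
    if (all(p >= 1) && all(p <= dm))
      acc <- c(acc, suv_values[p[1], p[2], p[3]])
  }
  list(center = as.integer(ctr), suv_mean = sum(acc) / length(acc),
       median_score = med, n_candidates = nrow(cand))
}

# average ranks by explicit sorting, then the Pearson formula
oracle_spearman_rho <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) r[i] <- mean(which(sort(v) == v[i]))
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  out <- NULL
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), n - 1)))
  }
  out
}

oracle_perm_p <- function(x, y) {
  obs <- abs(oracle_spearman_rho(x, y))
  pm <- all_perms(length(y))
  stat <- apply(pm, 1, function(p) abs(oracle_spearman_rho(x, y[p])))
  mean(stat >= obs - 1e-12)
}

# single-ellipsoid phantom on a small grid: baseline SUV plus optional
# Gaussian voxel noise, with a deterministic seed
make_test_organ <- function(seed, grid = c(32L, 32L, 32L), spacing = c(2, 2, 2),
                            semiaxes = c(22, 18, 16), baseline = 11.8,
                            noise_frac = 0.05, background = 0.5) {
  set.seed(seed)
  ctr <- (grid * spacing) / 2 + spacing / 2  # on a voxel center
  x <- (seq_len(grid[1]) - 0.5) * spacing[1]
  y <- (seq_len(grid[2]) - 0.5) * spacing[2]
  z <- (seq_len(grid[3]) - 0.5) * spacing[3]
  qx <- ((x - ctr[1]) / semiaxes[1])^2
  qy <- ((y - ctr[2]) / semiaxes[2])^2
  qz <- ((z - ctr[3]) / semiaxes[3])^2
  mask <- array(outer(outer(qx, qy, "+"), qz, "+") <= 1, grid)
  vals <- array(background, grid)
  vals[mask] <- baseline
  if (noise_frac > 0)
    vals <- vals + rnorm(length(vals), 0, noise_frac * vals)
  list(vol = pet_volume(vals, spacing, kind = "suv"), mask = mask,
       baseline = baseline)
}

default_meta <- function() {
  scan_meta(injected_activity_MBq = 348, injection_time = 0, scan_time = 120,
            weight_kg = 87)
}
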