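test_that("decay correction follows the closed form and is monotone", {
  m0 <- scan_meta(200, 0, 0, 80)
  expect_identical(decay_correct(m0), 200)

  m1 <- scan_meta(200, 0, 109.77, 80)
  expect_equal(decay_correct(m1), 100)

  # 350 MBq, 2 h uptake: frozen from the closed form 350 * 2^(-120/109.77)
  m2 <- scan_meta(350, 0, 120, 80)
  expect_equal(decay_correct(m2), 164.052782096589, tolerance = 1e-12)

  dts <- seq(0, 300, by = 15)
  vals <- vapply(dts, function(dt)
    decay_correct(scan_meta(350, 0, dt, 80)), numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_true(all(vals <= 350))

  expect_error(scan_meta(350, 100, 50, 80), "scan precedes injection")
  expect_error(scan_meta(-1, 0, 10, 80), "positive")
  expect_error(scan_meta(350, 0, 10, 0), "positive")
})

test_that("scan_meta accepts ISO-8601 timestamps", {
  m <- scan_meta(350, "2024-01-01T10:00:00", "2024-01-01T12:00:00", 87)
  expect_equal(m$dt_min, 120)
})

test_that("to_suv matches the SUV definition and is linear", {
  meta <- scan_meta(164.3, 0, 0, 87)  # no decay over zero interval
  sp <- c(2, 2, 2)

  # uniform Ac equal to Ai(kBq)/w(g) gives SUV exactly 1
  ac1 <- 164.3 * 1000 / 87000
  v <- pet_volume(array(ac1, c(4, 4, 4)), sp, "activity")
  expect_equal(to_suv(v, meta)$values, array(1, c(4, 4, 4)))

  # zero activity maps to zero SUV
  v0 <- pet_volume(array(0, c(3, 3, 3)), sp, "activity")
  expect_true(all(to_suv(v0, meta)$values == 0))

  # hand-computed quotient: 18.88 / (164300/87000)
  v2 <- pet_volume(array(18.88, c(2, 2, 2)), sp, "activity")
  expect_equal(to_suv(v2, meta)$values[1], 9.99732197200243, tolerance = 1e-12)

  # linearity
  set.seed(11)
  a <- array(runif(64, 0, 30), c(4, 4, 4))
  s1 <- to_suv(pet_volume(a, sp, "activity"), meta)$values
  s3 <- to_suv(pet_volume(3 * a, sp, "activity"), meta)$values
  expect_equal(s3, 3 * s1, tolerance = 1e-12)

  expect_error(to_suv(to_suv(v2, meta), meta), "already")
})

test_that("from_suv inverts to_suv", {
  meta <- default_meta()
  set.seed(4)
  a <- array(runif(27, 0, 25), c(3, 3, 3))
  suv <- pet_volume(a, c(2, 2, 3), "suv")
  back <- to_suv(from_suv(suv, meta), meta)
  expect_equal(back$values, a, tolerance = 1e-12)
  expect_error(from_suv(back, meta), NA)
  expect_error(from_suv(pet_volume(a, c(2, 2, 3), "activity"), meta), "not in SUV")
})

test_that("sphere_offsets equals exhaustive enumeration and is symmetric", {
  cases <- list(list(d = 12.407009817988, s = c(2, 2, 2)),
                list(d = 15, s = c(2, 2, 2)),
                list(d = 15, s = c(2, 2, 3)),
                list(d = 30, s = c(3, 3, 3)),
                list(d = 7, s = c(1.5, 2, 2.5)))
  for (cs in cases) {
    off <- sphere_offsets(cs$d, cs$s)
    orc <- oracle_offsets(cs$d, cs$s)
    key <- function(m) sort(paste(m[, 1], m[, 2], m[, 3]))
    expect_identical(key(off), key(orc))
    # symmetric under negation
    expect_identical(key(off), key(-off))
  }
  # smaller than the voxel: only the center
  expect_identical(sphere_offsets(1.5, c(2, 2, 2)),
                   matrix(0L, 1, 3))
})

test_that("1 cm3 kernel volume converges to 1 cm3 within the boundary shell", {
  # the voxelized sphere can differ from the continuous one only by voxels
  # whose center lies within half a voxel diagonal of the surface
  d <- peak_sphere_diameter()
  r <- d / 2
  for (s in list(c(1, 1, 1), c(2, 2, 2), c(2, 2, 3), c(3, 3, 3), c(1.5, 2, 2))) {
    vox <- prod(s) / 1000
    off <- sphere_offsets(d, s)
    vol <- nrow(off) * vox
    half_diag <- sqrt(sum(s^2)) / 2
    lim <- ceiling((r + half_diag) / s)
    g <- as.matrix(expand.grid(-lim[1]:lim[1], -lim[2]:lim[2], -lim[3]:lim[3]))
    dist <- sqrt((g[, 1] * s[1])^2 + (g[, 2] * s[2])^2 + (g[, 3] * s[3])^2)
    shell <- sum(abs(dist - r) <= half_diag) * vox
    expect_lt(abs(vol - 1), shell + 1e-12)
  }
  # and the discretization is accurate at fine spacing
  fine <- nrow(sphere_offsets(d, c(0.5, 0.5, 0.5))) * 0.125 / 1000
  expect_lt(abs(fine - 1), 0.01)
})

test_that("suv_peak_map equals the brute-force kernel mean", {
  # constant field: peak map is the constant on the mask
  org <- make_test_organ(1, noise_frac = 0, background = 11.8)
  pm <- suv_peak_map(org$vol, org$mask)
  expect_equal(unname(pm$values[org$mask]),
               rep(11.8, sum(org$mask)))

  # single hot voxel on zero background: peak = V / kernel size
  sp <- c(2, 2, 2)
  a <- array(0, c(16, 16, 16))
  a[8, 8, 8] <- 100
  mask <- array(TRUE, c(16, 16, 16))
  pm2 <- suv_peak_map(pet_volume(a, sp, "suv"), mask)
  n_kernel <- nrow(oracle_offsets(peak_sphere_diameter(), sp))
  expect_equal(pm2$values[8, 8, 8], 100 / n_kernel, tolerance = 1e-12)

  # linear ramp: interior peak equals the center value (kernel symmetry)
  ramp <- array(rep(seq_len(16), each = 1), c(16, 16, 16))
  ramp <- aperm(ramp, c(1, 2, 3)) * 1.0
  pm3 <- suv_peak_map(pet_volume(ramp, sp, "suv"), mask)
  expect_equal(pm3$values[8, 9, 7], ramp[8, 9, 7], tolerance = 1e-10)

  # random field on an irregular mask: exact match with the oracle
  set.seed(21)
  b <- array(runif(20^3, 0, 20), c(20, 20, 20))
  msk <- array(FALSE, c(20, 20, 20))
  msk[4:17, 6:15, 3:18] <- TRUE
  msk[10:12, 10:12, 10:12] <- FALSE  # hole
  got <- suv_peak_map(pet_volume(b, sp, "suv"), msk)
  want <- oracle_peak_map(b, msk, sp)
  expect_equal(got$values[msk], want[msk], tolerance = 1e-10)

  expect_error(suv_peak_map(pet_volume(b, sp, "suv"),
                            array(FALSE, c(20, 20, 20))), "empty organ mask")
})

test_that("sphere_stats matches direct enumeration and its order property", {
  sp <- c(2, 2, 2)
  # constant field
  a <- array(7, c(11, 11, 11))
  st <- sphere_stats(a, c(6, 6, 6), sphere_spec(10), sp)
  expect_equal(st$mean, 7)
  expect_equal(st$max, 7)
  expect_equal(st$sd, 0)

  # two-valued toy field: direct enumeration over the kernel
  a2 <- array(1, c(11, 11, 11))
  a2[6, 6, 6] <- 9; a2[7, 6, 6] <- 9; a2[6, 5, 6] <- 9
  off <- oracle_offsets(10, sp)
  vals <- apply(off, 1, function(o) a2[6 + o[1], 6 + o[2], 6 + o[3]])
  st2 <- sphere_stats(a2, c(6, 6, 6), sphere_spec(10), sp)
  expect_equal(st2$mean, mean(vals), tolerance = 1e-12)
  expect_equal(st2$max, max(vals))
  expect_equal(st2$sd, sqrt(mean((vals - mean(vals))^2)), tolerance = 1e-12)
  expect_lte(st2$mean, st2$max)

  # sphere leaving the grid is an error
  expect_error(sphere_stats(a, c(1, 6, 6), sphere_spec(10), sp), "exits")
})
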