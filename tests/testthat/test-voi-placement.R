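test_that("valid_candidates matches the brute-force distance rule", {
  sp <- c(2, 2, 2)
  # cubic mask, 40 mm on a side, 15 mm sphere + 5 mm margin
  mask <- array(FALSE, c(32, 32, 32))
  mask[7:26, 7:26, 7:26] <- TRUE
  reg <- organ_region("spleen", mask)
  cand <- valid_candidates(reg, sp)
  fg <- which(mask, arr.ind = TRUE)
  d2 <- oracle_min_bg_dist2(mask, sp, fg)
  want <- fg[d2 >= (7.5 + 5)^2, , drop = FALSE]
  key <- function(m) sort(paste(m[, 1], m[, 2], m[, 3]))
  expect_identical(key(cand), key(want))
  expect_gt(nrow(cand), 0)

  # ellipsoidal mask
  org <- make_test_organ(3, noise_frac = 0)
  reg2 <- organ_region("kidneys", org$mask)
  cand2 <- valid_candidates(reg2, sp)
  fg2 <- which(org$mask, arr.ind = TRUE)
  d2b <- oracle_min_bg_dist2(org$mask, sp, fg2)
  want2 <- fg2[d2b >= (7.5 + 5)^2, , drop = FALSE]
  expect_identical(key(cand2), key(want2))
})

test_that("a 24 mm spherical organ cannot host a 15 mm sphere", {
  sp <- c(2, 2, 2)
  x <- (seq_len(24) - 0.5) * 2
  q <- outer(outer((x - 25)^2, (x - 25)^2, "+"), (x - 25)^2, "+")
  mask <- array(q <= 12^2, c(24, 24, 24))
  expect_gt(sum(mask), 0)
  reg <- organ_region("kidneys", mask)
  expect_error(valid_candidates(reg, sp), "organ too small")
})

test_that("shrinking the margin enlarges the candidate set", {
  org <- make_test_organ(5, noise_frac = 0)
  reg <- organ_region("spleen", org$mask)
  c5 <- valid_candidates(reg, c(2, 2, 2), edge_margin_mm = 5)
  c0 <- valid_candidates(reg, c(2, 2, 2), edge_margin_mm = 0)
  expect_gt(nrow(c0), nrow(c5))
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  expect_true(all(key(c5) %in% key(c0)))
})

test_that("score_candidates matches hand enumeration", {
  sp <- c(2, 2, 2)
  org <- make_test_organ(7, noise_frac = 0.1)
  pm <- suv_peak_map(org$vol, org$mask)
  reg <- organ_region("spleen", org$mask)
  cand <- valid_candidates(reg, sp)
  sc <- score_candidates(pm, cand, reg$measurement_sphere, sp)

  # constant peak map: every score equals the constant
  pmc <- pm
  pmc$values[org$mask] <- 4.2
  scc <- score_candidates(pmc, cand, reg$measurement_sphere, sp)
  expect_equal(unname(scc$scores), rep(4.2, nrow(cand)), tolerance = 1e-12)

  # direct enumeration on a handful of candidates
  off <- oracle_offsets(15, sp)
  for (q in c(1L, nrow(cand) %/% 2L, nrow(cand))) {
    acc <- c()
    for (t in seq_len(nrow(off))) {
      p <- cand[q, ] + off[t, ]
      if (all(p >= 1) && all(p <= dim(pm$values))) {
        v <- pm$values[p[1], p[2], p[3]]
        if (!is.na(v)) acc <- c(acc, v)
      }
    }
    mu <- mean(acc)
    expect_equal(sc$scores[q], max(acc) + sqrt(mean((acc - mu)^2)),
                 tolerance = 1e-10)
  }

  # inserting a hot voxel never decreases a score whose sphere covers it
  hot <- pm
  ctr <- cand[1, ]
  hot$values[ctr[1], ctr[2], ctr[3]] <- max(pm$values, na.rm = TRUE) * 10
  sc_hot <- score_candidates(hot, cand, reg$measurement_sphere, sp)
  covers <- vapply(seq_len(nrow(cand)), function(q) {
    d2 <- sum(((cand[q, ] - ctr) * sp)^2)
    d2 <= 7.5^2
  }, logical(1))
  expect_true(all(sc_hot$scores[covers] >= sc$scores[covers] - 1e-12))
})

test_that("select_center targets the median with a deterministic tie-break", {
  ctr3 <- rbind(c(1, 1, 1), c(2, 1, 1), c(3, 1, 1))
  sel <- select_center(c(1, 2, 3), ctr3)
  expect_equal(sel$median_score, 2)
  expect_identical(sel$index, c(2L, 1L, 1L))

  # even count, both candidates equidistant from the median: smallest
  # (z, y, x) lexicographic index wins
  ctr2 <- rbind(c(5, 5, 9), c(2, 2, 3))
  sel2 <- select_center(c(1, 3), ctr2)
  expect_equal(sel2$median_score, 2)
  expect_identical(sel2$index, c(2L, 2L, 3L))

  # 100 random scores against a sort-based reference
  set.seed(13)
  sco <- runif(100)
  ctr <- cbind(sample(1:20, 100, TRUE), sample(1:20, 100, TRUE),
               sample(1:20, 100, TRUE))
  sel3 <- select_center(sco, ctr)
  srt <- sort(sco)
  med <- (srt[50] + srt[51]) / 2
  dd <- abs(sco - med)
  near <- which(dd <= min(dd) + 1e-9)
  near <- near[order(ctr[near, 3], ctr[near, 2], ctr[near, 1])]
  expect_identical(sel3$index, as.integer(ctr[near[1], ]))
  expect_equal(sel3$score, sco[near[1]])
  expect_equal(sel3$median_score, med)
})

test_that("place_and_measure returns the exact constant on a uniform organ", {
  org <- make_test_organ(2, noise_frac = 0, baseline = 11.8)
  reg <- organ_region("liver", org$mask, diameter_mm = 15)
  res <- place_and_measure(org$vol, reg)
  expect_equal(res$suv_mean, 11.8, tolerance = 1e-12)
  expect_gte(res$n_candidates, 1)
})

test_that("placement is shift-invariant up to the chosen voxel", {
  org <- make_test_organ(9, noise_frac = 0.08)
  reg <- organ_region("spleen", org$mask)
  r1 <- place_and_measure(org$vol, reg)
  shifted <- pet_volume(org$vol$values + 5, org$vol$spacing, "suv")
  r2 <- place_and_measure(shifted, reg)
  expect_identical(r1$center, r2$center)
  expect_equal(r2$suv_mean, r1$suv_mean + 5, tolerance = 1e-9)
  expect_equal(r2$median_score, r1$median_score + 5, tolerance = 1e-9)
})

test_that("placement is reproducible bit-for-bit for fixed inputs", {
  org <- make_test_organ(17, noise_frac = 0.05)
  reg <- organ_region("kidneys", org$mask)
  r1 <- place_and_measure(org$vol, reg)
  r2 <- place_and_measure(org$vol, reg)
  expect_identical(r1$center, r2$center)
  expect_identical(r1$suv_mean, r2$suv_mean)
})

test_that("per-component placement averages the paired-organ components", {
  sp <- c(2, 2, 2)
  vals <- array(0.5, c(48, 48, 24))
  mask <- array(FALSE, c(48, 48, 24))
  x <- (seq_len(48) - 0.5) * 2; z <- (seq_len(24) - 0.5) * 2
  q1 <- outer(outer((x - 29)^2, (x - 29)^2, "+"), (z - 25)^2, "+")
  q2 <- outer(outer((x - 67)^2, (x - 67)^2, "+"), (z - 25)^2, "+")
  mask[q1 <= 15^2] <- TRUE
  mask[q2 <= 15^2] <- TRUE
  vals[array(q1 <= 15^2, dim(mask))] <- 10
  vals[array(q2 <= 15^2, dim(mask))] <- 20
  vol <- pet_volume(vals, sp, "suv")
  reg <- organ_region("kidneys", mask)
  pooled <- place_and_measure(vol, reg)
  split <- place_and_measure(vol, reg, per_component = TRUE)
  expect_length(split$components, 2)
  expect_equal(split$suv_mean, 15, tolerance = 1e-9)
  # pooled places a single sphere, so it sits in one of the two components
  expect_true(abs(pooled$suv_mean - 10) < 1e-6 ||
                abs(pooled$suv_mean - 20) < 1e-6)
})

test_that("label_components separates disjoint blobs", {
  m <- array(FALSE, c(10, 10, 10))
  m[2:4, 2:4, 2:4] <- TRUE
  m[7:9, 7:9, 7:9] <- TRUE
  lab <- label_components(m)
  expect_equal(max(lab), 2)
  expect_equal(sum(lab > 0), sum(m))
  expect_equal(length(unique(lab[m])), 2)
})
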