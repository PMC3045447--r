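test_that("valley threshold separates well-separated Gaussian modes", {
  set.seed(1)
  v <- c(rnorm(50000, 0.2, 0.05), rnorm(50000, 0.8, 0.05))
  dim(v) <- c(100, 100, 10)
  res <- valley_threshold(v)
  expect_gte(res$threshold, 0.4)
  expect_lte(res$threshold, 0.6)
  # valley lies strictly between the two detected peaks
  expect_gt(res$threshold, min(res$histogram$peaks))
  expect_lt(res$threshold, max(res$histogram$peaks))
  # smoothing approximately preserves the histogram mass
  h <- res$histogram
  expect_rel_equal(sum(h$smoothed), sum(h$counts), 0.02)
})

test_that("a two-valued image is split exactly at the generating partition", {
  set.seed(2)
  v <- array(sample(c(0, 1), 8000, replace = TRUE), dim = c(20, 20, 20))
  res <- valley_threshold(v, clip_quantiles = c(0, 1))
  expect_gt(res$threshold, 0)
  expect_lt(res$threshold, 1)
  expect_identical((v >= res$threshold), (v == 1))

  # Otsu fallback reproduces the same partition
  thr <- otsu_threshold(v)
  expect_gt(thr, 0); expect_lt(thr, 1)
  expect_identical((v >= thr), (v == 1))
})

test_that("Otsu criterion matches the brute-force between-class-variance scan", {
  set.seed(3)
  v <- c(rnorm(4000, 0.3, 0.08), rnorm(2000, 0.75, 0.05))
  thr <- otsu_threshold(v, n_bins = 128)
  # independent exhaustive scan over candidate thresholds
  cand <- seq(min(v), max(v), length.out = 512)
  bcv <- vapply(cand, function(t) {
    a <- v[v < t]; b <- v[v >= t]
    if (length(a) == 0 || length(b) == 0) return(-Inf)
    length(a) * length(b) * (mean(a) - mean(b))^2
  }, numeric(1))
  best <- cand[which.max(bcv)]
  expect_lt(abs(thr - best), diff(range(v)) / 64)
})

test_that("Otsu criterion agrees with an independent implementation", {
  skip_if_not_installed("EBImage")
  set.seed(4)
  v <- c(rnorm(5000, 0.3, 0.06), rnorm(5000, 0.7, 0.06))
  v <- pmin(pmax(v, 0), 1)
  thr <- otsu_threshold(v, n_bins = 256)
  img <- EBImage::Image(array(v, dim = c(100, 100)))
  ref <- EBImage::otsu(img, range = c(0, 1), levels = 256)
  expect_lt(abs(thr - ref), 2 / 256)
})

test_that("unimodal histograms fall back to Otsu or fail when disabled", {
  set.seed(5)
  v <- array(rnorm(8000, 0.5, 0.02), dim = c(20, 20, 20))
  expect_message(res <- valley_threshold(v), "Otsu")
  expect_true(is.finite(res$threshold))
  expect_error(valley_threshold(v, fallback_otsu = FALSE), "fallback")
})

test_that("zeroing below threshold rescales survivors onto [0, 1]", {
  v <- array(0.1, dim = c(10, 10, 4))
  v[3:6, 3:6, 2:3] <- 0.8
  out <- zero_below_and_rescale(v, 0.5)
  expect_equal(sort(unique(as.numeric(out))), c(0, 1))
  expect_equal(out[4, 4, 2], 1)
  expect_equal(out[1, 1, 1], 0)
  # background variability is removed entirely below threshold
  expect_lt(sd(out[v < 0.5]), sd(v[v < 0.5]) + 1e-12)

  # threshold at the minimum: pure affine rescale, nothing zeroed
  set.seed(6)
  v2 <- array(runif(1000, 2, 5), dim = c(10, 10, 10))
  out2 <- zero_below_and_rescale(v2, min(v2))
  expect_equal(range(out2), c(0, 1))
  expect_equal(out2, (v2 - min(v2)) / diff(range(v2)))
  expect_error(zero_below_and_rescale(v2, 10), "below the threshold")
})

test_that("bone thresholding hits the planted ribs in the absorption limit", {
  # contact-plane (z = 0) acquisition: gray values are attenuation
  # densities, so bone is cleanly above tissue
  cs <- contact_study()
  ct <- cs$ct
  tab <- build_material_table(18)
  lam <- energy_to_wavelength(18) * 1e-4
  mu_t <- 4 * pi / lam * tab$beta[tab$material == "soft_tissue"]
  mu_b <- 4 * pi / lam * tab$beta[tab$material == "bone"]
  seg <- segment_bone(ct, (mu_t + mu_b) / 2)
  gt <- phantom_mask(cs$phantom, "bone", pitch_um = ct$pitch_um,
                     dims = dim(ct$data))
  expect_gte(dice_coefficient(seg$labels > 0, gt), 0.9)

  # threshold above the maximum: empty mask, warning not error
  expect_warning(e <- segment_bone(ct, max(ct$data) * 2), "empty")
  expect_equal(sum(e$labels), 0)
  # threshold at the minimum: full mask
  f <- segment_bone(ct, min(ct$data))
  expect_equal(sum(f$labels > 0), length(ct$data))
})

test_that("airway segmentation recovers the air spaces of the phantom", {
  # absorption limit: a threshold between the air and tissue gray levels
  # recovers the air spaces voxel for voxel
  cs <- contact_study()
  lam <- energy_to_wavelength(18) * 1e-4
  mu_t <- 4 * pi / lam *
    build_material_table(18)$beta[2]
  aw0 <- segment_airways(cs$ct, mu_t / 2)
  gt0 <- phantom_mask(cs$phantom, "air", pitch_um = cs$ct$pitch_um,
                      dims = dim(cs$ct$data))
  expect_gte(dice_coefficient(aw0$labels > 0, gt0), 0.85)

  # phase-contrast study: fringe halos widen the mask (undershoot bands
  # below the valley), but it still covers the true air spaces
  run <- small_run()
  gt_air <- phantom_mask(run$phantom, "air", pitch_um = run$ct$pitch_um,
                         dims = dim(run$ct$data))
  aw <- run$airways$labels > 0
  expect_gte(sum(aw & gt_air) / sum(gt_air), 0.85)
  # an all-tissue volume has no airways at an air-level threshold
  solid <- array(1, dim = c(16, 16, 16))
  expect_error(segment_airways(solid, 0.5), "raise")
})

test_that("region growing equals exhaustive flood fill and is monotone", {
  run <- small_run()
  v <- run$ct_smoothed$data
  thr <- run$valley$threshold
  # crop around the trachea
  root <- run$phantom$branches[1, ]
  ctr <- round(c(root$x0, root$y0, (root$z0 + root$z1) / 2) /
                 run$ct$pitch_um)
  lo <- pmax(ctr - 20, 1); hi <- pmin(ctr + 20, dim(v))
  crop <- v[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  seed_vox <- ctr - lo + 1
  grown <- region_grow_3d(crop, seed_vox, thr, connectivity = 26)

  # oracle: exhaustive BFS flood fill in plain R on the thresholded mask
  lab <- r_flood_fill(crop <= thr, seed_vox)
  expect_identical(grown$labels > 0, lab)

  # soundness: every grown voxel satisfies the predicate
  expect_true(all(crop[grown$labels > 0] <= thr))
  # monotonicity: relaxing the threshold never shrinks the region
  grown2 <- region_grow_3d(crop, seed_vox, thr * 1.5 + 1e-5)
  expect_true(all(grown2$labels[grown$labels > 0] > 0))
  # seed failing the predicate is rejected by name
  expect_error(region_grow_3d(crop, seed_vox, min(crop) - 1),
               "seed voxel value")
})

test_that("segmentations are idempotent", {
  run <- small_run()
  a1 <- segment_airways(run$ct_smoothed, run$valley$threshold)
  a2 <- segment_airways(run$ct_smoothed, run$valley$threshold)
  expect_identical(a1$labels, a2$labels)
})
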