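test_that("connected-component labelling honours connectivity", {
  m <- array(FALSE, dim = c(8, 8, 8))
  m[1:2, 1:2, 1:2] <- TRUE
  m[5:6, 5:6, 5:6] <- TRUE
  expect_equal(max(label_components(m, 26)$labels), 2)

  # diagonal touch: one component at 26, two at 6
  d <- array(FALSE, dim = c(4, 4, 4))
  d[2, 2, 2] <- TRUE; d[3, 3, 3] <- TRUE
  expect_equal(max(label_components(d, 26)$labels), 1)
  expect_equal(max(label_components(d, 6)$labels), 2)

  # ids ordered by minimum linear voxel index
  lab <- label_components(m, 26)$labels
  expect_equal(lab[1, 1, 1], 1L)
  expect_equal(lab[5, 5, 5], 2L)
})

test_that("equivalent diameter follows the volume-sphere closed form", {
  expect_equal(equivalent_diameter(1, 4), (6 * 64 / pi)^(1 / 3),
               tolerance = 1e-12)
  # voxelized 130 um sphere at 4 um pitch: within one voxel
  mask <- sphere_mask(130, 4)
  expect_lt(abs(equivalent_diameter(mask, 4) - 130), 4)
  # pitch rescaling is exact
  expect_equal(equivalent_diameter(100, 8), 2 * equivalent_diameter(100, 4))
  expect_error(equivalent_diameter(0, 4), "empty")
})

test_that("Feret diameters of spheres, rods and single voxels", {
  mask <- sphere_mask(130, 4)
  f <- feret_diameters(mask, 4)
  expect_lt(abs(f$d_max_um - 130), 8)
  expect_lt(abs(f$d_min_um - 130), 8)
  expect_lt(abs(f$d_max_um / f$d_min_um - 1), 0.1)

  rod <- array(FALSE, dim = c(5, 5, 14))
  rod[3, 3, 3:12] <- TRUE
  fr <- feret_diameters(rod, 4)
  expect_lt(abs(fr$d_max_um - 40), 4)
  expect_lt(abs(fr$d_min_um - 4), 4 + 1e-9)

  single <- array(FALSE, dim = c(3, 3, 3)); single[2, 2, 2] <- TRUE
  fs <- feret_diameters(single, 4)
  expect_equal(fs$d_max_um, 4)
  expect_equal(fs$d_min_um, 4)
})

test_that("mesh surface area converges to the analytic sphere area", {
  # r = 65 um at 2 um pitch: within 3%
  m2 <- sphere_mask(130, 2)
  a2 <- surface_area(m2, 2)
  expect_rel_equal(a2, 4 * pi * 65^2, 0.03)
  # halving the pitch shrinks the relative error
  errs <- vapply(c(16, 8, 4), function(p) {
    abs(surface_area(sphere_mask(130, p), p) / (4 * pi * 65^2) - 1)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.01)

  # voxel-face fallback is exact on an axis-aligned cube
  cube <- array(FALSE, dim = c(12, 12, 12))
  cube[3:10, 3:10, 3:10] <- TRUE       # side 8 voxels = 32 um
  expect_equal(surface_area(cube, 4, method = "voxel"), 6 * 32^2)
  # degenerate single voxel falls back with a warning
  single <- array(FALSE, dim = c(3, 3, 3)); single[2, 2, 2] <- TRUE
  expect_warning(a1 <- surface_area(single, 4), "voxel-face")
  expect_equal(a1, 6 * 16)
})

test_that("isoperimetric inequality holds for measured components", {
  for (d_um in c(90, 130)) {
    mask <- sphere_mask(d_um, 4)
    a <- surface_area(mask, 4)
    v <- sum(mask) * 4^3
    expect_gte(a, (36 * pi * v^2)^(1 / 3) * 0.98)
  }
})

test_that("measured stats are rotation-robust", {
  mask <- sphere_mask(110, 4, margin_vox = 6)
  lab <- label_components(mask, 26, pitch_um = 4)
  s0 <- measure_all(lab)
  # 90-degree rotation about each axis is a relabelling of voxel axes
  rots <- list(function(m) aperm(m, c(2, 1, 3)),
               function(m) aperm(m, c(1, 3, 2)),
               function(m) aperm(m, c(3, 2, 1)))
  for (rot in rots) {
    sr <- measure_all(label_components(rot(mask), 26, pitch_um = 4))
    for (col in c("eq_diam_um", "dmax_um", "dmin_um", "surface_area_um2")) {
      expect_rel_equal(sr[[col]], s0[[col]], 0.01)
    }
  }
})

test_that("measure_all yields one sane record per labelled component", {
  m <- array(FALSE, dim = c(24, 24, 24))
  m[3:8, 3:8, 3:8] <- TRUE
  m[14:21, 12:19, 10:17] <- TRUE
  lab <- label_components(m, 26, pitch_um = 4)
  st <- measure_all(lab)
  expect_s3_class(st, "alveolus_stats")
  expect_equal(nrow(st), 2)
  expect_equal(st$id, c(1, 2))
  expect_true(all(st$ratio >= 1))
  expect_true(all(st$dmin_um <= st$eq_diam_um + 1e-9))
  expect_true(all(st$eq_diam_um <= st$dmax_um + 1e-9))
  # centroids in world um
  expect_equal(st$cx_um[1], mean((3:8 - 0.5) * 4))

  empty <- label_components(array(FALSE, dim = c(4, 4, 4)), 26, pitch_um = 4)
  st0 <- measure_all(empty)
  expect_equal(nrow(st0), 0)
})

test_that("solid-component selection drops shell-shaped artefacts", {
  both <- array(FALSE, dim = c(64, 64, 64))
  both[5:20, 5:20, 5:20] <- TRUE                # solid block
  shell <- sphere_mask(60, 2, margin_vox = 2)   # thin spherical shell
  inner <- sphere_mask(54, 2, margin_vox = 3.5)
  sh <- shell & !inner
  off <- 28L
  both[off + seq_len(dim(sh)[1]), off + seq_len(dim(sh)[2]),
       off + seq_len(dim(sh)[3])] <- sh
  lab <- label_components(both, 26, pitch_um = 2)
  expect_equal(max(lab$labels), 2)
  kept <- select_solid_components(lab, core_radius = 2)
  ids <- sort(unique(kept$labels[kept$labels > 0]))
  expect_length(ids, 1)
  # the survivor is the solid block, not the shell
  w <- which(kept$labels == ids, arr.ind = TRUE)
  expect_true(all(w[, 1] >= 5 & w[, 1] <= 20))
})
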