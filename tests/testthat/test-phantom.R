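test_that("airway tree recursion gives 2^d - 1 branches with scaled radii", {
  spec1 <- small_spec()
  spec1$tree$depth <- 1L
  expect_equal(nrow(generate_airway_tree(spec1)), 1)

  spec4 <- phantom_spec(
    extent_um = 1024, pitch_um = 4,
    tree = list(depth = 4, root_radius_um = 300, radius_ratio = 0.7,
                root_length_um = 150, length_ratio = 0.7,
                branch_angle_deg = c(20, 30)),
    cylinder_radius_frac = 0.49, seed = 2
  )
  tree <- generate_airway_tree(spec4)
  expect_equal(nrow(tree), 15)
  term <- tree[tree$terminal, ]
  expect_equal(nrow(term), 8)
  expect_equal(unique(term$radius_um), 300 * 0.7^3, tolerance = 1e-12)
  # connectivity: every non-root branch starts at its parent's end
  for (i in 2:15) {
    p <- tree[tree$id == tree$parent[i], ]
    expect_equal(c(tree$x0[i], tree$y0[i], tree$z0[i]),
                 c(p$x1, p$y1, p$z1))
  }
})

test_that("tree generation is deterministic and respects the volume", {
  t1 <- generate_airway_tree(small_spec())
  t2 <- generate_airway_tree(small_spec())
  expect_identical(t1, t2)
  bad <- small_spec()
  bad$tree$root_length_um <- 5000   # runs out of the cylinder
  expect_error(generate_airway_tree(bad), "generation")
})

test_that("alveoli respect the diameter range and never overlap", {
  spec <- small_spec()
  tree <- generate_airway_tree(spec)
  # degenerate range pins the diameter exactly
  one <- populate_alveoli(tree, 1, c(130, 130), seed = 1, spec = spec)
  expect_equal(one$diameter_um, 130)

  spec20 <- default_phantom_spec(seed = 4)
  ph <- build_phantom(spec20)
  alv <- ph$alveoli
  expect_equal(nrow(alv), 21)
  expect_true(all(alv$diameter_um >= 100 & alv$diameter_um <= 150))
  # brute-force pairwise separation check
  ctr <- as.matrix(alv[, c("cx_um", "cy_um", "cz_um")])
  r <- alv$diameter_um / 2
  for (i in seq_len(nrow(alv) - 1)) {
    for (j in seq(i + 1, nrow(alv))) {
      expect_gt(sqrt(sum((ctr[i, ] - ctr[j, ])^2)), r[i] + r[j])
    }
  }
  # every sphere fully inside the volume
  ext <- spec20$extent_um
  expect_true(all(ctr - r > 0) && all(sweep(ctr, 2, ext) + r < 0))
})

test_that("identical spec and seed give a bit-identical phantom volume", {
  pv1 <- rasterize_phantom(build_phantom(small_spec()))
  pv2 <- rasterize_phantom(build_phantom(small_spec()))
  expect_identical(pv1$labels, pv2$labels)
})

test_that("rasterization recovers analytic volumes", {
  # uniform soft tissue: cylinder flag disabled via an all-tissue mask path
  spec <- small_spec()
  ph <- build_phantom(spec)
  # single air sphere of d = 130 at 4 um pitch: voxel count within 5%
  mask <- sphere_mask(130, 4)
  expect_rel_equal(sum(mask) * 4^3, pi / 6 * 130^3, 0.05)

  # air voxel volume of the full phantom within 5% of the analytic
  # sphere + capsule volumes (pitch far below the smallest radius)
  pv <- rasterize_phantom(ph)
  gt_air <- phantom_mask(ph, "air", pitch_um = 4)
  vol_vox <- sum(gt_air) * 4^3
  br <- ph$branches
  len <- sqrt((br$x1 - br$x0)^2 + (br$y1 - br$y0)^2 + (br$z1 - br$z0)^2)
  vol_caps <- sum(pi * br$radius_um^2 * len + 4 / 3 * pi * br$radius_um^3)
  vol_sph <- sum(pi / 6 * ph$alveoli$diameter_um^3)
  # capsules of parent/child branches overlap at the joints; subtract the
  # child end-sphere once per joint as a first-order correction
  joint <- sum(4 / 3 * pi * br$radius_um[!is.na(br$parent)]^3)
  expect_rel_equal(vol_vox, vol_caps + vol_sph - joint, 0.08)

  # labels are air inside every ground-truth alveolus centre
  for (i in seq_len(nrow(ph$alveoli))) {
    vx <- round(c(ph$alveoli$cx_um[i], ph$alveoli$cy_um[i],
                  ph$alveoli$cz_um[i]) / 4)
    expect_equal(pv$labels[vx[1], vx[2], vx[3]], 0L)
  }
})

test_that("masking the tree leaves exactly the planted alveoli as components", {
  ph <- build_phantom(default_phantom_spec(seed = 2))
  pitch <- 8
  air <- phantom_mask(ph, "air", pitch_um = pitch)
  tree <- phantom_mask(ph, "tree", pitch_um = pitch)
  detached <- air & !tree
  lab <- label_components(detached, connectivity = 26, pitch_um = pitch)
  expect_equal(max(lab$labels), nrow(ph$alveoli))
})

test_that("refractive volumes map labels through the material table", {
  tab <- build_material_table(18)
  lab <- array(c(0L, 1L, 2L, 1L), dim = c(4, 1, 1))
  rv <- refractive_volume(lab, tab, pitch_um = 4)
  expect_equal(rv$delta[2, 1, 1], tab$delta[tab$material == "soft_tissue"])
  expect_equal(rv$beta[3, 1, 1], tab$beta[tab$material == "bone"])
  expect_equal(dim(rv$delta), dim(lab))
})
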