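test_that("iso-surface of a binary sphere is watertight with chi = 2", {
  mask <- sphere_mask(100, 4)
  mesh <- extract_isosurface(array(as.numeric(mask), dim = dim(mask)), 0.5,
                             pitch_um = 4)
  expect_gt(nrow(mesh$faces), 100)
  expect_equal(euler_characteristic(mesh), 2)
  expect_equal(mesh_component_count(mesh), 1)

  # mesh area of an r = 65 um sphere within 3% at 2 um pitch (smoothed
  # component route)
  a <- surface_area(sphere_mask(130, 2), 2)
  expect_rel_equal(a, 4 * pi * 65^2, 0.03)

  # two disjoint spheres give two mesh components
  two <- array(FALSE, dim = c(50, 30, 30))
  s <- sphere_mask(60, 4, margin_vox = 3)
  n <- dim(s)[1]
  two[1:n, 1:n, 1:n] <- s
  two[29 + 1:n, 1:n, 1:n] <- s
  mesh2 <- extract_isosurface(array(as.numeric(two), dim = dim(two)), 0.5,
                              pitch_um = 4)
  expect_equal(mesh_component_count(mesh2), 2)
  expect_equal(euler_characteristic(mesh2), 4)

  # iso level must sit inside the value range
  expect_error(extract_isosurface(array(0, c(4, 4, 4)) + 1, 2, 4), "range")
})

test_that("meshes are deterministic for fixed input", {
  mask <- sphere_mask(80, 4)
  f <- array(as.numeric(mask), dim = dim(mask))
  m1 <- extract_isosurface(f, 0.5, pitch_um = 4)
  m2 <- extract_isosurface(f, 0.5, pitch_um = 4)
  expect_identical(m1$vertices, m2$vertices)
  expect_identical(m1$faces, m2$faces)
})

test_that("mesh export round-trips through STL, PLY and OBJ", {
  # unit cube: 8 vertices, 12 triangles
  v <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
    c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
    c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6)
  )
  cube <- surface_mesh(v, f, name = "cube")
  td <- temp_dir()

  stl <- file.path(td, "cube.stl")
  export_mesh(cube, stl)
  expect_equal(length(grep("facet normal", readLines(stl))), 12)
  back_stl <- read_mesh(stl)
  expect_equal(nrow(back_stl$faces), 12)
  expect_equal(mesh_area(back_stl), mesh_area(cube))

  ply <- file.path(td, "cube.ply")
  export_mesh(cube, ply)
  back <- read_mesh(ply)
  expect_equal(back$vertices, cube$vertices, tolerance = 1e-6)
  expect_equal(back$faces, cube$faces)
  expect_equal(nrow(back$vertices), 8)

  obj <- file.path(td, "cube.obj")
  export_mesh(cube, obj)
  back_obj <- read_mesh(obj)
  expect_equal(back_obj$vertices, cube$vertices, tolerance = 1e-6)
  expect_equal(back_obj$faces, cube$faces)

  empty <- surface_mesh(matrix(numeric(0), ncol = 3),
                        matrix(integer(0), ncol = 3))
  expect_error(export_mesh(empty, file.path(td, "e.stl")), "empty")
})

test_that("plane clipping keeps, splits or empties a mesh", {
  mask <- sphere_mask(120, 2)
  mesh <- xpcilung:::component_mesh(mask, 2)
  ctr <- colMeans(mesh$vertices)
  full <- mesh_area(mesh)

  below <- clip_mesh(mesh, ctr - c(0, 0, 500), c(0, 0, 1))
  expect_equal(nrow(below$faces), 0)
  above <- clip_mesh(mesh, ctr + c(0, 0, 500), c(0, 0, 1))
  expect_equal(mesh_area(above), full)

  half <- clip_mesh(mesh, ctr, c(0, 0, 1))
  expect_rel_equal(mesh_area(half), full / 2, 0.03)
  expect_error(clip_mesh(mesh, ctr, c(0, 0, 0)), "degenerate")
})

test_that("volume TIFF stacks round-trip with sidecar metadata", {
  td <- temp_dir()
  set.seed(8)
  vol <- array(rnorm(16 * 16 * 4), dim = c(16, 16, 4))
  p <- file.path(td, "v.tif")
  write_volume(vol, p, pitch_um = 8, meta = list(stage = "test"))
  r1 <- read_volume(p)
  expect_equal(r1$pitch_um, 8)
  expect_equal(r1$meta$stage, "test")
  # first pass: quantization at 2^-32 of the range
  expect_lt(max(abs(r1$data - vol)), diff(range(vol)) * 2^-30)
  # storage is stable: a second round trip stays on the quantization grid
  p2 <- file.path(td, "v2.tif")
  write_volume(r1$data, p2, pitch_um = 8)
  r2 <- read_volume(p2)
  expect_lt(max(abs(r2$data - r1$data)), diff(range(vol)) * 2^-30)

  # label volumes round-trip exactly
  lab <- label_components(sphere_mask(40, 4), 26, pitch_um = 4)
  pl <- file.path(td, "lab.tif")
  write_volume(lab, pl)
  rl <- read_volume(pl)
  expect_identical(rl$data, lab$labels)
  expect_equal(rl$meta$legend$component_1, 1)

  # a truncated file fails loudly
  writeBin(readBin(p, "raw", 100), file.path(td, "trunc.tif"))
  file.copy(paste0(p, ".json"), file.path(td, "trunc.tif.json"))
  expect_error(read_volume(file.path(td, "trunc.tif")))
})

test_that("projection sets and stats tables round-trip", {
  td <- temp_dir()
  tab <- build_material_table(18)
  rv <- refractive_volume(array(1L, dim = c(16, 16, 8)), tab, pitch_um = 4)
  geom <- beam_geometry(detector_pitch_um = 8, n_angles = 4,
                        flat_photons = 1e4, sim_pitch_um = 2)
  ps <- acquire_ct(rv, geom, seed = 3)
  write_projection_set(ps, file.path(td, "acq"))
  back <- read_projection_set(file.path(td, "acq"))
  expect_equal(back$angles_deg, ps$angles_deg)
  expect_equal(back$geometry$energy_keV, 18)
  # quantization is relative to the stored scale (0 .. brightest pixel)
  expect_lt(max(abs(back$images - ps$images)) /
              max(ps$images, ps$flat), 2^-30)

  st <- measure_all(label_components(sphere_mask(60, 4), 26, pitch_um = 4))
  f <- file.path(td, "stats.csv")
  write_stats_csv(st, f)
  st2 <- read_stats_csv(f)
  expect_equal(st2$eq_diam_um, st$eq_diam_um, tolerance = 1e-9)
})

test_that("configs and manifests round-trip losslessly", {
  td <- temp_dir()
  cfg <- list(
    phantom = list(extent_um = c(512, 512, 512), pitch_um = 4,
                   alveoli = list(count = 5, diameter_range_um = c(80, 110))),
    geometry = list(energy_keV = 18, distance_m = 1.2,
                    detector_pitch_um = 8, n_angles = 120),
    seed = 7
  )
  f <- file.path(td, "cfg.yaml")
  write_config(cfg, f)
  expect_equal(read_config(f), cfg)

  mf <- list(stage = "reconstruct", filter = "ramp", angles = 120)
  g <- file.path(td, "manifest.json")
  write_manifest(mf, g)
  expect_equal(read_manifest(g), mf)
})
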