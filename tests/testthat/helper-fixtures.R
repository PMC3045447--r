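# Shared fixtures. Heavy simulated objects are built once per test run and
# cached in this environment.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# a compact lung phantom: 512 um cube at 4 um pitch (128^3), depth-2 tree,
# 5 alveoli of 80-110 um, 2 ribs
small_spec <- function(seed = 11) {
  phantom_spec(
    extent_um = 512, pitch_um = 4,
    tree = list(depth = 2, root_radius_um = 50, radius_ratio = 0.7,
                root_length_um = 130, length_ratio = 0.8),
    alveoli = list(count = 5, diameter_range_um = c(80, 110), wall_um = 30,
                   jitter_um = 30),
    ribs = list(count = 2, tube_radius_um = 24, ring_radius_frac = 0.33),
    seed = seed
  )
}

small_geometry <- function(n_angles = 120) {
  beam_geometry(detector_pitch_um = 8, n_angles = n_angles,
                flat_photons = 1e4)
}

# the full chain on the compact phantom (about half a minute; reused by the
# segmentation, morphometry and pipeline tests)
small_run <- function() {
  fixture("small_run", function() {
    run_pipeline(small_spec(), small_geometry(), seed = 5)
  })
}

# voxelized sphere mask of diameter d at a given pitch, centred
sphere_mask <- function(diameter_um, pitch_um, margin_vox = 4) {
  r <- diameter_um / 2
  n <- ceiling(diameter_um / pitch_um) + 2 * margin_vox
  ctr <- n / 2 * pitch_um
  ax <- (seq_len(n) - 0.5) * pitch_um - ctr
  r2 <- outer(outer(ax^2, ax^2, `+`), ax^2, `+`)
  r2 <= r^2
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(abs(object / expected - 1), tol)
}

temp_dir <- function() {
  d <- tempfile("xpci")
  dir.create(d)
  d
}

# exhaustive flood fill in plain R (independent oracle for region growing)
r_flood_fill <- function(mask, seed_vox, connectivity = 26) {
  d <- dim(mask)
  lab <- array(FALSE, dim = d)
  queue <- matrix(seed_vox, ncol = 3)
  lab[queue] <- TRUE
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, ]
  while (nrow(queue) > 0) {
    nxt <- list()
    for (r in seq_len(nrow(queue))) {
      cand <- sweep(offs, 2, queue[r, ], `+`)
      ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
        cand[, 2] >= 1 & cand[, 2] <= d[2] &
        cand[, 3] >= 1 & cand[, 3] <= d[3]
      cand <- cand[ok, , drop = FALSE]
      inmask <- mask[cand] & !lab[cand]
      if (any(inmask)) {
        sel <- cand[inmask, , drop = FALSE]
        lab[sel] <- TRUE
        nxt[[length(nxt) + 1]] <- sel
      }
    }
    queue <- if (length(nxt) > 0) unique(do.call(rbind, nxt)) else
      matrix(numeric(0), ncol = 3)
  }
  lab
}

# contact-plane (z = 0) acquisition and reconstruction of the compact
# phantom: gray values are attenuation densities (no fringes), shared by
# the absorption-limit segmentation tests
contact_study <- function() {
  fixture("contact_study", function() {
    ph <- build_phantom(small_spec(seed = 21))
    rv <- refractive_volume(rasterize_phantom(ph), build_material_table(18))
    geom <- beam_geometry(distance_m = 0, detector_pitch_um = 8,
                          n_angles = 180, flat_photons = 0, sim_pitch_um = 4)
    ct <- suppressWarnings(reconstruct_volume(acquire_ct(rv, geom, seed = 1)))
    list(phantom = ph, ct = ct)
  })
}
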