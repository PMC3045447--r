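test_that("wavelength follows the hc product", {
  expect_equal(energy_to_wavelength(18), 0.68880, tolerance = 1e-5)
  expect_equal(energy_to_wavelength(12.39842), 1.00000, tolerance = 1e-5)
  expect_equal(energy_to_wavelength(36), energy_to_wavelength(18) / 2)
  expect_error(energy_to_wavelength(0), "positive")
  # lambda * E = hc to 5 significant figures
  g <- beam_geometry()
  expect_equal(g$wavelength_A * g$energy_keV, 12.3984, tolerance = 1e-4)
})

test_that("paper-default geometry schedules 1296 angles over 180 degrees", {
  g <- beam_geometry()
  a <- projection_angles(g)
  expect_length(a, 1296)
  expect_equal(diff(a)[1], 180 / 1296)
  expect_true(all(a >= 0 & a < 180))
  expect_equal(g$detector_pitch_um, 13)
  expect_equal(g$distance_m, 1.2)
  # simulation pitch resolves a quarter of the first Fresnel zone
  lam_um <- g$wavelength_A * 1e-4
  expect_lte(g$sim_pitch_um, sqrt(lam_um * 1.2e6) / 4 + 1e-9)
  ratio <- g$detector_pitch_um / g$sim_pitch_um
  expect_equal(ratio, round(ratio), tolerance = 1e-9)
})

test_that("line integrals match the analytic slab and cylinder", {
  tab <- build_material_table(18)
  lam <- energy_to_wavelength(18) * 1e-4
  bt <- tab$beta[tab$material == "soft_tissue"]
  dl <- tab$delta[tab$material == "soft_tissue"]
  geom <- beam_geometry(detector_pitch_um = 8, n_angles = 1, sim_pitch_um = 2)

  # all-vacuum volume projects to zero
  rv0 <- refractive_volume(array(0L, dim = c(32, 32, 4)) * 0L,
                           tab, pitch_um = 4)
  rv0$delta[] <- 0; rv0$beta[] <- 0
  m0 <- project_mu_phi(rv0, 45, geom)
  expect_equal(max(abs(m0$mu)), 0)
  expect_equal(max(abs(m0$phi)), 0)

  # uniform slab at normal incidence: mu = 4 pi beta t / lambda,
  # phi = -2 pi delta t / lambda, to 0.1%
  dims <- c(64, 64, 8); pitch <- 4
  rv <- refractive_volume(array(1L, dim = dims), tab, pitch_um = pitch)
  maps <- project_mu_phi(rv, 0, geom)
  t_um <- dims[2] * pitch
  ctr <- nrow(maps$mu) / 2
  expect_rel_equal(maps$mu[ctr, 4], 4 * pi / lam * bt * t_um, 0.001)
  expect_rel_equal(maps$phi[ctr, 4], -2 * pi / lam * dl * t_um, 0.001)
  # mu >= 0 and phi <= 0 everywhere
  expect_true(all(maps$mu >= 0))
  expect_true(all(maps$phi <= 0))

  # tissue cylinder: chord-length profile 2 sqrt(R^2 - s^2) at any angle
  R <- 180
  lab2 <- array(0L, dim = c(128, 128, 8))
  xs <- (seq_len(128) - 0.5) * pitch - 256
  disk <- outer(xs^2, xs^2, `+`) <= R^2
  for (k in 1:8) lab2[, , k] <- disk
  rv2 <- refractive_volume(lab2, tab, pitch_um = pitch)
  for (ang in c(0, 30, 117)) {
    m2 <- project_mu_phi(rv2, ang, geom)
    s <- (seq_len(nrow(m2$mu)) - 0.5 - nrow(m2$mu) / 2) * 2
    chord <- ifelse(abs(s) < R, 2 * sqrt(pmax(R^2 - s^2, 0)), 0)
    sel <- abs(s) < 0.8 * R
    err <- max(abs(m2$mu[sel, 4] - 4 * pi / lam * bt * chord[sel]))
    expect_lt(err / max(4 * pi / lam * bt * chord), 0.02)
  }
})

test_that("doubling delta doubles phi exactly", {
  tab <- build_material_table(18)
  rv <- refractive_volume(array(1L, dim = c(32, 32, 4)), tab, pitch_um = 4)
  geom <- beam_geometry(detector_pitch_um = 8, n_angles = 1, sim_pitch_um = 2)
  m1 <- project_mu_phi(rv, 10, geom)
  rv$delta <- rv$delta * 2
  m2 <- project_mu_phi(rv, 10, geom)
  expect_equal(m2$phi, 2 * m1$phi)
})

test_that("transmission applies Beer-Lambert amplitude and phase", {
  z4 <- matrix(0, 4, 4)
  expect_equal(transmission(phase_maps(z4, z4, 1, 0.6888)),
               matrix(1 + 0i, 4, 4))
  q <- transmission(phase_maps(z4 + 2 * log(2), z4, 1, 0.6888))
  expect_equal(Mod(q[1, 1])^2, 0.25)
  q2 <- transmission(phase_maps(z4, z4 - pi, 1, 0.6888))
  expect_equal(q2[1, 1], -1 + 0i)
  expect_equal(Mod(q2[2, 2])^2, 1)   # pure phase object: unit intensity
})

test_that("free-space propagation is unitary with plane-wave eigenfunctions", {
  n <- 96
  wf <- matrix(1 + 0i, n, n)
  I <- propagate_angular_spectrum(wf, 0.6888, 1.2, 4)
  expect_equal(range(I), c(1, 1), tolerance = 1e-9)

  # z = 0 is the identity on intensity
  set.seed(7)
  wf2 <- matrix(complex(modulus = runif(n * n, 0.5, 1),
                        argument = runif(n * n, -1, 0)), n, n)
  expect_equal(propagate_angular_spectrum(wf2, 0.6888, 0, 4), Mod(wf2)^2)

  # energy conservation through free space (Parseval), 0.1%
  x <- (seq_len(n) - n / 2) * 4
  bump <- exp(-outer(x^2, x^2, `+`) / (2 * 60^2))
  wf3 <- exp(-1i * 0.8 * bump)
  dim(wf3) <- c(n, n)
  I3 <- propagate_angular_spectrum(wf3, 0.6888, 1.2, 4)
  expect_rel_equal(sum(I3), n * n, 0.001)
})

test_that("aliasing guard names the minimum valid pitch", {
  wf <- matrix(1 + 0i, 16, 16)
  expect_error(propagate_angular_spectrum(wf, 0.6888, 1.2, 1),
               "minimum valid pitch")
})

test_that("phase edge fringes match the analytic knife-edge solution", {
  skip_if_not_installed("pracma")
  lamA <- energy_to_wavelength(18)
  lam <- lamA * 1e-4
  z <- 1.2e6
  n <- 1024; pitch <- 2
  x <- (seq_len(n) - 0.5 - n / 2) * pitch
  phi_step <- -0.5
  field <- matrix(exp(1i * ifelse(x > 0, phi_step, 0)), n, 64)
  prof <- propagate_angular_spectrum(field, lamA, 1.2, pitch)[, 32]
  # closed-form Fresnel-integral knife edge
  ab <- c(1 + 0i, exp(1i * phi_step))
  t0 <- -x * sqrt(2 / (lam * z))
  C <- pracma::fresnelC(t0); S <- pracma::fresnelS(t0)
  U <- (ab[1] * ((C + 0.5) + 1i * (S + 0.5)) +
          ab[2] * ((0.5 - C) + 1i * (0.5 - S))) / sqrt(2i)
  Io <- Mod(U)^2
  sel <- abs(x) < 100
  # first fringe maximum within one sample of the analytic position
  expect_lte(abs(x[sel][which.max(prof[sel])] - x[sel][which.max(Io[sel])]),
             pitch)
  # profile agrees pointwise to a few percent of the fringe amplitude
  amp <- max(Io) - min(Io)
  expect_lt(max(abs(prof[sel] - Io[sel])) / amp, 0.2)
})

test_that("weak-object propagator agrees with the exact propagator", {
  n <- 128
  x <- (seq_len(n) - n / 2) * 2
  g <- exp(-outer(x^2, x^2, `+`) / (2 * 40^2))
  maps <- phase_maps(0.02 * g, -0.3 * g, 2, energy_to_wavelength(18))
  Iw <- propagate_weak_object(maps, 1.2)
  Ie <- propagate_angular_spectrum(transmission(maps),
                                   energy_to_wavelength(18), 1.2, 2)
  contrast <- max(Ie) - min(Ie)
  expect_lt(sqrt(mean((Iw - Ie)^2)) / contrast, 0.01)
  # limiting cases: nothing in the beam; contact plane
  z0 <- matrix(0, n, n)
  expect_equal(propagate_weak_object(phase_maps(z0, z0, 2, 0.6888), 1.2),
               z0 + 1)
  expect_equal(propagate_weak_object(maps, 0), 1 - maps$mu,
               tolerance = 1e-10)
})

test_that("cylinder edges gain an overshoot-undershoot pair only after propagation", {
  tab <- build_material_table(18)
  R <- 120
  lab <- array(0L, dim = c(128, 128, 32))
  xs <- (seq_len(128) - 0.5) * 4 - 256
  disk <- outer(xs^2, xs^2, `+`) <= R^2
  for (k in 1:32) lab[, , k] <- disk
  rv <- refractive_volume(lab, tab, pitch_um = 4)
  geom <- beam_geometry(detector_pitch_um = 8, n_angles = 1, sim_pitch_um = 2)
  maps <- project_mu_phi(rv, 0, geom)
  wf <- transmission(maps)
  I0 <- Mod(wf)^2                    # contact plane
  Iz <- propagate_angular_spectrum(wf, geom$wavelength_A, 1.2,
                                   c(2, 4))
  prof0 <- I0[, 16]; profz <- Iz[, 16]
  s <- (seq_len(nrow(maps$mu)) - 0.5 - nrow(maps$mu) / 2) * 2
  near <- abs(abs(s) - R) < 30
  # at the detector: overshoot above and undershoot below the far field
  expect_gt(max(profz[near]), 1.05)
  expect_lt(min(profz[near]), 0.95)
  # at contact: pure absorption dip, no overshoot above unity
  expect_lt(max(prof0), 1 + 1e-6)
  expect_gt(min(prof0), exp(-4 * pi / (geom$wavelength_A * 1e-4) *
                              build_material_table(18)$beta[2] * 2 * R) - 0.01)
})

test_that("acquisition is deterministic and vacuum reproduces the flat field", {
  tab <- build_material_table(18)
  lab <- array(0L, dim = c(32, 32, 8))
  rv <- refractive_volume(lab, tab, pitch_um = 4)
  rv$delta[] <- 0; rv$beta[] <- 0    # true vacuum
  geom <- beam_geometry(detector_pitch_um = 8, n_angles = 1,
                        flat_photons = 0, sim_pitch_um = 2)
  expect_warning(ps <- acquire_ct(rv, geom, seed = 1), "noise disabled")
  expect_equal(dim(ps$images)[3], 1)
  expect_equal(max(abs(ps$images[, , 1] - ps$flat)), 0, tolerance = 1e-6)

  geom2 <- beam_geometry(detector_pitch_um = 8, n_angles = 3,
                         flat_photons = 1e4, sim_pitch_um = 2)
  a1 <- acquire_ct(rv, geom2, seed = 42)
  a2 <- acquire_ct(rv, geom2, seed = 42)
  expect_identical(a1$images, a2$images)
  expect_identical(a1$flat, a2$flat)
  a3 <- acquire_ct(rv, geom2, seed = 43)
  expect_false(identical(a1$images, a3$images))
})
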