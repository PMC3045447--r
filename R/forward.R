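#' X-ray wavelength from photon energy
#'
#' `lambda = hc / E` with the CODATA hc product 12.398420 keV A.
#'
#' @param energy_keV photon energy in keV (> 0).
#' @return wavelength in Angstrom.
#' @examples
#' energy_to_wavelength(18)  # 0.68880 A
#' @export
energy_to_wavelength <- function(energy_keV) {
  if (any(!is.finite(energy_keV)) || any(energy_keV <= 0)) {
    stop("photon energy must be positive")
  }
  12.39841984 / energy_keV
}

#' Acquisition geometry for in-line phase-contrast CT
#'
#' Collects the beamline parameters of a parallel, monochromatic in-line
#' imaging setup: beam energy, free-space propagation (sample-to-detector)
#' distance, detector pixel pitch, and the projection schedule. Defaults are
#' the synchrotron configuration used for the mouse-lung study: 18 keV,
#' z = 1.2 m, 13 um pixels, 1296 projections over 180 degrees.
#'
#' The simulation pitch is the transverse sampling used for wave
#' propagation; it must resolve the first Fresnel zone, so it defaults to
#' the largest integer fraction of the detector pitch not exceeding
#' `min(detector/2, sqrt(lambda z)/4)`.
#'
#' @param energy_keV beam energy (keV).
#' @param distance_m propagation distance z (m), > 0.
#' @param detector_pitch_um detector pixel pitch (um).
#' @param n_angles number of projections.
#' @param angular_range_deg angular span of the scan; 180 for parallel-beam.
#' @param flat_photons expected photon count per detector pixel in the flat
#'   field (Poisson noise scale); `<= 0` disables noise.
#' @param n_flat_frames flat-field frames averaged into the reference image.
#' @param sim_pitch_um override the simulation pitch (um).
#' @return A `beam_geometry` list with derived `wavelength_A` and
#'   `sim_pitch_um`.
#' @export
beam_geometry <- function(energy_keV = 18, distance_m = 1.2,
                          detector_pitch_um = 13, n_angles = 1296,
                          angular_range_deg = 180, flat_photons = 1e4,
                          n_flat_frames = 128, sim_pitch_um = NULL) {
  if (distance_m < 0) stop("propagation distance must be >= 0")
  lambda_A <- energy_to_wavelength(energy_keV)
  lambda_um <- lambda_A * 1e-4
  z_um <- distance_m * 1e6
  if (is.null(sim_pitch_um)) {
    p_max <- min(detector_pitch_um / 2,
                 if (z_um > 0) sqrt(lambda_um * z_um) / 4 else Inf)
    sim_pitch_um <- detector_pitch_um / ceiling(detector_pitch_um / p_max)
  }
  structure(list(
    energy_keV = energy_keV, wavelength_A = lambda_A,
    distance_m = distance_m, detector_pitch_um = detector_pitch_um,
    n_angles = as.integer(n_angles), angular_range_deg = angular_range_deg,
    flat_photons = flat_photons, n_flat_frames = as.integer(n_flat_frames),
    sim_pitch_um = sim_pitch_um
  ), class = "beam_geometry")
}

#' @export
print.beam_geometry <- function(x, ...) {
  cat(sprintf(paste0("<beam_geometry> %.4g keV (lambda %.5f A), z = %.3g m, ",
                     "%.3g um detector, %d angles over %g deg\n"),
              x$energy_keV, x$wavelength_A, x$distance_m,
              x$detector_pitch_um, x$n_angles, x$angular_range_deg))
  invisible(x)
}

#' Projection angles of a geometry
#'
#' Equally spaced angles starting at 0, spanning `[0, angular_range_deg)`.
#'
#' @param geometry a [beam_geometry()].
#' @return numeric vector of angles in degrees.
#' @export
projection_angles <- function(geometry) {
  geometry$angular_range_deg * (seq_len(geometry$n_angles) - 1) /
    geometry$n_angles
}

#' Attenuation and phase line integrals of one projection
#'
#' For a parallel beam at a given rotation angle, computes the attenuation
#' map `mu = (4 pi / lambda) integral(beta dl)` and phase map
#' `phi = -(2 pi / lambda) integral(delta dl)` (radians; `delta >= 0`
#' retards the phase, so `phi <= 0`). Line integrals use ray-driven
#' midpoint sampling of the in-slice bilinear interpolant; rays are spaced
#' at the simulation pitch transversally and at the volume pitch along the
#' rotation axis.
#'
#' @param rvol a [refractive_volume()].
#' @param angle_deg projection angle in `[0, 180)`.
#' @param geometry a [beam_geometry()].
#' @param n_cols number of transverse samples (defaults to volume extent /
#'   simulation pitch).
#' @return A `phase_maps` list: matrices `mu`, `phi` (columns = slices),
#'   `pitch_um = c(transverse, axial)`, `angle_deg`, `wavelength_A`.
#' @export
project_mu_phi <- function(rvol, angle_deg, geometry, n_cols = NULL) {
  if (!inherits(rvol, "refractive_volume")) {
    stop("rvol must be a refractive_volume")
  }
  dims <- dim(rvol$delta)
  pv <- rvol$pitch_um
  ps <- geometry$sim_pitch_um
  n_cols <- n_cols %||% round(dims[1] * pv / ps)
  s_grid <- (seq_len(n_cols) - 0.5 - n_cols / 2) * ps
  pr <- project_rays_cpp(rvol$delta, rvol$beta, as.integer(dims), pv,
                         angle_deg * pi / 180, s_grid, min(ps, pv))
  lambda_um <- geometry$wavelength_A * 1e-4
  structure(list(
    mu = 4 * pi / lambda_um * pr$b,
    phi = -2 * pi / lambda_um * pr$a,
    pitch_um = c(ps, pv),
    angle_deg = angle_deg,
    wavelength_A = geometry$wavelength_A
  ), class = "phase_maps")
}

#' Phase/attenuation maps from explicit matrices
#'
#' Constructor used for analytic test objects (slabs, Gaussian phase bumps)
#' that never pass through a voxel volume.
#'
#' @param mu attenuation map (dimensionless line integral), `>= 0`.
#' @param phi phase map (radians), `<= 0` under the sign convention that a
#'   positive refractive decrement retards the phase.
#' @param pitch_um sampling pitch (scalar or `c(px, py)`).
#' @param wavelength_A beam wavelength.
#' @param angle_deg optional projection angle tag.
#' @export
phase_maps <- function(mu, phi, pitch_um, wavelength_A, angle_deg = 0) {
  stopifnot(identical(dim(mu), dim(phi)))
  if (any(mu < 0)) stop("attenuation map mu must be >= 0")
  if (any(phi > 1e-12)) stop("phase map phi must be <= 0 (delta retards)")
  if (length(pitch_um) == 1) pitch_um <- rep(pitch_um, 2)
  structure(list(mu = mu, phi = phi, pitch_um = pitch_um,
                 angle_deg = angle_deg, wavelength_A = wavelength_A),
            class = "phase_maps")
}

#' Complex transmission of a thin object
#'
#' The object multiplies a unit incident plane wave by
#' `q = exp(-mu/2 + i phi)`: amplitude `exp(-mu/2)` (Beer-Lambert in
#' intensity) and phase `phi`.
#'
#' @param maps a `phase_maps` object.
#' @return complex matrix (the exit-plane wavefield).
#' @export
transmission <- function(maps) {
  if (!inherits(maps, "phase_maps")) stop("maps must be a phase_maps object")
  q <- exp(complex(real = -maps$mu / 2, imaginary = maps$phi))
  dim(q) <- dim(maps$mu)
  q
}

# edge-replicating pad of a matrix to (n1 + 2*p1) x (n2 + 2*p2)
pad_replicate <- function(x, p1, p2) {
  n1 <- nrow(x); n2 <- ncol(x)
  i <- pmin(pmax(seq_len(n1 + 2 * p1) - p1, 1), n1)
  j <- pmin(pmax(seq_len(n2 + 2 * p2) - p2, 1), n2)
  x[i, j, drop = FALSE]
}

fft_freqs <- function(n, pitch) {
  k <- c(seq(0, floor((n - 1) / 2)), seq(-floor(n / 2), -1))
  k / (n * pitch)
}

#' Free-space propagation by the angular-spectrum method
#'
#' Propagates a sampled complex wavefield over a distance z in vacuum using
#' the exact angular-spectrum transfer function
#' `H(f) = exp(i 2 pi z / lambda (sqrt(1 - lambda^2 f^2) - 1))`
#' (paraxially `exp(-i pi lambda z f^2)`), with 2x edge-replicating padding
#' to suppress wrap-around, and returns the intensity `|U_z|^2` cropped to
#' the input grid. Evanescent components are truncated. Free-space
#' propagation is unitary, so total intensity is conserved.
#'
#' The sampled transfer function aliases when `lambda z > N p^2` (N = padded
#' length); violating pitches are rejected with the minimum valid pitch.
#'
#' @param wavefield complex matrix (exit-plane field).
#' @param wavelength_A wavelength in Angstrom.
#' @param distance_m propagation distance in metres (0 is the identity).
#' @param pitch_um sampling pitch in um (scalar or `c(px, py)`).
#' @return numeric matrix of intensities.
#' @export
propagate_angular_spectrum <- function(wavefield, wavelength_A, distance_m,
                                       pitch_um) {
  if (length(pitch_um) == 1) pitch_um <- rep(pitch_um, 2)
  if (distance_m == 0) return(Mod(wavefield)^2)
  lambda <- wavelength_A * 1e-4
  z <- distance_m * 1e6
  n1 <- nrow(wavefield); n2 <- ncol(wavefield)
  p1 <- ceiling(n1 / 2); p2 <- ceiling(n2 / 2)
  N1 <- n1 + 2 * p1; N2 <- n2 + 2 * p2
  pmin_valid <- sqrt(lambda * z / min(N1, N2))
  if (lambda * z > min(N1 * pitch_um[1]^2, N2 * pitch_um[2]^2)) {
    stop(sprintf(paste0("Fresnel kernel aliased at pitch (%.3g, %.3g) um; ",
                        "minimum valid pitch is about %.3g um at this ",
                        "distance and energy"),
                 pitch_um[1], pitch_um[2], pmin_valid))
  }
  u <- pad_replicate(wavefield, p1, p2)
  fx <- fft_freqs(N1, pitch_um[1])
  fy <- fft_freqs(N2, pitch_um[2])
  f2 <- outer(fx^2, fy^2, `+`)
  arg <- 1 - lambda^2 * f2
  H <- ifelse(arg >= 0,
              exp(2i * pi * z / lambda * (sqrt(pmax(arg, 0)) - 1)),
              0)
  U <- fft(fft(u) * H, inverse = TRUE) / (N1 * N2)
  Mod(U[p1 + seq_len(n1), p2 + seq_len(n2)])^2
}

#' Linearized (weak-object) intensity at the detector
#'
#' Under the weak-object approximation the Fourier transform of the
#' recorded intensity is
#' `F(I)(u,v) = delta(u,v) - M(u,v) + 2 pi lambda z (u^2 + v^2) Phi(u,v)`,
#' with `M`, `Phi` the transforms of the attenuation and phase maps and
#' `(u, v)` in cycles per unit length. The quadratic term converts phase
#' curvature into measurable contrast; at `z = 0` the intensity reduces to
#' the pure absorption image `1 - mu`.
#'
#' Valid for `max(mu) << 1` and slowly varying phase; violating the regime
#' degrades accuracy but not validity.
#'
#' @param maps a `phase_maps` object.
#' @param distance_m propagation distance in metres.
#' @return numeric matrix of intensities.
#' @export
propagate_weak_object <- function(maps, distance_m) {
  if (!inherits(maps, "phase_maps")) stop("maps must be a phase_maps object")
  lambda <- maps$wavelength_A * 1e-4
  z <- distance_m * 1e6
  n1 <- nrow(maps$mu); n2 <- ncol(maps$mu)
  p1 <- ceiling(n1 / 2); p2 <- ceiling(n2 / 2)
  N1 <- n1 + 2 * p1; N2 <- n2 + 2 * p2
  mu <- pad_replicate(maps$mu, p1, p2)
  phi <- pad_replicate(maps$phi, p1, p2)
  f2 <- outer(fft_freqs(N1, maps$pitch_um[1])^2,
              fft_freqs(N2, maps$pitch_um[2])^2, `+`)
  Ihat <- -fft(mu) + 2 * pi * lambda * z * f2 * fft(phi)
  I <- 1 + Re(fft(Ihat, inverse = TRUE)) / (N1 * N2)
  I[p1 + seq_len(n1), p2 + seq_len(n2)]
}

# Fourier (sinc) resampling of a real matrix to new dimensions by spectrum
# truncation / zero-padding; used to bring axial sampling to the isotropic
# simulation pitch before propagation.
fourier_resample <- function(x, new_dim) {
  n <- dim(x)
  if (all(n == new_dim)) return(x)
  X <- fft(x)
  pack <- function(N, M) {
    # index map from old spectrum length N into new length M
    keep <- min(N, M)
    half <- floor((keep - 1) / 2)
    pos <- seq_len(half + 1)                 # DC .. +half
    neg <- if (keep > half + 1) seq(N - (keep - half - 1) + 1, N) else integer(0)
    list(old = c(pos, neg),
         new = c(pos, if (length(neg)) seq(M - length(neg) + 1, M) else integer(0)))
  }
  m1 <- pack(n[1], new_dim[1]); m2 <- pack(n[2], new_dim[2])
  Y <- matrix(0 + 0i, new_dim[1], new_dim[2])
  Y[m1$new, m2$new] <- X[m1$old, m2$old]
  Re(fft(Y, inverse = TRUE)) / prod(n)
}

# area-weighted (block-mean) binning; factors must be integers
bin_block <- function(x, f1, f2) {
  n1 <- nrow(x); n2 <- ncol(x)
  if (n1 %% f1 != 0 || n2 %% f2 != 0) {
    stop("binning factors must divide the image dimensions")
  }
  m1 <- n1 / f1; m2 <- n2 / f2
  dim(x) <- c(f1, m1, f2, m2)
  out <- apply(x, c(2, 4), mean)
  out
}

#' Simulate a phase-contrast CT acquisition
#'
#' For each of N equally spaced angles in `[0, 180)`: project the
#' refractive volume to attenuation/phase maps, form the complex
#' transmission, propagate to the detector plane (exact angular-spectrum
#' propagator by default, or the linearized weak-object propagator),
#' downsample to the detector pitch by area-weighted binning, scale to the
#' flat-field photon count and apply Poisson noise. The flat field is
#' recorded with no object as the average of `n_flat_frames` noisy frames.
#'
#' @param rvol a [refractive_volume()].
#' @param geometry a [beam_geometry()]; the detector pitch must be an
#'   integer multiple of both the simulation pitch and the volume pitch.
#' @param seed RNG seed for the photon noise (identical seeds give
#'   identical noisy stacks).
#' @param propagator `"exact"` (angular spectrum) or `"weak"`.
#' @param verbose print progress.
#' @return A `projection_set`: array `images` (detector x, detector row,
#'   angle) in photon counts, matrix `flat`, `angles_deg`, `geometry`,
#'   `seed`, `propagator`.
#' @export
acquire_ct <- function(rvol, geometry, seed = 1L,
                       propagator = c("exact", "weak"), verbose = FALSE) {
  propagator <- match.arg(propagator)
  dims <- dim(rvol$delta)
  pv <- rvol$pitch_um
  ps <- geometry$sim_pitch_um
  pd <- geometry$detector_pitch_um
  fx <- pd / ps
  if (abs(fx - round(fx)) > 1e-9) {
    stop("detector pitch must be an integer multiple of the simulation pitch")
  }
  fx <- as.integer(round(fx))
  fz <- pd / pv
  if (abs(fz - round(fz)) > 1e-9) {
    stop("detector pitch must be an integer multiple of the volume pitch")
  }
  n_cols <- round(dims[1] * pv / ps / fx) * fx
  n_rows_det <- floor(dims[3] * pv / pd)
  n_rows_sim <- n_rows_det * fx   # rows at isotropic sim pitch
  angles <- projection_angles(geometry)
  photons <- geometry$flat_photons
  noise <- photons > 0
  if (!noise) {
    warning("flat-field photon count <= 0: noise disabled")
    photons <- 1
  }
  images <- array(0, dim = c(n_cols / fx, n_rows_det, length(angles)))
  with_seed(seed, {
    for (ai in seq_along(angles)) {
      maps <- project_mu_phi(rvol, angles[ai], geometry, n_cols = n_cols)
      mu <- fourier_resample(maps$mu, c(n_cols, n_rows_sim))
      phi <- fourier_resample(maps$phi, c(n_cols, n_rows_sim))
      # resampling overshoot can leave slightly negative mu; clamp
      mu[mu < 0] <- 0
      phi[phi > 0] <- 0
      if (propagator == "exact") {
        wf <- exp(complex(real = -mu / 2, imaginary = phi))
        dim(wf) <- dim(mu)
        I <- propagate_angular_spectrum(wf, geometry$wavelength_A,
                                        geometry$distance_m, ps)
      } else {
        m2 <- phase_maps(mu, phi, ps, geometry$wavelength_A, angles[ai])
        I <- propagate_weak_object(m2, geometry$distance_m)
      }
      Idet <- bin_block(I, fx, fx) * photons
      if (noise) Idet[] <- rpois(length(Idet), pmax(Idet, 0))
      images[, , ai] <- Idet
      if (verbose && ai %% 20 == 0) {
        message("projection ", ai, "/", length(angles))
      }
    }
    flat <- matrix(photons, n_cols / fx, n_rows_det)
    if (noise) {
      acc <- matrix(0, n_cols / fx, n_rows_det)
      for (i in seq_len(geometry$n_flat_frames)) {
        acc <- acc + rpois(length(acc), photons)
      }
      flat <- acc / geometry$n_flat_frames
    }
    structure(list(images = images, flat = flat, angles_deg = angles,
                   geometry = geometry, seed = seed, propagator = propagator),
              class = "projection_set")
  })
}

#' @export
print.projection_set <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("<projection_set> %d projections of %d x %d pixels (%s propagator, seed %s)\n",
              d[3], d[1], d[2], x$propagator, format(x$seed)))
  invisible(x)
}
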