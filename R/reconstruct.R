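#' Flat-field normalization of a projection set
#'
#' Divides every projection pixel-wise by the flat-field (no object)
#' reference, removing beam structure; vacuum regions normalize to ~1.
#'
#' @param pset a `projection_set` from [acquire_ct()] (or read from disk).
#' @return numeric array of normalized intensities (same dims as `images`).
#' @export
flat_field_normalize <- function(pset) {
  flat <- pset$flat
  nbad <- sum(flat <= 0)
  if (nbad > 0) {
    stop(nbad, " flat-field pixel(s) are zero or negative; cannot normalize")
  }
  sweep(pset$images, c(1, 2), flat, `/`)
}

#' Convert normalized projections to per-slice sinograms
#'
#' The line-integral (attenuation-convention) sinogram value is
#' `-log(intensity)`; intensities are clamped below at `floor` so photon
#' starvation cannot produce infinities.
#'
#' @param normalized array from [flat_field_normalize()].
#' @param angles_deg projection angles.
#' @param pitch_um detector pitch.
#' @param floor positive clamp applied before the log.
#' @return A `sinogram_stack`: array `(angle, detector column, slice)` with
#'   `angles_deg` and `pitch_um`.
#' @export
to_sinograms <- function(normalized, angles_deg, pitch_um, floor = 1e-6) {
  if (any(!is.finite(normalized))) {
    stop("non-finite intensities in normalized projections")
  }
  if (floor <= 0) {
    if (any(normalized <= 0)) {
      stop("non-positive intensity after clamping floor disabled")
    }
  }
  v <- -log(pmax(normalized, floor))
  # (x, row, angle) -> (angle, x, row)
  s <- aperm(v, c(3, 1, 2))
  structure(list(data = s, angles_deg = angles_deg, pitch_um = pitch_um),
            class = "sinogram_stack")
}

# Discrete Ram-Lak (ramp) filter in the frequency domain, built from the
# band-limited spatial kernel (h(0) = 1/(4 d^2), h(odd n) = -1/(pi n d)^2)
# so the DC response is correct for finite sampling.
ramp_filter_spectrum <- function(npad, pitch, window = c("ramp", "hann")) {
  window <- match.arg(window)
  n <- seq(0, npad - 1)
  nn <- pmin(n, npad - n)  # signed lag magnitude, circular
  h <- numeric(npad)
  h[1] <- 1 / (4 * pitch^2)
  odd <- nn %% 2 == 1
  h[odd] <- -1 / (pi * nn[odd] * pitch)^2
  H <- Re(fft(h))
  if (window == "hann") {
    f <- fft_freqs(npad, pitch)
    fn <- 1 / (2 * pitch)
    H <- H * 0.5 * (1 + cos(pi * f / fn))
  }
  H
}

filter_sinogram_rows <- function(sino, pitch, filter) {
  na <- nrow(sino); ns <- ncol(sino)
  npad <- 2^ceiling(log2(2 * ns))
  H <- ramp_filter_spectrum(npad, pitch, filter)
  out <- matrix(0, na, ns)
  pad <- matrix(0, na, npad)
  pad[, seq_len(ns)] <- sino
  # filter all rows at once: FFT along detector axis
  P <- t(mvfft(t(pad)))
  Q <- t(mvfft(t(P * rep(H, each = na)), inverse = TRUE)) / npad
  out[] <- Re(Q[, seq_len(ns)]) * pitch
  out
}

#' Filtered back projection of one sinogram
#'
#' Standard parallel-beam FBP: each projection row is ramp-filtered in the
#' frequency domain (Ram-Lak, optionally Hann-windowed, cut at Nyquist) and
#' back-projected with linear interpolation, scaled by `pi / n_angles`.
#' The rotation centre is the detector centre.
#'
#' @param sino matrix `(angle, detector column)` of line integrals.
#' @param angles_deg projection angles in `[0, 180)`.
#' @param pitch_um detector pitch; the output pixel pitch.
#' @param filter `"ramp"` or `"hann"`.
#' @return square matrix (side = detector columns) of reconstructed values
#'   (line-integral density per um).
#' @export
fbp_reconstruct <- function(sino, angles_deg, pitch_um,
                            filter = c("ramp", "hann")) {
  filter <- match.arg(filter)
  if (nrow(sino) < 2) stop("fewer than 2 projection angles")
  if (any(angles_deg < 0 | angles_deg >= 180)) {
    stop("angles must span [0, 180)")
  }
  ns <- ncol(sino)
  q <- filter_sinogram_rows(sino, pitch_um, filter)
  s0 <- (0.5 - ns / 2) * pitch_um
  backproject_cpp(q, angles_deg * pi / 180, s0, pitch_um, ns, pitch_um)
}

#' Reconstruct a CT volume from a projection set
#'
#' Flat-field normalizes, forms `-log` sinograms and applies FBP slice by
#' slice. Edge-enhanced fringes in the projections carry through to local
#' over/undershoots at interfaces in the slices.
#'
#' @param pset a `projection_set`.
#' @param filter `"ramp"` or `"hann"`.
#' @param verbose print progress.
#' @return A `ct_volume`: array `data` (x, y, slice), `pitch_um`, `filter`,
#'   `angles_deg`.
#' @export
reconstruct_volume <- function(pset, filter = c("ramp", "hann"),
                               verbose = FALSE) {
  filter <- match.arg(filter)
  norm <- flat_field_normalize(pset)
  sin_stack <- to_sinograms(norm, pset$angles_deg,
                            pset$geometry$detector_pitch_um)
  ns <- dim(sin_stack$data)[2]
  nz <- dim(sin_stack$data)[3]
  vol <- array(0, dim = c(ns, ns, nz))
  for (k in seq_len(nz)) {
    vol[, , k] <- fbp_reconstruct(sin_stack$data[, , k],
                                  sin_stack$angles_deg,
                                  sin_stack$pitch_um, filter)
    if (verbose && k %% 32 == 0) message("slice ", k, "/", nz)
  }
  structure(list(data = vol, pitch_um = pset$geometry$detector_pitch_um,
                 filter = filter, angles_deg = pset$angles_deg),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ct_volume> %d x %d x %d at %.3g um (%s filter), range [%.3g, %.3g]\n",
              d[1], d[2], d[3], x$pitch_um, x$filter,
              min(x$data), max(x$data)))
  invisible(x)
}

#' @describeIn reconstruct_volume display one reconstructed slice in gray
#'   scale.
#' @param x a `ct_volume`.
#' @param slice slice index (default: middle).
#' @param ... passed to [graphics::image()].
#' @export
plot.ct_volume <- function(x, slice = NULL, ...) {
  k <- slice %||% ceiling(dim(x$data)[3] / 2)
  sl <- x$data[, , k]
  graphics::image(
    (seq_len(nrow(sl)) - 0.5) * x$pitch_um,
    (seq_len(ncol(sl)) - 0.5) * x$pitch_um,
    sl, col = grDevices::gray.colors(256), asp = 1,
    xlab = "x (um)", ylab = "y (um)",
    main = sprintf("slice %d (%s filter)", k, x$filter), ...
  )
  invisible(x)
}

#' Box-smooth a CT volume
#'
#' Cubic mean filter of half-width `radius` voxels (edge-aware), the
#' standard denoising step before histogram thresholding of noisy FBP
#' volumes.
#'
#' @param ct a `ct_volume` or numeric array.
#' @param radius half-width in voxels.
#' @return same type as the input.
#' @export
smooth_volume <- function(ct, radius = 1L) {
  if (inherits(ct, "ct_volume")) {
    ct$data <- box_mean3_cpp(ct$data, as.integer(dim(ct$data)),
                             as.integer(radius))
    ct
  } else {
    box_mean3_cpp(ct, as.integer(dim(ct)), as.integer(radius))
  }
}

#' Edge-response width of a reconstructed edge profile
#'
#' Fits the edge-spread function across a high-contrast interface and
#' reports the full width at half maximum of its derivative (the line
#' spread function), plus the 10-90% rise width, both via linear
#' interpolation between samples.
#'
#' @param profile numeric vector crossing one edge (low to high or high to
#'   low).
#' @param pitch_um sample spacing.
#' @return list with `fwhm_um`, `width_10_90_um`.
#' @export
edge_response <- function(profile, pitch_um) {
  n <- length(profile)
  if (n < 5) stop("profile too short")
  if (profile[1] > profile[n]) profile <- rev(profile)
  x <- seq_len(n) * pitch_um
  # resample the ESF on a fine grid so differentiation does not widen the
  # line spread function beyond the data's own sampling
  fine <- stats::spline(x, profile, n = 16 * n)
  lsf <- diff(fine$y) / diff(fine$x)[1]
  xm <- (fine$x[-1] + fine$x[-length(fine$x)]) / 2
  a <- abs(lsf)
  pk <- which.max(a)
  half <- a[pk] / 2
  left <- pk; while (left > 1 && a[left - 1] > half) left <- left - 1
  right <- pk
  while (right < length(a) && a[right + 1] > half) right <- right + 1
  interp_cross <- function(i_out, i_in) {
    if (i_out < 1 || i_out > length(a)) return(xm[i_in])
    xm[i_out] + (half - a[i_out]) / (a[i_in] - a[i_out]) *
      (xm[i_in] - xm[i_out])
  }
  fwhm <- abs(interp_cross(right + 1, right) - interp_cross(left - 1, left))
  # 10-90% rise of the ESF between robust end plateaus
  third <- max(2, floor(n / 3))
  lo_v <- stats::median(profile[seq_len(third)])
  hi_v <- stats::median(profile[seq(n - third + 1, n)])
  v10 <- lo_v + 0.1 * (hi_v - lo_v)
  v90 <- lo_v + 0.9 * (hi_v - lo_v)
  cross <- function(level) {
    idx <- which(diff(sign(fine$y - level)) != 0)
    if (length(idx) == 0) return(NA_real_)
    i <- idx[which.min(abs(idx - pk))]
    fine$x[i] + (level - fine$y[i]) / (fine$y[i + 1] - fine$y[i]) *
      (fine$x[i + 1] - fine$x[i])
  }
  w1090 <- abs(cross(v90) - cross(v10))
  list(fwhm_um = fwhm, width_10_90_um = w1090)
}
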