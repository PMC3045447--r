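#' Default desk-scale phantom and acquisition
#'
#' The default study phantom is a 1.024 mm cube at 4 um pitch (256^3
#' voxels): a soft-tissue body cylinder with a depth-4 airway tree (root
#' radius 80 um) and 21 alveoli drawn uniformly from the 100-150 um
#' immature-mouse diameter range, plus 4 rib arcs. The matched acquisition
#' images it at 18 keV over 1.2 m onto an 8 um detector (2x the phantom
#' pitch) with 240 projections over 180 degrees and 1e4 photons/pixel —
#' a scaled-down field of view chosen so the full pipeline runs in minutes;
#' the full-size beamline geometry remains the [beam_geometry()] default.
#'
#' @param seed phantom seed.
#' @return a [phantom_spec()] / [beam_geometry()].
#' @export
default_phantom_spec <- function(seed = 1L) {
  phantom_spec(extent_um = c(1024, 1024, 1024), pitch_um = 4, seed = seed)
}

#' @rdname default_phantom_spec
#' @param n_angles projections over 180 degrees.
#' @export
default_study_geometry <- function(n_angles = 240) {
  beam_geometry(energy_keV = 18, distance_m = 1.2, detector_pitch_um = 8,
                n_angles = n_angles, flat_photons = 1e4)
}

#' Dice overlap coefficient of two masks
#' @param a,b logical arrays of equal dimension.
#' @return `2|A n B| / (|A| + |B|)`.
#' @export
dice_coefficient <- function(a, b) {
  2 * sum(a & b) / (sum(a) + sum(b))
}

world_to_voxel <- function(p_um, pitch_um) {
  as.integer(pmax(1, round(p_um / pitch_um + 0.5)))
}

#' Run the full simulate - reconstruct - segment - measure pipeline
#'
#' Chains every stage on a phantom with known ground truth:
#' \enumerate{
#'   \item build and rasterize the phantom; populate delta/beta volumes;
#'   \item simulate the phase-contrast CT acquisition ([acquire_ct()]);
#'   \item flat-field normalize and FBP-reconstruct ([reconstruct_volume()]);
#'   \item box-smooth, find the histogram-valley threshold, segment bone and
#'     whole airways, grow the bronchial tree from a seed placed in the
#'     trachea (taken from ground truth), and remove it from the airways;
#'   \item label the remaining air chambers and measure them
#'     ([measure_all()]).
#' }
#'
#' The bone threshold is placed midway between the expected reconstructed
#' attenuation densities of tissue and bone (known from the material
#' table); the airway and region-growing thresholds are the automatic
#' histogram-valley threshold.
#'
#' @param spec a [phantom_spec()].
#' @param geometry a [beam_geometry()].
#' @param seed seed for the acquisition noise.
#' @param propagator `"exact"` or `"weak"`.
#' @param filter FBP filter.
#' @param smooth_radius pre-segmentation box smoothing half-width (voxels).
#' @param min_component_voxels smallest air chamber kept by the measurement
#'   stage (speck rejection).
#' @param out_dir optional output directory (volumes, labels, stats CSV and
#'   run manifest are written there).
#' @param verbose print stage progress.
#' @return an `xpci_run` list with every intermediate product and the
#'   morphometry table `stats`.
#' @export
run_pipeline <- function(spec = default_phantom_spec(),
                         geometry = default_study_geometry(),
                         seed = 1L, propagator = "exact", filter = "hann",
                         smooth_radius = 1L, min_component_voxels = 50L,
                         airway_threshold = NULL, bone_threshold = NULL,
                         clip_quantiles = c(0.02, 0.98),
                         out_dir = NULL, verbose = FALSE) {
  t0 <- Sys.time()
  say <- function(...) if (verbose) message(...)
  say("building phantom")
  phantom <- build_phantom(spec)
  pvol <- rasterize_phantom(phantom)
  tab <- build_material_table(geometry$energy_keV)
  rvol <- refractive_volume(pvol, tab)
  say("simulating ", geometry$n_angles, " projections")
  pset <- acquire_ct(rvol, geometry, seed = seed, propagator = propagator,
                     verbose = verbose)
  say("reconstructing")
  ct <- reconstruct_volume(pset, filter = filter)
  ct_s <- smooth_volume(ct, smooth_radius)
  say("segmenting")
  vt <- valley_threshold(ct_s, clip_quantiles = clip_quantiles)
  air_thr <- airway_threshold %||% vt$threshold
  lambda_um <- geometry$wavelength_A * 1e-4
  mu_lin <- function(m) 4 * pi / lambda_um * tab$beta[tab$material == m]
  bone_thr <- bone_threshold %||% ((mu_lin("soft_tissue") + mu_lin("bone")) / 2)
  bone <- segment_bone(ct_s, bone_thr)
  # background suppression view (tissue on black), as in the study's
  # processed slices; air is below the valley, so airway extraction works
  # on the un-transformed volume
  ct_rescaled <- zero_below_and_rescale(ct_s, vt$threshold)
  airways <- segment_airways(ct_s, air_thr)
  # seed a third of the way up the trachea
  root <- phantom$branches[1, ]
  seed_pt <- c(root$x0, root$y0, root$z0) +
    0.4 * c(root$x1 - root$x0, root$y1 - root$y0, root$z1 - root$z0)
  seed_vox <- world_to_voxel(seed_pt, ct$pitch_um)
  tree <- region_grow_3d(ct_s, seed_vox, air_thr)
  alv_mask <- airways$labels > 0L & tree$labels == 0L
  say("measuring")
  comp <- label_components(alv_mask, pitch_um = ct$pitch_um)
  comp <- select_solid_components(comp, core_radius = 2L)
  pks <- vt$histogram$peaks
  if (length(pks) == 2 && !any(is.na(pks))) {
    # real chambers sit far below the air background; fringe webs do not
    comp <- select_dark_components(comp, ct_s$data,
                                   cutoff = pks[1] - (pks[2] - pks[1]))
  }
  stats <- measure_all(comp, min_voxels = min_component_voxels)
  run <- structure(list(
    spec = spec, geometry = geometry, seed = seed,
    phantom = phantom, phantom_volume = pvol, material_table = tab,
    projections = pset, ct = ct, ct_smoothed = ct_s,
    ct_rescaled = ct_rescaled,
    valley = vt, bone = bone, airways = airways, tree = tree,
    components = comp, stats = stats,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ), class = "xpci_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_volume(ct, file.path(out_dir, "ct.tif"))
    write_volume(bone, file.path(out_dir, "labels_bone.tif"))
    write_volume(airways, file.path(out_dir, "labels_airways.tif"))
    write_volume(tree, file.path(out_dir, "labels_tree.tif"))
    write_volume(comp, file.path(out_dir, "labels_alveoli.tif"))
    write_stats_csv(stats, file.path(out_dir, "alveolus_stats.csv"))
    h <- vt$histogram
    utils::write.csv(
      data.frame(gray = h$mids, count = h$counts, smoothed = h$smoothed),
      file.path(out_dir, "histogram.csv"), row.names = FALSE
    )
    utils::write.csv(phantom$alveoli,
                     file.path(out_dir, "ground_truth_alveoli.csv"),
                     row.names = FALSE)
    write_manifest(run_manifest(run), file.path(out_dir, "manifest.json"))
  }
  run
}

run_manifest <- function(run) {
  list(
    package = list(name = "xpcilung",
                   version = as.character(utils::packageVersion("xpcilung"))),
    seed = run$seed,
    phantom = unclass(run$spec),
    geometry = unclass(run$geometry),
    acquisition = list(propagator = run$projections$propagator,
                       n_angles = length(run$projections$angles_deg)),
    reconstruction = list(filter = run$ct$filter,
                          pitch_um = run$ct$pitch_um),
    segmentation = list(valley_threshold = run$valley$threshold,
                        connectivity = 26),
    morphometry = list(n_components = nrow(run$stats),
                       mean_eq_diam_um = mean(run$stats$eq_diam_um)),
    elapsed_s = run$elapsed_s
  )
}

#' @export
print.xpci_run <- function(x, ...) {
  cat(sprintf("<xpci_run> seed %d, %d projections, %s propagator\n",
              x$seed, length(x$projections$angles_deg),
              x$projections$propagator))
  cat(sprintf("  planted %d alveoli (%.4g-%.4g um), recovered %d components\n",
              nrow(x$phantom$alveoli), min(x$phantom$alveoli$diameter_um),
              max(x$phantom$alveoli$diameter_um), nrow(x$stats)))
  if (nrow(x$stats) > 0) {
    cat(sprintf("  mean measured equivalent diameter %.4g um\n",
                mean(x$stats$eq_diam_um)))
  }
  invisible(x)
}

#' @export
summary.xpci_run <- function(object, ...) {
  gt <- object$phantom$alveoli
  st <- object$stats
  out <- list(
    planted = nrow(gt),
    recovered = nrow(st),
    mean_eq_diam_um = if (nrow(st)) mean(st$eq_diam_um) else NA_real_,
    mean_true_diam_um = mean(gt$diameter_um),
    valley_threshold = object$valley$threshold,
    elapsed_s = object$elapsed_s
  )
  class(out) <- "summary.xpci_run"
  out
}

#' @export
print.summary.xpci_run <- function(x, ...) {
  cat(sprintf("planted alveoli: %d (true mean diameter %.4g um)\n",
              x$planted, x$mean_true_diam_um))
  cat(sprintf("recovered components: %d, mean equivalent diameter %.4g um\n",
              x$recovered, x$mean_eq_diam_um))
  cat(sprintf("valley threshold %.4g, elapsed %.1f s\n",
              x$valley_threshold, x$elapsed_s))
  invisible(x)
}

#' Match measured components to planted alveoli
#'
#' Greedy nearest-centroid matching within `max_dist_um`; used for
#' parameter-recovery checks.
#'
#' @param run an `xpci_run`.
#' @param max_dist_um maximum centroid distance for a match.
#' @return data frame of matches: ground-truth id, component id, true and
#'   measured diameters and their error.
#' @export
match_alveoli <- function(run, max_dist_um = 60) {
  gt <- run$phantom$alveoli
  st <- run$stats
  if (nrow(st) == 0) {
    return(data.frame(gt_id = integer(0), comp_id = integer(0),
                      true_diam_um = numeric(0), eq_diam_um = numeric(0),
                      error_um = numeric(0)))
  }
  used <- logical(nrow(st))
  rows <- lapply(seq_len(nrow(gt)), function(i) {
    d <- sqrt((st$cx_um - gt$cx_um[i])^2 + (st$cy_um - gt$cy_um[i])^2 +
                (st$cz_um - gt$cz_um[i])^2)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) == 0 || d[j] > max_dist_um) return(NULL)
    used[j] <<- TRUE
    data.frame(gt_id = gt$id[i], comp_id = st$id[j],
               true_diam_um = gt$diameter_um[i],
               eq_diam_um = st$eq_diam_um[j],
               error_um = st$eq_diam_um[j] - gt$diameter_um[i])
  })
  out <- do.call(rbind, rows)
  out %||% data.frame(gt_id = integer(0), comp_id = integer(0),
                      true_diam_um = numeric(0), eq_diam_um = numeric(0),
                      error_um = numeric(0))
}

#' Detector-limited edge resolution study
#'
#' Simulates a sharp tissue/air bar edge at the full-size beamline
#' geometry (18 keV, z = 1.2 m, 13 um detector by default), reconstructs
#' it, and measures the edge-spread function across the interface: the
#' FWHM of its derivative is the system's spatial resolution, which for a
#' detector-limited setup is of the order of one detector pixel.
#'
#' @param energy_keV,distance_m,detector_pitch_um,n_angles acquisition
#'   parameters.
#' @param bar_width_um width of the tissue bar.
#' @param n_det detector columns simulated.
#' @param filter FBP filter.
#' @return list with `fwhm_um`, `width_10_90_um`, `ct` (the reconstructed
#'   slice), `profile`.
#' @export
edge_resolution_study <- function(energy_keV = 18, distance_m = 1.2,
                                  detector_pitch_um = 13, n_angles = 240,
                                  bar_width_um = 416, n_det = 96,
                                  filter = "ramp", sim_pitch_um = NULL) {
  geom <- beam_geometry(energy_keV = energy_keV, distance_m = distance_m,
                        detector_pitch_um = detector_pitch_um,
                        n_angles = n_angles, flat_photons = 0,
                        n_flat_frames = 1, sim_pitch_um = sim_pitch_um)
  ps <- geom$sim_pitch_um
  f <- as.integer(round(detector_pitch_um / ps))
  nx <- n_det * f
  nz <- 2L * f
  ext <- nx * ps
  # tissue bar centred in air: long axis along y
  tab <- build_material_table(energy_keV)
  labels <- array(0L, dim = c(nx, nx, nz))
  xs <- (seq_len(nx) - 0.5) * ps - ext / 2
  in_bar_x <- abs(xs) <= bar_width_um / 2
  in_bar_y <- abs(xs) <= ext * 0.3
  labels[in_bar_x, in_bar_y, ] <- 1L
  rvol <- refractive_volume(labels, tab, pitch_um = ps)
  pset <- suppressWarnings(
    acquire_ct(rvol, geom, seed = 1L, propagator = "exact")
  )
  ct <- reconstruct_volume(pset, filter = filter)
  slice <- ct$data[, , 1]
  n <- nrow(slice)
  ctr <- n / 2
  rows <- seq(round(ctr - n * 0.1), round(ctr + n * 0.1))
  prof <- rowMeans(slice[, rows])
  # profile crossing the +x edge of the bar, away from the opposite edge
  edge_x <- bar_width_um / 2
  i_edge <- round(edge_x / detector_pitch_um + ctr)
  span <- max(8, round(120 / detector_pitch_um))
  idx <- max(1, i_edge - span):min(n, i_edge + span)
  er <- edge_response(rev(prof[idx]), detector_pitch_um)
  c(er, list(ct = ct, profile = prof))
}
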