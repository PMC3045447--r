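# Volume, table, configuration and manifest I/O.
#
# Volumes travel as multi-page TIFF (one page per z slice) with a JSON
# sidecar (<path>.json) holding dimensions, pitch, value scaling and any
# extra metadata. TIFF pages store normalized 32-bit samples; the affine
# (lo, hi) scale in the sidecar restores physical values on read, with a
# worst-case quantization of 2^-32 of the value range. Integer label
# volumes round-trip exactly. The write -> read map is idempotent: a second
# round trip is bit-identical.

sidecar_path <- function(path) paste0(path, ".json")

#' Write a volume as a multi-page TIFF stack with JSON sidecar
#'
#' @param vol numeric or integer 3D array, or a `ct_volume` /
#'   `phantom_volume` / `label_volume` (pitch and type are taken from it).
#' @param path output TIFF path.
#' @param pitch_um voxel pitch recorded in the sidecar.
#' @param meta named list of extra metadata for the sidecar.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, pitch_um = NULL, meta = list()) {
  type <- "float"
  if (inherits(vol, "ct_volume")) {
    pitch_um <- pitch_um %||% vol$pitch_um
    meta$filter <- vol$filter
    vol <- vol$data
  } else if (inherits(vol, "label_volume")) {
    pitch_um <- pitch_um %||% vol$pitch_um
    meta$legend <- as.list(vol$legend)
    type <- "label"
    vol <- vol$labels
  } else if (inherits(vol, "phantom_volume")) {
    pitch_um <- pitch_um %||% vol$pitch_um
    type <- "label"
    vol <- vol$labels
  }
  if (is.integer(vol) || type == "label") type <- "label"
  d <- dim(vol)
  if (length(d) == 2) {
    d <- c(d, 1L)
    dim(vol) <- d
  }
  if (type == "label") {
    lo <- 0; hi <- 4294967295
    pages <- lapply(seq_len(d[3]), function(k) vol[, , k] / hi)
  } else {
    lo <- min(vol); hi <- max(vol)
    den <- if (hi > lo) hi - lo else 1
    pages <- lapply(seq_len(d[3]), function(k) (vol[, , k] - lo) / den)
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  jsonlite::write_json(
    c(list(dims = d, pitch_um = pitch_um, lo = lo, hi = hi, type = type),
      meta),
    sidecar_path(path), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a volume written by [write_volume()]
#'
#' @param path TIFF path (the `<path>.json` sidecar must exist).
#' @return list `data` (array; integer for label volumes), `pitch_um`,
#'   `meta`.
#' @export
read_volume <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) stop("missing volume sidecar ", sc)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE),
    error = function(e) stop("unreadable TIFF ", path, ": ",
                             conditionMessage(e))
  )
  d <- as.integer(meta$dims)
  if (length(pages) != d[3] || !all(dim(pages[[1]]) == d[1:2])) {
    stop("TIFF stack dimensions disagree with the sidecar for ", path)
  }
  # pages come back as sample / (2^32 - 1) in double precision
  vol <- array(0, dim = d)
  for (k in seq_len(d[3])) vol[, , k] <- pages[[k]]
  if (identical(meta$type, "label")) {
    out <- array(as.integer(round(vol * 4294967295)), dim = d)
  } else {
    out <- vol * (meta$hi - meta$lo) + meta$lo
  }
  extra <- meta[setdiff(names(meta), c("dims", "pitch_um", "lo", "hi", "type"))]
  list(data = out, pitch_um = meta$pitch_um, meta = extra)
}

#' Write / read a projection set
#'
#' Projections as one multi-page TIFF (one page per angle), the flat field
#' as a second TIFF, and a JSON sidecar with the beam geometry, angles and
#' seed.
#'
#' @param pset a `projection_set`.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_projection_set <- function(pset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(pset$images)
  g <- pset$geometry
  lo <- min(pset$images, 0); hi <- max(pset$images, pset$flat)
  pages <- lapply(seq_len(d[3]), function(k)
    (pset$images[, , k] - lo) / (hi - lo))
  tiff::writeTIFF(pages, file.path(dir, "projections.tif"),
                  bits.per.sample = 32L, compression = "none")
  tiff::writeTIFF(list((pset$flat - lo) / (hi - lo)),
                  file.path(dir, "flat.tif"),
                  bits.per.sample = 32L, compression = "none")
  jsonlite::write_json(list(
    dims = d, lo = lo, hi = hi,
    angles_deg = pset$angles_deg, seed = pset$seed,
    propagator = pset$propagator,
    geometry = unclass(g)
  ), file.path(dir, "acquisition.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_projection_set
#' @param dir directory written by `write_projection_set`.
#' @export
read_projection_set <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "acquisition.json"),
                              simplifyVector = TRUE)
  d <- as.integer(meta$dims)
  pages <- tiff::readTIFF(file.path(dir, "projections.tif"), all = TRUE)
  if (length(pages) != d[3]) stop("projection stack truncated in ", dir)
  images <- array(0, dim = d)
  for (k in seq_len(d[3])) {
    images[, , k] <- pages[[k]] * (meta$hi - meta$lo) + meta$lo
  }
  flat <- tiff::readTIFF(file.path(dir, "flat.tif")) *
    (meta$hi - meta$lo) + meta$lo
  g <- do.call(beam_geometry, meta$geometry[c(
    "energy_keV", "distance_m", "detector_pitch_um", "n_angles",
    "angular_range_deg", "flat_photons", "n_flat_frames", "sim_pitch_um")])
  structure(list(images = images, flat = flat, angles_deg = meta$angles_deg,
                 geometry = g, seed = meta$seed,
                 propagator = meta$propagator),
            class = "projection_set")
}

#' Write morphometry records to CSV
#' @param stats an `alveolus_stats` data frame.
#' @param path output CSV.
#' @export
write_stats_csv <- function(stats, path) {
  write.csv(as.data.frame(stats), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stats_csv
#' @export
read_stats_csv <- function(path) {
  out <- read.csv(path)
  class(out) <- c("alveolus_stats", "data.frame")
  out
}

#' Read / write a pipeline configuration
#'
#' Plain-text YAML with nested sections (`phantom`, `geometry`,
#' `segmentation`, `morphometry`, `seed`, `out_dir`); round-trips
#' losslessly.
#'
#' @param path YAML file.
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' @rdname read_config
#' @param config named list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Write the run manifest
#'
#' Every pipeline stage records its parameters into one JSON manifest
#' sufficient to re-execute the run.
#'
#' @param manifest named list of stage parameter records.
#' @param path output JSON.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) jsonlite::read_json(path,
                                                    simplifyVector = TRUE)
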