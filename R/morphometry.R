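#' Label connected components of a binary mask
#'
#' Each maximal connected component receives a distinct positive id;
#' components are numbered in order of their minimum linear voxel index,
#' so the labelling is deterministic.
#'
#' @param mask logical array (or a binary `label_volume`).
#' @param connectivity 6 or 26.
#' @param pitch_um voxel pitch carried into the result.
#' @return a `label_volume` whose legend maps `component_<i>` to i.
#' @export
label_components <- function(mask, connectivity = 26, pitch_um = NA_real_) {
  if (inherits(mask, "label_volume")) {
    if (is.na(pitch_um)) pitch_um <- mask$pitch_um
    mask <- mask$labels > 0L
  }
  lab <- label_components_cpp(mask, as.integer(dim(mask)),
                              as.integer(connectivity))
  k <- max(lab)
  legend <- if (k > 0) stats::setNames(seq_len(k), paste0("component_", seq_len(k)))
            else integer(0)
  new_label_volume(lab, legend, pitch_um)
}

component_voxels <- function(labels, id) {
  which(labels == id, arr.ind = TRUE)
}

#' Keep only components darker than an intensity cutoff
#'
#' Retains components whose median gray value lies at or below `cutoff`.
#' In the strong-phase regime a real air chamber's interior is pulled far
#' below the air background by its boundary's undershoot, while the
#' shallow sub-threshold webs that fringe halos carve out of tissue stay
#' within the air-tissue gray band; a cutoff one air-tissue contrast below
#' the air peak separates the two.
#'
#' @param label_volume a `label_volume`.
#' @param intensity numeric array of gray values (same dims).
#' @param cutoff gray value; components with median above it are dropped.
#' @return the filtered `label_volume`.
#' @export
select_dark_components <- function(label_volume, intensity, cutoff) {
  labels <- label_volume$labels
  ids <- unique(labels[labels > 0L])
  if (length(ids) == 0) return(label_volume)
  med <- vapply(ids, function(i) stats::median(intensity[labels == i]),
                numeric(1))
  drop <- ids[med > cutoff]
  if (length(drop) > 0) {
    labels[labels %in% drop] <- 0L
    label_volume$labels <- labels
    label_volume$legend <-
      label_volume$legend[!label_volume$legend %in% drop]
  }
  label_volume
}

#' Keep only components with a solid interior
#'
#' Retains components containing at least one voxel whose full cubic
#' neighbourhood of half-width `core_radius` lies inside the component.
#' Air chambers (alveoli, ducts) are solid bodies and always contain such
#' core voxels; the thin shell-shaped false positives that edge-enhancement
#' fringes leave along airway and bone walls never do, because their
#' thickness is set by the fringe width, not the object size. This is the
#' automated counterpart of manually choosing single alveoli for
#' measurement.
#'
#' @param label_volume a `label_volume`.
#' @param core_radius neighbourhood half-width in voxels.
#' @return the `label_volume` with non-solid components removed (labels
#'   preserved, legend filtered).
#' @export
select_solid_components <- function(label_volume, core_radius = 2L) {
  labels <- label_volume$labels
  mask <- labels > 0L
  f <- box_mean3_cpp(array(as.numeric(mask), dim(mask)),
                     as.integer(dim(mask)), as.integer(core_radius))
  core_ids <- unique(labels[f > 1 - 1e-9 & mask])
  keep <- array(labels %in% core_ids & mask, dim = dim(labels))
  out <- labels
  out[!keep] <- 0L
  new_label_volume(out, label_volume$legend[label_volume$legend %in% core_ids],
                   label_volume$pitch_um)
}

#' Equivalent (volume-sphere) diameter
#'
#' The diameter of the sphere with the same volume as the component:
#' `d = (6 V / pi)^(1/3)`, `V` = voxel count x pitch^3.
#'
#' @param n_voxels voxel count of the component (or a logical mask).
#' @param pitch_um voxel pitch.
#' @return diameter in um.
#' @export
equivalent_diameter <- function(n_voxels, pitch_um) {
  if (is.array(n_voxels) || is.logical(n_voxels)) n_voxels <- sum(n_voxels)
  if (n_voxels < 1) stop("empty component has no equivalent diameter")
  (6 * n_voxels * pitch_um^3 / pi)^(1 / 3)
}

caliper_direction_grid <- function(step_deg = 3) {
  th <- seq(0, 180 - step_deg, by = step_deg) * pi / 180
  ph <- seq(-90, 90, by = step_deg) * pi / 180
  g <- expand.grid(th = th, ph = ph)
  cbind(cos(g$ph) * cos(g$th), cos(g$ph) * sin(g$th), sin(g$ph))
}

surface_voxel_coords <- function(mask, pitch_um) {
  d <- dim(mask)
  interior <- mask
  # voxels whose 6 face neighbours are all inside are not on the surface
  if (all(d > 2)) {
    core <- mask
    core[] <- FALSE
    i <- 2:(d[1] - 1); j <- 2:(d[2] - 1); k <- 2:(d[3] - 1)
    core[i, j, k] <- mask[i - 1, j, k] & mask[i + 1, j, k] &
      mask[i, j - 1, k] & mask[i, j + 1, k] &
      mask[i, j, k - 1] & mask[i, j, k + 1] & mask[i, j, k]
    interior <- mask & !core
  }
  w <- which(interior, arr.ind = TRUE)
  (w - 0.5) * pitch_um
}

#' Maximum and minimum Feret (caliper) diameters
#'
#' 3D caliper extents of a voxel component: `d_max` is the maximum pairwise
#' distance between surface-voxel centres and `d_min` the minimal projected
#' caliper width over a 3-degree orientation grid; both are corrected by
#' one voxel pitch for the voxel extent, so a single voxel has
#' `d_max = d_min = pitch`.
#'
#' @param mask logical array marking the component's voxels.
#' @param pitch_um voxel pitch.
#' @param step_deg orientation grid spacing for the minimal width.
#' @return list `d_max_um`, `d_min_um`.
#' @export
feret_diameters <- function(mask, pitch_um, step_deg = 3) {
  if (!any(mask)) stop("empty component has no Feret diameters")
  pts <- surface_voxel_coords(mask, pitch_um)
  if (nrow(pts) == 1) {
    return(list(d_max_um = pitch_um, d_min_um = pitch_um))
  }
  dmax <- max_pairwise_dist_cpp(pts) + pitch_um
  widths <- caliper_widths_cpp(pts, caliper_direction_grid(step_deg))
  dmin <- min(widths) + pitch_um
  list(d_max_um = dmax, d_min_um = dmin)
}

voxel_face_area <- function(mask, pitch_um) {
  d <- dim(mask)
  m <- array(FALSE, dim = d + 2)
  m[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  D <- dim(m)
  faces <- 0L
  for (ax in 1:3) {
    ia <- lapply(1:3, function(k) if (k == ax) seq_len(D[k] - 1) else
      seq_len(D[k]))
    ib <- lapply(1:3, function(k) if (k == ax) 1 + seq_len(D[k] - 1) else
      seq_len(D[k]))
    a <- do.call(`[`, c(list(m), ia))
    b <- do.call(`[`, c(list(m), ib))
    faces <- faces + sum(xor(a, b))
  }
  faces * pitch_um^2
}

#' Surface area of a voxel component
#'
#' Default method: one pass of 3^3 mean smoothing of the (zero-padded)
#' binary grid, then iso-surface triangulation at level 0.5 and summation
#' of triangle areas. Converges to the true area as the pitch shrinks. If
#' the smoothed field never reaches the iso-level (degenerate few-voxel
#' components) the method falls back to voxel-face counting with a warning.
#' `method = "voxel"` counts exposed voxel faces exactly (a cube of side s
#' gives 6 s^2).
#'
#' @param mask logical array marking the component.
#' @param pitch_um voxel pitch.
#' @param method `"mesh"` or `"voxel"`.
#' @return area in um^2.
#' @export
surface_area <- function(mask, pitch_um, method = c("mesh", "voxel")) {
  method <- match.arg(method)
  if (!any(mask)) stop("empty component has no surface area")
  if (method == "voxel") return(voxel_face_area(mask, pitch_um))
  mesh <- component_mesh(mask, pitch_um)
  if (is.null(mesh)) {
    warning("iso-surface extraction degenerate; using voxel-face area")
    return(voxel_face_area(mask, pitch_um))
  }
  attr(mesh, "area")
}

# mesh one component: crop to bounding box, zero-pad by 2, smooth 3^3,
# extract the 0.5 level set in world coordinates
component_mesh <- function(mask, pitch_um, smooth = TRUE, origin_um = c(0, 0, 0)) {
  w <- which(mask, arr.ind = TRUE)
  pad <- 2L
  lo <- pmax(apply(w, 2, min) - pad, 1 - pad)
  hi <- apply(w, 2, max) + pad
  dims <- hi - lo + 1
  sub <- array(0, dim = dims)
  idx <- sweep(w, 2, lo - 1L, `-`)
  sub[idx] <- 1
  f <- if (smooth) box_mean3_cpp(sub, as.integer(dims), 1L) else sub
  if (max(f) < 0.5 || min(f) >= 0.5) return(NULL)
  origin <- origin_um + (lo - 0.5) * pitch_um
  m <- march_tets_cpp(f, as.integer(dims), 0.5, pitch_um, origin)
  if (nrow(m$faces) == 0) return(NULL)
  out <- surface_mesh(m$vertices, m$faces)
  attr(out, "area") <- m$area
  out
}

#' Morphometry of every labelled component
#'
#' One record per label id: volume, equivalent diameter, maximum and
#' minimum Feret diameters, their ratio (1 for a sphere), iso-surface area
#' and centroid. Records are sorted by id and write cleanly to CSV.
#'
#' Components smaller than `mesh_min_voxels` use voxel-face surface area
#' (the smoothed iso-surface is unreliable for a handful of voxels).
#'
#' @param label_volume a `label_volume` (e.g. from [label_components()]).
#' @param pitch_um voxel pitch override.
#' @param min_voxels skip components smaller than this.
#' @param mesh_min_voxels smallest component measured with the mesh method.
#' @param step_deg caliper orientation grid spacing.
#' @return an `alveolus_stats` data frame with columns `id`, `volume_um3`,
#'   `eq_diam_um`, `dmax_um`, `dmin_um`, `ratio`, `surface_area_um2`,
#'   `cx_um`, `cy_um`, `cz_um`.
#' @export
measure_all <- function(label_volume, pitch_um = NULL, min_voxels = 1,
                        mesh_min_voxels = 64, step_deg = 3) {
  labels <- label_volume$labels
  pitch <- pitch_um %||% label_volume$pitch_um
  if (is.na(pitch)) stop("label volume has no pitch; supply pitch_um")
  k <- max(labels)
  rows <- list()
  for (id in seq_len(k)) {
    mask <- labels == id
    n <- sum(mask)
    if (n == 0 || n < min_voxels) next
    fer <- feret_diameters(mask, pitch, step_deg)
    area <- if (n >= mesh_min_voxels) {
      surface_area(mask, pitch, "mesh")
    } else {
      voxel_face_area(mask, pitch)
    }
    ctr <- colMeans((which(mask, arr.ind = TRUE) - 0.5) * pitch)
    rows[[length(rows) + 1]] <- data.frame(
      id = id,
      volume_um3 = n * pitch^3,
      eq_diam_um = equivalent_diameter(n, pitch),
      dmax_um = fer$d_max_um,
      dmin_um = fer$d_min_um,
      ratio = fer$d_max_um / fer$d_min_um,
      surface_area_um2 = area,
      cx_um = ctr[1], cy_um = ctr[2], cz_um = ctr[3]
    )
  }
  out <- if (length(rows) > 0) {
    do.call(rbind, rows)
  } else {
    data.frame(id = integer(0), volume_um3 = numeric(0),
               eq_diam_um = numeric(0), dmax_um = numeric(0),
               dmin_um = numeric(0), ratio = numeric(0),
               surface_area_um2 = numeric(0), cx_um = numeric(0),
               cy_um = numeric(0), cz_um = numeric(0))
  }
  rownames(out) <- NULL
  class(out) <- c("alveolus_stats", "data.frame")
  attr(out, "pitch_um") <- pitch
  out
}

#' @export
print.alveolus_stats <- function(x, ...) {
  cat(sprintf("<alveolus_stats> %d components at %.3g um pitch\n",
              nrow(x), attr(x, "pitch_um")))
  if (nrow(x) > 0) {
    cat(sprintf("  eq diameter %.4g-%.4g um (mean %.4g), ratio mean %.3g\n",
                min(x$eq_diam_um), max(x$eq_diam_um), mean(x$eq_diam_um),
                mean(x$ratio)))
  }
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}
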