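#' Specify a digital lung phantom
#'
#' The phantom is the pipeline's ground-truth object: a soft-tissue cylinder
#' (the animal body, mounted with its axis on the CT rotation axis) embedded
#' in air, containing a bifurcating air-filled airway tree, air-filled
#' alveolar spheres of known diameter attached near the terminal branches,
#' and bone rib arcs near the body surface. Every structure is analytic, so
#' each downstream stage (projection, reconstruction, segmentation,
#' morphometry) can be validated by parameter recovery.
#'
#' Alveoli are kept pairwise separated and detached from the airway lumen by
#' a tissue wall (`wall_um`): real alveolar sacs share walls and open into
#' their ducts, but per-object validation requires separable chambers.
#'
#' @param extent_um volume extent per axis (um), length 1 or 3.
#' @param pitch_um voxel pitch (um).
#' @param tree list: `depth` (bifurcation generations), `root_radius_um`,
#'   `radius_ratio` (child/parent), `root_length_um`, `length_ratio`,
#'   `branch_angle_deg` (range, degrees off the parent axis).
#' @param alveoli list: `count`, `diameter_range_um` (`c(lo, hi)`),
#'   `wall_um` (tissue gap to ducts and between alveoli), `jitter_um`
#'   (attachment distance jitter).
#' @param ribs list: `count`, `tube_radius_um`, `arc_deg`,
#'   `ring_radius_frac` (ring radius as a fraction of the extent).
#' @param cylinder_radius_frac body cylinder radius as a fraction of the
#'   smallest transverse extent.
#' @param seed integer seed; identical spec + seed give a bit-identical
#'   phantom.
#' @return A `lung_phantom_spec` list.
#' @seealso [build_phantom()], [default_phantom_spec()]
#' @export
phantom_spec <- function(extent_um = c(1024, 1024, 1024),
                         pitch_um = 4,
                         tree = list(),
                         alveoli = list(),
                         ribs = list(),
                         cylinder_radius_frac = 0.42,
                         seed = 1L) {
  if (length(extent_um) == 1) extent_um <- rep(extent_um, 3)
  tree <- utils::modifyList(list(
    depth = 4L, root_radius_um = 80, radius_ratio = 0.75,
    root_length_um = 240, length_ratio = 0.78,
    branch_angle_deg = c(20, 35)
  ), tree)
  alveoli <- utils::modifyList(list(
    count = 21L, diameter_range_um = c(100, 150),
    wall_um = 30, jitter_um = 60
  ), alveoli)
  ribs <- utils::modifyList(list(
    count = 4L, tube_radius_um = 36, arc_deg = 110, ring_radius_frac = 0.35
  ), ribs)
  spec <- structure(list(
    extent_um = as.numeric(extent_um), pitch_um = pitch_um,
    tree = tree, alveoli = alveoli, ribs = ribs,
    cylinder_radius_frac = cylinder_radius_frac, seed = as.integer(seed)
  ), class = "lung_phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  d <- spec$alveoli$diameter_range_um
  if (length(d) != 2 || d[1] > d[2]) {
    stop("alveolar diameter range must be c(lo, hi) with lo <= hi")
  }
  if (any(spec$extent_um <= 0)) stop("zero- or negative-extent volume")
  radii <- c(spec$tree$root_radius_um *
               spec$tree$radius_ratio^(seq_len(spec$tree$depth) - 1),
             d[1] / 2, spec$ribs$tube_radius_um)
  if (any(radii <= 2 * spec$pitch_um)) {
    stop("all structure radii must exceed 2 x voxel pitch (",
         spec$pitch_um, " um): smallest radius ", min(radii), " um")
  }
  if (spec$alveoli$count < 1) stop("alveolus count must be >= 1")
  if (spec$tree$depth < 1) stop("tree depth must be >= 1")
  invisible(spec)
}

#' @export
print.lung_phantom_spec <- function(x, ...) {
  cat(sprintf("<lung_phantom_spec> %s um extent, %.3g um pitch, seed %d\n",
              paste(x$extent_um, collapse = " x "), x$pitch_um, x$seed))
  cat(sprintf("  tree: depth %d, root radius %.3g um, ratio %.3g\n",
              x$tree$depth, x$tree$root_radius_um, x$tree$radius_ratio))
  cat(sprintf("  alveoli: %d, diameters %.4g-%.4g um\n", x$alveoli$count,
              x$alveoli$diameter_range_um[1], x$alveoli$diameter_range_um[2]))
  cat(sprintf("  ribs: %d arcs, tube radius %.3g um\n",
              x$ribs$count, x$ribs$tube_radius_um))
  invisible(x)
}

rotate_about <- function(v, axis, angle) {
  # Rodrigues rotation of vector v about unit axis
  axis <- axis / sqrt(sum(axis^2))
  v * cos(angle) + pracma_cross(axis, v) * sin(angle) +
    axis * sum(axis * v) * (1 - cos(angle))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Generate the bifurcating airway tree
#'
#' A connected binary tree rooted at a single trachea segment running down
#' the rotation (z) axis. Each generation halves into two children with
#' radius and length scaled by the configured ratios and directions tilted
#' off the parent axis by an angle drawn from `branch_angle_deg`, at opposite
#' azimuths. All segments must stay inside the body cylinder.
#'
#' @param spec a [phantom_spec()].
#' @param seed RNG seed (defaults to the spec's).
#' @return data frame with one row per branch: `id`, `parent`, `generation`
#'   (1 = trachea), endpoints `x0,y0,z0,x1,y1,z1` (um), `radius_um`,
#'   `terminal`.
#' @export
generate_airway_tree <- function(spec, seed = spec$seed) {
  ext <- spec$extent_um
  cyl_r <- spec$cylinder_radius_frac * min(ext[1], ext[2])
  centre <- ext / 2
  tr <- spec$tree
  with_seed(seed, {
    rows <- list()
    grow <- function(start, dir, radius, len, gen, parent) {
      end <- start + dir * len
      margin <- radius + 4 * spec$pitch_um
      rad_end <- sqrt(sum((end[1:2] - centre[1:2])^2))
      if (rad_end > cyl_r - margin ||
          end[3] < margin || end[3] > ext[3] - margin) {
        stop("airway branch at generation ", gen,
             " leaves the body cylinder; shrink lengths or angles")
      }
      id <- length(rows) + 1L
      rows[[id]] <<- data.frame(
        id = id, parent = parent, generation = gen,
        x0 = start[1], y0 = start[2], z0 = start[3],
        x1 = end[1], y1 = end[2], z1 = end[3],
        radius_um = radius, terminal = gen == tr$depth
      )
      if (gen < tr$depth) {
        polar <- runif(2, tr$branch_angle_deg[1], tr$branch_angle_deg[2]) *
          pi / 180
        az0 <- runif(1, 0, 2 * pi)
        az <- c(az0, az0 + pi + runif(1, -pi / 6, pi / 6))
        # orthonormal frame around the parent direction
        up <- if (abs(dir[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
        e1 <- pracma_cross(dir, up); e1 <- e1 / sqrt(sum(e1^2))
        e2 <- pracma_cross(dir, e1)
        for (ci in 1:2) {
          cd <- dir * cos(polar[ci]) +
            (e1 * cos(az[ci]) + e2 * sin(az[ci])) * sin(polar[ci])
          cd <- cd / sqrt(sum(cd^2))
          grow(end, cd, radius * tr$radius_ratio, len * tr$length_ratio,
               gen + 1L, id)
        }
      }
    }
    # the trachea's rounded cap must stay clear of the volume border
    z0 <- max(0.08 * ext[3], tr$root_radius_um + 8 * spec$pitch_um)
    root_start <- c(centre[1], centre[2], z0)
    grow(root_start, c(0, 0, 1), tr$root_radius_um, tr$root_length_um,
         1L, NA_integer_)
    do.call(rbind, rows)
  })
}

point_segment_distance <- function(p, a, b) {
  u <- b - a
  len2 <- sum(u^2)
  t <- if (len2 > 0) max(0, min(1, sum((p - a) * u) / len2)) else 0
  sqrt(sum((a + t * u - p)^2))
}

point_arc_distance <- function(p, arc) {
  # arc: list(cx, cy, cz, R, a0, a1)
  dx <- p[1] - arc$cx; dy <- p[2] - arc$cy; dz <- p[3] - arc$cz
  ang <- atan2(dy, dx)
  while (ang < arc$a0) ang <- ang + 2 * pi
  if (ang <= arc$a1) {
    sqrt((sqrt(dx^2 + dy^2) - arc$R)^2 + dz^2)
  } else {
    e0 <- c(arc$cx + arc$R * cos(arc$a0), arc$cy + arc$R * sin(arc$a0), arc$cz)
    e1 <- c(arc$cx + arc$R * cos(arc$a1), arc$cy + arc$R * sin(arc$a1), arc$cz)
    min(sqrt(sum((p - e0)^2)), sqrt(sum((p - e1)^2)))
  }
}

#' Attach ground-truth alveoli near the terminal branches
#'
#' Spheres with diameters drawn uniformly from `d_range` are placed near the
#' endpoints of terminal airway segments by rejection sampling: each placed
#' sphere must keep a tissue wall (`wall_um`) to every other alveolus, to
#' every branch (including its own duct), to the ribs and to the body
#' cylinder surface, so that each alveolus is a separate air chamber.
#'
#' @param tree branch data frame from [generate_airway_tree()].
#' @param count number of alveoli.
#' @param d_range diameter range `c(lo, hi)` in um.
#' @param seed RNG seed.
#' @param spec the [phantom_spec()] (supplies extent, wall, jitter, ribs).
#' @param ribs optional list of rib arcs (as built by [build_phantom()]).
#' @param max_tries rejection-sampling attempts per alveolus.
#' @return data frame `id`, `cx_um`, `cy_um`, `cz_um`, `diameter_um`,
#'   `terminal_id`.
#' @export
populate_alveoli <- function(tree, count, d_range, seed, spec,
                             ribs = list(), max_tries = 8000L) {
  terms <- tree[tree$terminal, , drop = FALSE]
  if (nrow(terms) == 0) stop("tree has no terminal segments")
  ext <- spec$extent_um
  centre <- ext / 2
  cyl_r <- spec$cylinder_radius_frac * min(ext[1], ext[2])
  wall <- spec$alveoli$wall_um
  jit <- spec$alveoli$jitter_um
  segs <- lapply(seq_len(nrow(tree)), function(i) {
    list(a = c(tree$x0[i], tree$y0[i], tree$z0[i]),
         b = c(tree$x1[i], tree$y1[i], tree$z1[i]),
         r = tree$radius_um[i])
  })
  with_seed(seed, {
    placed <- matrix(numeric(0), ncol = 4) # cx, cy, cz, r
    term_id <- integer(0)
    for (n in seq_len(count)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        # spread over terminals, but re-draw when a region is crowded
        ti <- if (try == 1) {
          terms$id[((n - 1) %% nrow(terms)) + 1]
        } else {
          terms$id[sample.int(nrow(terms), 1)]
        }
        seg <- segs[[ti]]
        axis_dir <- (seg$b - seg$a) / sqrt(sum((seg$b - seg$a)^2))
        r <- runif(1, d_range[1], d_range[2]) / 2
        # direction biased along the duct continuation
        u <- axis_dir + rnorm(3, sd = 1.0)
        u <- u / sqrt(sum(u^2))
        dist <- seg$r + wall + r + runif(1, 0, jit)
        ctr <- seg$b + u * dist
        # inside the body cylinder and volume, with a wall of tissue around
        if (sqrt(sum((ctr[1:2] - centre[1:2])^2)) > cyl_r - r - wall) next
        if (any(ctr < r + wall) || any(ctr > ext - r - wall)) next
        # tissue wall to every branch (its own duct included)
        clear <- TRUE
        for (s in segs) {
          if (point_segment_distance(ctr, s$a, s$b) < s$r + r + wall) {
            clear <- FALSE; break
          }
        }
        if (!clear) next
        # wall to previously placed alveoli
        if (nrow(placed) > 0) {
          dd <- sqrt(colSums((t(placed[, 1:3, drop = FALSE]) - ctr)^2))
          if (any(dd < placed[, 4] + r + wall)) next
        }
        # wall to rib arcs
        if (length(ribs) > 0) {
          dr <- vapply(ribs, function(a)
            point_arc_distance(ctr, a), numeric(1))
          if (any(dr < spec$ribs$tube_radius_um + r + wall)) next
        }
        placed <- rbind(placed, c(ctr, r))
        term_id <- c(term_id, ti)
        ok <- TRUE
        break
      }
      if (!ok) {
        stop("could not place ", count, " non-overlapping alveoli (placed ",
             nrow(placed), "); enlarge the volume or shrink diameters")
      }
    }
    data.frame(
      id = seq_len(nrow(placed)),
      cx_um = placed[, 1], cy_um = placed[, 2], cz_um = placed[, 3],
      diameter_um = 2 * placed[, 4],
      terminal_id = term_id
    )
  })
}

#' Build the analytic phantom geometry
#'
#' Deterministically generates the airway tree, alveoli and rib arcs from a
#' spec (same spec + seed always give the same geometry).
#'
#' @param spec a [phantom_spec()].
#' @return A `lung_phantom` list: `spec`, `branches`, `alveoli` (the
#'   ground-truth table), `ribs`, `cylinder`.
#' @export
build_phantom <- function(spec) {
  validate_phantom_spec(spec)
  ext <- spec$extent_um
  tree <- generate_airway_tree(spec, seed = spec$seed)
  ring_R <- spec$ribs$ring_radius_frac * min(ext[1], ext[2])
  arc_half <- spec$ribs$arc_deg / 2 * pi / 180
  nrib <- spec$ribs$count
  ribs <- list()
  if (nrib > 0) {
    zf <- seq(0.22, 0.78, length.out = nrib)
    az <- with_seed(spec$seed + 7L, runif(nrib, 0, 2 * pi))
    ribs <- lapply(seq_len(nrib), function(i) {
      list(cx = ext[1] / 2, cy = ext[2] / 2, cz = zf[i] * ext[3],
           R = ring_R, tube = spec$ribs$tube_radius_um,
           a0 = az[i] - arc_half, a1 = az[i] + arc_half)
    })
  }
  alv <- populate_alveoli(tree, spec$alveoli$count,
                          spec$alveoli$diameter_range_um,
                          seed = spec$seed + 1L, spec = spec, ribs = ribs)
  structure(list(spec = spec, branches = tree, alveoli = alv, ribs = ribs,
                 cylinder = list(cx = ext[1] / 2, cy = ext[2] / 2,
                                 radius = spec$cylinder_radius_frac *
                                   min(ext[1], ext[2]))),
            class = "lung_phantom")
}

#' @export
print.lung_phantom <- function(x, ...) {
  cat(sprintf(paste0("<lung_phantom> %d airway branches, %d alveoli ",
                     "(%.4g-%.4g um), %d ribs\n"),
              nrow(x$branches), nrow(x$alveoli),
              min(x$alveoli$diameter_um), max(x$alveoli$diameter_um),
              length(x$ribs)))
  invisible(x)
}

#' Rasterize a phantom into a material label volume
#'
#' Voxels are labelled by the material at their centre (0 air, 1 soft
#' tissue, 2 bone); airway lumina and alveolar interiors are air. The
#' ground-truth alveolus table travels with the volume.
#'
#' @param phantom a `lung_phantom` from [build_phantom()] (or a spec, which
#'   is built first).
#' @param pitch_um voxel pitch; defaults to the spec's.
#' @return A `phantom_volume` list: integer array `labels` (dims from extent
#'   and pitch), `pitch_um`, `phantom`, `ground_truth`.
#' @export
rasterize_phantom <- function(phantom, pitch_um = NULL) {
  if (inherits(phantom, "lung_phantom_spec")) phantom <- build_phantom(phantom)
  spec <- phantom$spec
  pitch <- pitch_um %||% spec$pitch_um
  smallest <- min(phantom$branches$radius_um, phantom$alveoli$diameter_um / 2)
  if (pitch > smallest) {
    warning("voxel pitch ", pitch, " um exceeds the smallest structure ",
            "radius (", signif(smallest, 3), " um); structures may vanish")
  }
  dims <- as.integer(round(spec$extent_um / pitch))
  if (any(dims < 1)) stop("zero-extent volume after rasterization")
  br <- as.matrix(phantom$branches[, c("x0", "y0", "z0", "x1", "y1", "z1",
                                       "radius_um")])
  sp <- as.matrix(phantom$alveoli[, c("cx_um", "cy_um", "cz_um")])
  sp <- cbind(sp, phantom$alveoli$diameter_um / 2)
  rb <- if (length(phantom$ribs) > 0) {
    do.call(rbind, lapply(phantom$ribs, function(a)
      c(a$cx, a$cy, a$cz, a$R, a$tube, a$a0, a$a1)))
  } else {
    matrix(numeric(0), ncol = 7)
  }
  labels <- rasterize_phantom_cpp(
    dims, pitch,
    c(phantom$cylinder$cx, phantom$cylinder$cy, phantom$cylinder$radius),
    br, sp, rb
  )
  structure(list(labels = labels, pitch_um = pitch, phantom = phantom,
                 ground_truth = phantom$alveoli),
            class = "phantom_volume")
}

#' @export
print.phantom_volume <- function(x, ...) {
  d <- dim(x$labels)
  tb <- tabulate(x$labels + 1L, nbins = 3)
  cat(sprintf("<phantom_volume> %d x %d x %d at %.3g um: %.1f%% air, %.1f%% tissue, %.1f%% bone\n",
              d[1], d[2], d[3], x$pitch_um,
              100 * tb[1] / sum(tb), 100 * tb[2] / sum(tb),
              100 * tb[3] / sum(tb)))
  invisible(x)
}

#' Rasterize a ground-truth mask of selected phantom structures
#'
#' Rasterizes only the requested structures on an arbitrary grid. Used to
#' compare segmentations on the reconstruction grid against analytic truth.
#'
#' @param phantom a `lung_phantom`.
#' @param what one of `"air"` (tree + alveoli), `"tree"`, `"alveoli"`,
#'   `"bone"`.
#' @param pitch_um grid pitch; `dims` grid dimensions (defaults from the
#'   spec extent).
#' @return logical array.
#' @export
phantom_mask <- function(phantom, what = c("air", "tree", "alveoli", "bone"),
                         pitch_um = phantom$spec$pitch_um, dims = NULL) {
  what <- match.arg(what)
  spec <- phantom$spec
  dims <- as.integer(dims %||% round(spec$extent_um / pitch_um))
  empty7 <- matrix(numeric(0), ncol = 7)
  empty4 <- matrix(numeric(0), ncol = 4)
  br <- as.matrix(phantom$branches[, c("x0", "y0", "z0", "x1", "y1", "z1",
                                       "radius_um")])
  sp <- cbind(as.matrix(phantom$alveoli[, c("cx_um", "cy_um", "cz_um")]),
              phantom$alveoli$diameter_um / 2)
  rb <- if (length(phantom$ribs) > 0) {
    do.call(rbind, lapply(phantom$ribs, function(a)
      c(a$cx, a$cy, a$cz, a$R, a$tube, a$a0, a$a1)))
  } else {
    empty7
  }
  lab <- switch(what,
    air = rasterize_phantom_cpp(dims, pitch_um, c(0, 0, -1), br, sp, empty7),
    tree = rasterize_phantom_cpp(dims, pitch_um, c(0, 0, -1), br, empty4,
                                 empty7),
    alveoli = rasterize_phantom_cpp(dims, pitch_um, c(0, 0, -1),
                                    matrix(numeric(0), ncol = 7), sp, empty7),
    bone = rasterize_phantom_cpp(dims, pitch_um, c(0, 0, 0),
                                 matrix(numeric(0), ncol = 7), empty4, rb)
  )
  if (what == "bone") array(lab == 2L, dim = dims) else
    array(lab == 0L, dim = dims)
}

#' Populate refractive-index volumes from a label volume
#'
#' Maps material labels to voxel grids of the refractive decrement `delta`
#' and absorption index `beta` at the table's energy.
#'
#' @param phantom_volume a `phantom_volume` (or bare integer label array).
#' @param material_table a [build_material_table()] result.
#' @param pitch_um required when a bare array is given.
#' @return A `refractive_volume` list: arrays `delta`, `beta`, `pitch_um`,
#'   `energy_keV`, and `ground_truth` when available.
#' @export
refractive_volume <- function(phantom_volume, material_table,
                              pitch_um = NULL) {
  if (inherits(phantom_volume, "phantom_volume")) {
    labels <- phantom_volume$labels
    pitch_um <- phantom_volume$pitch_um
    gt <- phantom_volume$ground_truth
  } else {
    labels <- phantom_volume
    if (is.null(pitch_um)) stop("pitch_um required for a bare label array")
    gt <- NULL
  }
  lk <- material_lookup(material_table)
  delta <- array(lk$delta[labels + 1L], dim = dim(labels))
  beta <- array(lk$beta[labels + 1L], dim = dim(labels))
  structure(list(delta = delta, beta = beta, pitch_um = pitch_um,
                 energy_keV = attr(material_table, "energy_keV"),
                 ground_truth = gt),
            class = "refractive_volume")
}
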