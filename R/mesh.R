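#' Construct a surface mesh
#'
#' @param vertices n x 3 numeric matrix (world um).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param name optional structure name.
#' @return a `surface_mesh` list.
#' @export
surface_mesh <- function(vertices, faces, name = NULL) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(faces) > 0 &&
      (min(faces) < 1 || max(faces) > nrow(vertices))) {
    stop("face indices out of range")
  }
  structure(list(vertices = vertices, faces = faces, name = name),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh>%s %d vertices, %d faces, area %.5g um^2\n",
              if (!is.null(x$name)) paste0(" '", x$name, "'") else "",
              nrow(x$vertices), nrow(x$faces), mesh_area(x)))
  invisible(x)
}

#' Total triangle area of a mesh
#' @param mesh a `surface_mesh`.
#' @return area in um^2.
#' @export
mesh_area <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0) return(0)
  v <- mesh$vertices
  a <- v[f[, 1], , drop = FALSE]
  u <- v[f[, 2], , drop = FALSE] - a
  w <- v[f[, 3], , drop = FALSE] - a
  cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
  cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
  cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' Volume enclosed by a closed, outward-oriented mesh
#'
#' Divergence-theorem sum of signed tetrahedron volumes against the
#' origin; requires a watertight mesh with consistent outward winding (as
#' produced by [extract_isosurface()]).
#'
#' @param mesh a `surface_mesh`.
#' @return volume in um^3.
#' @export
mesh_volume <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0) return(0)
  v <- mesh$vertices
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c <- v[f[, 3], , drop = FALSE]
  det <- a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
    a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
    a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])
  abs(sum(det)) / 6
}

# undirected unique edges of the face list
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' Euler characteristic V - E + F
#'
#' 2 for each closed sphere-topology surface; additive over components.
#' @param mesh a `surface_mesh`.
#' @export
euler_characteristic <- function(mesh) {
  used <- sort(unique(as.vector(mesh$faces)))
  length(used) - nrow(mesh_edges(mesh)) + nrow(mesh$faces)
}

#' Connected components of a mesh
#'
#' Union-find over shared vertices.
#' @param mesh a `surface_mesh`.
#' @return integer: number of connected components (of used vertices).
#' @export
mesh_component_count <- function(mesh) {
  n <- nrow(mesh$vertices)
  if (nrow(mesh$faces) == 0) return(0L)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  f <- mesh$faces
  for (r in seq_len(nrow(f))) {
    a <- find(f[r, 1]); b <- find(f[r, 2]); c <- find(f[r, 3])
    parent[b] <- a; parent[find(c)] <- a
  }
  used <- unique(as.vector(f))
  length(unique(vapply(used, find, integer(1))))
}

#' Extract an iso-surface from a scalar volume
#'
#' Triangulates the `iso_level` level set by marching tetrahedra; vertices
#' are in world um via the pitch (grid node (i,j,k), 1-based, maps to
#' `origin_um + (i - 0.5) * pitch_um`). Deterministic for fixed input, and
#' watertight on closed components.
#'
#' @param volume numeric array (or `ct_volume`).
#' @param iso_level level strictly inside the volume's value range.
#' @param pitch_um voxel pitch (defaulted from a `ct_volume`).
#' @param origin_um world position offset of the grid corner.
#' @param name optional name.
#' @return a `surface_mesh`.
#' @export
extract_isosurface <- function(volume, iso_level, pitch_um = NULL,
                               origin_um = c(0, 0, 0), name = NULL) {
  pitch_um <- get_volume_pitch(volume, pitch_um)
  v <- get_volume_data(volume)
  if (is.logical(v)) v <- array(as.numeric(v), dim = dim(v))
  rng <- range(v)
  if (iso_level <= rng[1] || iso_level >= rng[2]) {
    stop("iso level ", iso_level, " outside the value range (",
         signif(rng[1], 4), ", ", signif(rng[2], 4), ")")
  }
  m <- march_tets_cpp(v, as.integer(dim(v)), iso_level, pitch_um,
                      origin_um + 0.5 * pitch_um)
  surface_mesh(m$vertices, m$faces, name = name)
}

#' Clip a mesh by a plane
#'
#' Keeps the part of the surface in the half-space
#' `dot(x - point, normal) <= 0`; triangles crossing the plane are split at
#' the intersection (the cut is left open).
#'
#' @param mesh a `surface_mesh`.
#' @param point a point on the plane (um).
#' @param normal plane normal (non-zero; points away from the kept side).
#' @return a `surface_mesh`.
#' @export
clip_mesh <- function(mesh, point, normal) {
  nlen <- sqrt(sum(normal^2))
  if (nlen == 0) stop("degenerate plane normal")
  normal <- normal / nlen
  v <- mesh$vertices
  d <- as.numeric((v - matrix(point, nrow(v), 3, byrow = TRUE)) %*% normal)
  keepv <- d <= 0
  out_v <- list(); out_f <- list()
  nv <- 0L
  addv <- function(p) {
    nv <<- nv + 1L
    out_v[[nv]] <<- p
    nv
  }
  for (r in seq_len(nrow(mesh$faces))) {
    idx <- mesh$faces[r, ]
    dd <- d[idx]
    if (all(dd <= 0)) {
      a <- addv(v[idx[1], ]); b <- addv(v[idx[2], ]); c <- addv(v[idx[3], ])
      out_f[[length(out_f) + 1]] <- c(a, b, c)
    } else if (all(dd > 0)) {
      next
    } else {
      # Sutherland-Hodgman clip of the triangle against the plane
      poly <- list()
      for (e in 1:3) {
        i1 <- idx[e]; i2 <- idx[if (e == 3) 1 else e + 1]
        p1 <- v[i1, ]; p2 <- v[i2, ]
        d1 <- d[i1]; d2 <- d[i2]
        if (d1 <= 0) poly[[length(poly) + 1]] <- p1
        if ((d1 <= 0) != (d2 <= 0)) {
          t <- d1 / (d1 - d2)
          poly[[length(poly) + 1]] <- p1 + t * (p2 - p1)
        }
      }
      if (length(poly) >= 3) {
        ids <- vapply(poly, addv, integer(1))
        for (t in seq_len(length(ids) - 2)) {
          out_f[[length(out_f) + 1]] <- c(ids[1], ids[t + 1], ids[t + 2])
        }
      }
    }
  }
  if (length(out_f) == 0) {
    return(surface_mesh(matrix(numeric(0), ncol = 3),
                        matrix(integer(0), ncol = 3), name = mesh$name))
  }
  surface_mesh(do.call(rbind, out_v), do.call(rbind, out_f),
               name = mesh$name)
}

#' Export a mesh to STL, PLY or OBJ
#'
#' ASCII formats; the format is taken from the file extension unless given.
#' STL stores a triangle soup (vertex identity is not preserved); PLY and
#' OBJ preserve the vertex list. Coordinates are written in um with 6
#' decimals.
#'
#' @param mesh a `surface_mesh` with at least one face.
#' @param path output file.
#' @param format `"stl"`, `"ply"` or `"obj"` (default: from extension).
#' @return the path, invisibly.
#' @export
export_mesh <- function(mesh, path, format = NULL) {
  if (nrow(mesh$faces) == 0) stop("refusing to export an empty mesh")
  format <- tolower(format %||% tools::file_ext(path))
  if (!format %in% c("stl", "ply", "obj")) {
    stop("unsupported mesh format '", format, "'")
  }
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "stl") {
    name <- mesh$name %||% "mesh"
    writeLines(paste("solid", name), con)
    for (r in seq_len(nrow(f))) {
      a <- v[f[r, 1], ]; b <- v[f[r, 2], ]; c <- v[f[r, 3], ]
      n <- pracma_cross(b - a, c - a)
      nl <- sqrt(sum(n^2)); if (nl > 0) n <- n / nl
      writeLines(c(
        sprintf("  facet normal %.6e %.6e %.6e", n[1], n[2], n[3]),
        "    outer loop",
        sprintf("      vertex %.6f %.6f %.6f", a[1], a[2], a[3]),
        sprintf("      vertex %.6f %.6f %.6f", b[1], b[2], b[3]),
        sprintf("      vertex %.6f %.6f %.6f", c[1], c[2], c[3]),
        "    endloop",
        "  endfacet"), con)
    }
    writeLines(paste("endsolid", name), con)
  } else if (format == "ply") {
    writeLines(c("ply", "format ascii 1.0",
                 paste("element vertex", nrow(v)),
                 "property float x", "property float y", "property float z",
                 paste("element face", nrow(f)),
                 "property list uchar int vertex_indices",
                 "end_header"), con)
    writeLines(sprintf("%.6f %.6f %.6f", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L),
               con)
  } else {
    if (!is.null(mesh$name)) writeLines(paste("o", mesh$name), con)
    writeLines(sprintf("v %.6f %.6f %.6f", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  }
  invisible(path)
}

#' Read a mesh written by [export_mesh()]
#'
#' @param path STL/PLY/OBJ file.
#' @param format override the extension-derived format.
#' @return a `surface_mesh`.
#' @export
read_mesh <- function(path, format = NULL) {
  format <- tolower(format %||% tools::file_ext(path))
  lines <- readLines(path)
  if (format == "stl") {
    vl <- grep("^\\s*vertex", lines, value = TRUE)
    nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
      as.numeric(p[2:4])))
    nf <- nrow(nums) / 3
    surface_mesh(nums, matrix(seq_len(3 * nf), ncol = 3, byrow = TRUE))
  } else if (format == "ply") {
    nv <- as.integer(sub("element vertex ", "",
                         grep("^element vertex", lines, value = TRUE)))
    nf <- as.integer(sub("element face ", "",
                         grep("^element face", lines, value = TRUE)))
    hdr <- which(lines == "end_header")
    vs <- do.call(rbind, lapply(strsplit(lines[hdr + seq_len(nv)], "\\s+"),
                                function(p) as.numeric(p[1:3])))
    fs <- do.call(rbind, lapply(strsplit(lines[hdr + nv + seq_len(nf)], "\\s+"),
                                function(p) as.integer(p[2:4]) + 1L))
    surface_mesh(vs, fs)
  } else if (format == "obj") {
    vl <- grep("^v ", lines, value = TRUE)
    fl <- grep("^f ", lines, value = TRUE)
    vs <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(p)
      as.numeric(p[2:4])))
    fs <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(p)
      as.integer(sub("/.*", "", p[2:4]))))
    surface_mesh(vs, fs)
  } else {
    stop("unsupported mesh format '", format, "'")
  }
}
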