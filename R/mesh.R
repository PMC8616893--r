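#' Construct a labeled triangle surface mesh
#'
#' @param vertices n x 3 matrix of vertex positions (m).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param vertex_compartment Character compartment label per vertex.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, vertex_compartment) {
  vertices <- as_points3(vertices)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(faces) != 3L) stop("faces must be triangles", call. = FALSE)
  if (nrow(faces) > 0L && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range", call. = FALSE)
  if (length(vertex_compartment) != nrow(vertices))
    stop("one compartment label per vertex required", call. = FALSE)
  structure(list(vertices = vertices, faces = faces,
                 vertex_compartment = as.character(vertex_compartment)),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("<surface_mesh> ", nrow(x$vertices), " vertices, ",
      nrow(x$faces), " faces\n", sep = "")
  invisible(x)
}

# Parallel-transport frames along a polyline: list(tangents, normals,
# binormals), each npt x 3, tangents oriented along the polyline.
transport_frames <- function(cl) {
  npt <- nrow(cl)
  d <- diff(cl)
  seg_t <- unit_rows(d)
  tans <- matrix(0, npt, 3L)
  tans[1L, ] <- seg_t[1L, ]
  tans[npt, ] <- seg_t[npt - 1L, ]
  if (npt > 2L)
    tans[2:(npt - 1L), ] <- unit_rows(seg_t[1:(npt - 2L), , drop = FALSE] +
                                      seg_t[2:(npt - 1L), , drop = FALSE])
  nrm <- matrix(0, npt, 3L)
  nrm[1L, ] <- perp_unit(tans[1L, ])
  for (i in seq(2L, npt)) {
    # project previous normal off the new tangent
    n_prev <- nrm[i - 1L, ]
    t_i <- tans[i, ]
    n_i <- n_prev - sum(n_prev * t_i) * t_i
    if (vnorm(n_i) < 1e-12) n_i <- perp_unit(t_i)
    nrm[i, ] <- n_i / vnorm(n_i)
  }
  bin <- t(vapply(seq_len(npt), function(i) pracma_cross(tans[i, ], nrm[i, ]),
                  numeric(3)))
  list(tangents = tans, normals = nrm, binormals = bin)
}

# Capped tube for one segment. sides rings of the centerline's npt points
# (sides*npt ring vertices) plus 2 cap apexes; 2*sides*(npt-1) side faces
# plus 2*sides cap faces. Faces are wound so normals point outward.
segment_tube <- function(seg, sides) {
  cl <- seg$centerline
  npt <- nrow(cl)
  fr <- transport_frames(cl)
  theta <- 2 * pi * (seq_len(sides) - 1L) / sides
  verts <- matrix(0, sides * npt + 2L, 3L)
  for (i in seq_len(npt)) {
    ring <- cl[rep(i, sides), , drop = FALSE] +
      seg$radius * (outer(cos(theta), fr$normals[i, ]) +
                    outer(sin(theta), fr$binormals[i, ]))
    verts[((i - 1L) * sides + 1L):(i * sides), ] <- ring
  }
  apex0 <- sides * npt + 1L   # proximal cap apex
  apex1 <- sides * npt + 2L   # distal cap apex
  verts[apex0, ] <- cl[1L, ]
  verts[apex1, ] <- cl[npt, ]

  idx <- function(i, j) (i - 1L) * sides + ((j - 1L) %% sides) + 1L
  faces <- vector("list", 2L * sides * (npt - 1L) + 2L * sides)
  k <- 0L
  for (i in seq_len(npt - 1L)) {
    for (j in seq_len(sides)) {
      a <- idx(i, j); b <- idx(i, j + 1L)
      c2 <- idx(i + 1L, j); d2 <- idx(i + 1L, j + 1L)
      faces[[k <- k + 1L]] <- c(a, c2, b)
      faces[[k <- k + 1L]] <- c(b, c2, d2)
    }
  }
  for (j in seq_len(sides)) { # proximal cap faces toward -tangent
    faces[[k <- k + 1L]] <- c(apex0, idx(1L, j), idx(1L, j + 1L))
    faces[[k <- k + 1L]] <- c(apex1, idx(npt, j + 1L), idx(npt, j))
  }
  faces <- do.call(rbind, faces)
  m <- surface_mesh(verts, faces, rep(seg$compartment, nrow(verts)))
  if (mesh_signed_volume(m) < 0) m$faces <- m$faces[, c(1L, 3L, 2L)]
  m
}

#' Signed volume enclosed by a triangle mesh
#'
#' Divergence-theorem sum of signed tetrahedron volumes; positive for a
#' closed mesh with outward-oriented faces.
#'
#' @param mesh A [surface_mesh()].
#' @return Signed volume in cubic meters.
#' @export
mesh_signed_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  c2 <- v[f[, 3L], , drop = FALSE]
  cross_bc <- cbind(b[, 2] * c2[, 3] - b[, 3] * c2[, 2],
                    b[, 3] * c2[, 1] - b[, 1] * c2[, 3],
                    b[, 1] * c2[, 2] - b[, 2] * c2[, 1])
  sum(rowSums(a * cross_bc)) / 6
}

#' Sweep a vascular network into a labeled tube surface mesh
#'
#' One capped tube per segment (not a unioned watertight surface); every tube
#' is closed, outward-oriented, and its vertices carry the segment's
#' compartment label.
#'
#' @param net A [vascular_network()].
#' @param sides_per_ring Number of sides of each ring polygon (>= 3).
#' @return A [surface_mesh()].
#' @export
network_to_mesh <- function(net, sides_per_ring = 8L) {
  sides_per_ring <- as.integer(sides_per_ring)
  if (sides_per_ring < 3L) stop("sides_per_ring must be >= 3", call. = FALSE)
  parts <- lapply(net$segments, function(s) {
    validate_vessel_segment(s)
    segment_tube(s, sides_per_ring)
  })
  off <- 0L
  verts <- list(); faces <- list(); labs <- list()
  for (p in parts) {
    verts[[length(verts) + 1L]] <- p$vertices
    faces[[length(faces) + 1L]] <- p$faces + off
    labs[[length(labs) + 1L]] <- p$vertex_compartment
    off <- off + nrow(p$vertices)
  }
  surface_mesh(do.call(rbind, verts), do.call(rbind, faces),
               unlist(labs))
}

# Area-weighted per-vertex normals; rows of zeros where degenerate.
vertex_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  c2 <- v[f[, 3L], , drop = FALSE]
  e1 <- b - a; e2 <- c2 - a
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  out <- matrix(0, nrow(v), 3L)
  for (j in 1:3) {
    out[, 1] <- out[, 1] + tapply_add(fn[, 1], f[, j], nrow(v))
    out[, 2] <- out[, 2] + tapply_add(fn[, 2], f[, j], nrow(v))
    out[, 3] <- out[, 3] + tapply_add(fn[, 3], f[, j], nrow(v))
  }
  unit_rows(out)
}

tapply_add <- function(vals, idx, n) {
  out <- numeric(n)
  agg <- rowsum(vals, idx)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}

#' Write a surface mesh as binary STL
#'
#' Standard 84-byte header + 50 bytes per triangle (little-endian); facet
#' normals are recomputed from the winding. STL carries no per-vertex
#' attributes, so compartment labels are not preserved (use
#' [write_vtk_polydata()] for labeled export).
#'
#' @param mesh A [surface_mesh()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stl_binary <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- charToRaw(sprintf("%-80s", "avmflow binary STL"))[1:80]
  writeBin(hdr, con)
  nf <- nrow(mesh$faces)
  writeBin(as.integer(nf), con, size = 4L, endian = "little")
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]; b <- v[f[, 2L], , drop = FALSE]
  c2 <- v[f[, 3L], , drop = FALSE]
  e1 <- b - a; e2 <- c2 - a
  n <- unit_rows(cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                       e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                       e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]))
  block <- cbind(n, a, b, c2)
  for (i in seq_len(nf)) {
    writeBin(as.numeric(block[i, ]), con, size = 4L, endian = "little")
    writeBin(raw(2L), con)
  }
  invisible(path)
}

#' Write a surface mesh as legacy ASCII VTK PolyData
#'
#' Emits POINTS, POLYGONS and a per-vertex integer `compartment` attribute
#' (0 = artery, 1 = feeder, 2 = nidus, 3 = drainer, 4 = vein).
#'
#' @param mesh A [surface_mesh()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vtk_polydata <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  writeLines(c("# vtk DataFile Version 3.0",
               "avmflow surface mesh", "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d double", nv)), con)
  writeLines(apply(mesh$vertices, 1L, function(p)
    sprintf("%.12g %.12g %.12g", p[1], p[2], p[3])), con)
  writeLines(sprintf("POLYGONS %d %d", nf, 4L * nf), con)
  f0 <- mesh$faces - 1L
  writeLines(sprintf("3 %d %d %d", f0[, 1L], f0[, 2L], f0[, 3L]), con)
  comp_int <- match(mesh$vertex_compartment, compartments()) - 1L
  writeLines(c(sprintf("POINT_DATA %d", nv),
               "SCALARS compartment int 1", "LOOKUP_TABLE default",
               sprintf("%d", comp_int)), con)
  invisible(path)
}
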