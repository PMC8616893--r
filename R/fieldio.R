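#' Construct a Cartesian velocity grid
#'
#' The in-memory form of a VF 3D texture: a [grid_spec()] plus one
#' 3-component velocity vector per voxel, stored as an `n_voxels x 3` matrix
#' in x-fastest linear order. Velocities are zero outside the lumen.
#'
#' @param spec A [grid_spec()].
#' @param vectors `n_voxels x 3` numeric matrix (m/s); defaults to all-zero.
#' @return Object of class `velocity_grid`.
#' @export
velocity_grid <- function(spec, vectors = NULL) {
  nv <- n_voxels(spec)
  if (is.null(vectors)) vectors <- matrix(0, nv, 3L)
  vectors <- as.matrix(vectors)
  storage.mode(vectors) <- "double"
  if (nrow(vectors) != nv || ncol(vectors) != 3L)
    stop("vectors must be n_voxels x 3", call. = FALSE)
  if (!all(is.finite(vectors)))
    stop("velocity components must all be finite", call. = FALSE)
  structure(list(spec = spec, vectors = vectors), class = "velocity_grid")
}

#' @export
print.velocity_grid <- function(x, ...) {
  sp <- sqrt(rowSums(x$vectors^2))
  cat(sprintf("<velocity_grid> %d x %d x %d, step %g mm, %d non-zero voxels, max speed %.3g m/s\n",
              x$spec$dims[1], x$spec$dims[2], x$spec$dims[3],
              x$spec$step * 1e3, sum(sp > 0), max(sp)))
  invisible(x)
}

#' Reconstruct a 3D velocity field from a network flow solution
#'
#' Fills every lumen voxel with the laminar Poiseuille profile of its
#' nearest segment: axial velocity `2 * v_mean * (1 - (d/r)^2)` along the
#' local centerline tangent, where `d` is the distance to the centerline —
#' twice the mean velocity on the axis, zero at the wall (no slip). Voxels
#' outside every lumen stay zero. The expensive geometry search can be
#' reused across embolization variants by passing a precomputed
#' [lumen_index()].
#'
#' @param net A [vascular_network()].
#' @param solution A [solve_flow()] result on this network.
#' @param spec A [grid_spec()]; defaults to the network's lumen bounding box
#'   at 0.2 mm.
#' @param index Optional [lumen_index()] for `spec` (computed if missing).
#' @return A [velocity_grid()].
#' @export
reconstruct_velocity_field <- function(net, solution,
                                       spec = default_grid_spec(net),
                                       index = NULL) {
  if (is.null(index)) index <- lumen_index(net, spec)
  spec <- index$spec
  vec <- matrix(0, n_voxels(spec), 3L)
  if (length(index$voxel) > 0L) {
    vmean <- solution$mean_velocity[as.character(index$segment_id)]
    vmean[is.na(vmean)] <- 0  # blocked/cut-off segments carry no flow
    v_axis <- 2 * vmean * (1 - index$frac^2)
    vec[index$voxel, ] <- index$tangent * v_axis
  }
  velocity_grid(spec, vec)
}

#' Resample scattered point-sampled velocities onto a Cartesian grid
#'
#' Mesh-free, order-independent mapping of externally simulated velocity
#' samples (e.g. read from a legacy ASCII VTK file) to voxels: each voxel
#' takes the arithmetic mean of the sample vectors whose points fall inside
#' it; voxels with no samples stay zero. The level of detail is set by
#' `spec$step`. Samples outside the grid are counted and reported in the
#' `n_outside` attribute, not fatal.
#'
#' @param points `n x 3` sample positions (m).
#' @param vectors `n x 3` sample velocities (m/s).
#' @param spec A [grid_spec()].
#' @return A [velocity_grid()] with attribute `n_outside`.
#' @export
resample_points_to_grid <- function(points, vectors, spec) {
  points <- as_points3(points)
  vectors <- as_points3(vectors)
  if (nrow(points) != nrow(vectors))
    stop("points and vectors must have equal row counts", call. = FALSE)
  d <- spec$dims
  # voxel i covers centers origin + (i-1)*step, half-open bins around centers
  ijk <- sweep(sweep(points, 2L, spec$origin), 2L, spec$step, "/")
  ijk <- round(ijk)
  inside <- ijk[, 1L] >= 0 & ijk[, 1L] < d[1L] &
            ijk[, 2L] >= 0 & ijk[, 2L] < d[2L] &
            ijk[, 3L] >= 0 & ijk[, 3L] < d[3L]
  n_outside <- sum(!inside)
  vec <- matrix(0, n_voxels(spec), 3L)
  if (any(inside)) {
    lin <- ijk[inside, 1L] + d[1L] * (ijk[inside, 2L] + d[2L] * ijk[inside, 3L]) + 1L
    sums <- rowsum(vectors[inside, , drop = FALSE], lin)
    counts <- rowsum(rep(1, sum(inside)), lin)
    tgt <- as.integer(rownames(sums))
    vec[tgt, ] <- sums / counts[, 1L]
  }
  g <- velocity_grid(spec, vec)
  attr(g, "n_outside") <- n_outside
  g
}

#' Write a velocity grid as a binary VF 3D-texture file
#'
#' The vector-field ("VF_F") dialect consumed by game-engine particle
#' systems: 4-byte magic `"VF_F"`, three little-endian unsigned 16-bit
#' dimensions (x, y, z), then `nx*ny*nz` vectors of three little-endian
#' 32-bit IEEE-754 floats with the x index varying fastest, then y, then z.
#' File size is exactly `10 + 12*nx*ny*nz` bytes.
#'
#' @param grid A [velocity_grid()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vf <- function(grid, path) {
  d <- grid$spec$dims
  if (any(d > 65535L)) stop("dims exceed 16-bit VF header", call. = FALSE)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("VF_F"), con)
  d16 <- ifelse(d > 32767L, d - 65536L, d)  # two's-complement for writeBin
  writeBin(as.integer(d16), con, size = 2L, endian = "little")
  # row-major x-fastest: t(vectors) interleaves (vx, vy, vz) per voxel
  writeBin(as.numeric(t(grid$vectors)), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a binary VF vector-field file
#'
#' Inverse of [write_vf()]; validates the `"VF_F"` magic and that the
#' payload holds exactly `nx*ny*nz` float triplets. The grid's world
#' placement is not stored in a VF file, so `origin`/`step` are taken from
#' the arguments.
#'
#' @param path VF file path.
#' @param origin,step Spatial placement to attach (defaults: zero origin,
#'   0.2 mm step).
#' @return A [velocity_grid()].
#' @export
read_vf <- function(path, origin = c(0, 0, 0), step = 2e-4) {
  sz <- file.info(path)$size
  if (is.na(sz)) stop("cannot read ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 4L))
  if (!identical(magic, "VF_F"))
    stop("not a VF_F vector-field file (magic '", magic, "')", call. = FALSE)
  d <- readBin(con, "integer", 3L, size = 2L, signed = FALSE,
               endian = "little")
  expected <- 10 + 12 * prod(as.numeric(d))
  if (sz != expected)
    stop("truncated or oversized VF payload: expected ", expected,
         " bytes, file has ", sz, call. = FALSE)
  n <- prod(as.numeric(d))
  vals <- readBin(con, "numeric", 3L * n, size = 4L, endian = "little")
  velocity_grid(grid_spec(origin, step, d), matrix(vals, ncol = 3L, byrow = TRUE))
}

#' Read points and vectors from a legacy ASCII VTK file
#'
#' Supports the legacy ASCII dialect with a `POINTS` section and a
#' 3-component point-data `VECTORS` section — the intermediate the external
#' CFD results are exported to before VF conversion. Binary or XML VTK
#' variants are rejected as unsupported.
#'
#' @param path VTK file path.
#' @return List with `points` and `vectors` (each n x 3 matrices).
#' @export
read_vtk_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) >= 3L && toupper(trimws(lines[3L])) == "BINARY")
    stop("binary legacy VTK is unsupported; export ASCII", call. = FALSE)
  if (any(grepl("^\\s*<\\?xml|^\\s*<VTKFile", lines[seq_len(min(3L, length(lines)))])))
    stop("XML VTK dialects are unsupported; export legacy ASCII", call. = FALSE)
  toks_after <- function(start, n_num) {
    vals <- numeric(0)
    i <- start
    while (length(vals) < n_num) {
      if (i > length(lines))
        stop("truncated VTK data: expected ", n_num, " numbers, found ",
             length(vals), call. = FALSE)
      tok <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
      tok <- tok[nzchar(tok)]
      if (length(tok) > 0L) {
        nums <- suppressWarnings(as.numeric(tok))
        if (any(is.na(nums)))
          stop("truncated VTK data: expected ", n_num, " numbers, found ",
               length(vals), " before non-numeric line ", i, call. = FALSE)
        vals <- c(vals, nums)
      }
      i <- i + 1L
    }
    if (length(vals) > n_num)
      stop("malformed VTK data block: more numbers than declared", call. = FALSE)
    vals
  }
  pts_line <- grep("^\\s*POINTS\\s+", lines)
  if (length(pts_line) == 0L) stop("no POINTS section found", call. = FALSE)
  np <- as.integer(strsplit(trimws(lines[pts_line[1L]]), "\\s+")[[1L]][2L])
  points <- matrix(toks_after(pts_line[1L] + 1L, 3L * np), ncol = 3L,
                   byrow = TRUE)
  vec_line <- grep("^\\s*VECTORS\\s+", lines)
  if (length(vec_line) == 0L)
    stop("no VECTORS point-data section found", call. = FALSE)
  vectors <- matrix(toks_after(vec_line[1L] + 1L, 3L * np), ncol = 3L,
                    byrow = TRUE)
  list(points = points, vectors = vectors)
}

#' Write points and vectors as a legacy ASCII VTK PolyData point cloud
#'
#' @param points,vectors `n x 3` matrices.
#' @param path Output path.
#' @param name Name of the VECTORS attribute (default "velocity").
#' @return `path`, invisibly.
#' @export
write_vtk_points <- function(points, vectors, path, name = "velocity") {
  points <- as_points3(points); vectors <- as_points3(vectors)
  n <- nrow(points)
  con <- file(path, "w")
  on.exit(close(con))
  fmt3 <- function(m) sprintf("%.12g %.12g %.12g", m[, 1L], m[, 2L], m[, 3L])
  writeLines(c("# vtk DataFile Version 3.0", "avmflow point samples",
               "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d double", n), fmt3(points),
               sprintf("VERTICES %d %d", n, 2L * n),
               sprintf("1 %d", seq_len(n) - 1L),
               sprintf("POINT_DATA %d", n),
               sprintf("VECTORS %s double", name), fmt3(vectors)), con)
  invisible(path)
}

#' Write a velocity grid as legacy ASCII VTK STRUCTURED_POINTS
#'
#' @param grid A [velocity_grid()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vtk_structured_points <- function(grid, path) {
  sp <- grid$spec
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "avmflow velocity grid",
               "ASCII", "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", sp$dims[1], sp$dims[2], sp$dims[3]),
               sprintf("ORIGIN %.12g %.12g %.12g", sp$origin[1], sp$origin[2],
                       sp$origin[3]),
               sprintf("SPACING %.12g %.12g %.12g", sp$step, sp$step, sp$step),
               sprintf("POINT_DATA %d", n_voxels(sp)),
               "VECTORS velocity double",
               sprintf("%.12g %.12g %.12g", grid$vectors[, 1L],
                       grid$vectors[, 2L], grid$vectors[, 3L])), con)
  invisible(path)
}
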