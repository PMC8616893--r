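#' Particle system configuration
#'
#' Mirrors the adjustable properties of the visualization particle system:
#' spawn rate, the cap on simultaneously existing particles (2 million by
#' default), particle lifetime and display size, the integrator and its time
#' step, and a seed making the whole simulation trace deterministic.
#'
#' @param spawn_rate Particles per second (>= 0).
#' @param max_alive Cap on simultaneously alive particles (>= 1; default
#'   2e6).
#' @param lifetime Particle lifetime in seconds (> 0).
#' @param particle_size Display size in meters (rendering metadata only).
#' @param seed Integer seed for spawn-position sampling.
#' @param integrator `"euler"` or `"rk4"`.
#' @param dt Time step in seconds (> 0).
#' @return Object of class `particle_config`.
#' @export
particle_config <- function(spawn_rate = 1e5, max_alive = 2e6, lifetime = 2,
                            particle_size = 1e-4, seed = 1L,
                            integrator = c("rk4", "euler"), dt = 0.01) {
  integrator <- match.arg(integrator)
  if (spawn_rate < 0) stop("spawn_rate must be >= 0", call. = FALSE)
  if (max_alive < 1) stop("max_alive must be >= 1", call. = FALSE)
  if (lifetime <= 0) stop("lifetime must be > 0", call. = FALSE)
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  structure(list(spawn_rate = spawn_rate, max_alive = as.numeric(max_alive),
                 lifetime = lifetime, particle_size = particle_size,
                 seed = as.integer(seed), integrator = integrator, dt = dt),
            class = "particle_config")
}

#' Empty particle population
#'
#' Positions, velocities, ages and alive flags are congruent arrays; the
#' state also carries the fractional spawn accumulator and the private RNG
#' stream that makes spawning deterministic.
#'
#' @param config A [particle_config()] (seeds the spawn RNG stream).
#' @return Object of class `particle_state`.
#' @export
particle_state <- function(config = particle_config()) {
  rng <- withr::with_seed(config$seed, .Random.seed)
  structure(list(positions = matrix(0, 0L, 3L),
                 velocities = matrix(0, 0L, 3L),
                 ages = numeric(0),
                 alive = logical(0),
                 spawn_accum = 0,
                 rng = rng),
            class = "particle_state")
}

#' Number of alive particles
#' @param state A [particle_state()].
#' @return Integer count.
#' @export
n_alive <- function(state) sum(state$alive)

#' @export
print.particle_state <- function(x, ...) {
  cat(sprintf("<particle_state> %d alive / %d slots, age range [%.3g, %.3g] s\n",
              n_alive(x), length(x$alive),
              if (n_alive(x)) min(x$ages[x$alive]) else 0,
              if (n_alive(x)) max(x$ages[x$alive]) else 0))
  invisible(x)
}

#' Spawn region: a disc
#'
#' Inflow disc (typically the inlet cross-section): particles are spawned
#' uniformly over it.
#'
#' @param center Numeric length-3 (m).
#' @param normal Numeric length-3, disc normal (need not be unit).
#' @param radius Disc radius (m, > 0).
#' @return Object of class `spawn_disc`.
#' @export
spawn_disc <- function(center, normal, radius) {
  if (radius <= 0) stop("disc radius must be > 0", call. = FALSE)
  structure(list(center = as.numeric(center),
                 normal = as.numeric(normal) / vnorm(as.numeric(normal)),
                 radius = as.numeric(radius)),
            class = "spawn_disc")
}

#' Spawn region: the lumen mask
#'
#' Particles are spawned uniformly over the inside voxels (jittered within
#' each voxel cube).
#'
#' @param mask Logical array from [voxelize_lumen()].
#' @param spec The matching [grid_spec()].
#' @return Object of class `spawn_mask`.
#' @export
spawn_mask <- function(mask, spec) {
  structure(list(voxels = which(mask), spec = spec), class = "spawn_mask")
}

sample_region <- function(region, n) {
  if (inherits(region, "spawn_disc")) {
    u <- perp_unit(region$normal)
    v <- pracma_cross(region$normal, u)
    rad <- region$radius * sqrt(runif(n))
    th <- 2 * pi * runif(n)
    outer(rad * cos(th), u) + outer(rad * sin(th), v) +
      rep(region$center, each = n)
  } else if (inherits(region, "spawn_mask")) {
    if (length(region$voxels) == 0L)
      stop("spawn mask has no inside voxels", call. = FALSE)
    lin <- region$voxels[sample.int(length(region$voxels), n, replace = TRUE)]
    voxel_centers(region$spec, lin) +
      matrix(runif(3L * n, -0.5, 0.5) * region$spec$step, n, 3L)
  } else stop("unsupported spawn region", call. = FALSE)
}

#' Spawn new particles
#'
#' Adds `floor`-accumulated `spawn_rate * dt` particles uniformly over the
#' spawn region with age 0 (the residual fraction is carried to the next
#' call). Spawning never pushes the alive count past `max_alive`: the excess
#' is suppressed. Sampling is deterministic in the state's private RNG
#' stream, seeded from `config$seed`. If a velocity grid is supplied the
#' initial velocity is looked up at the spawn position, else it is zero.
#'
#' @param state A [particle_state()].
#' @param config A [particle_config()].
#' @param region A [spawn_disc()] or [spawn_mask()].
#' @param dt Time step (s); defaults to `config$dt`.
#' @param grid Optional [velocity_grid()] for initial velocities.
#' @return The updated `particle_state`.
#' @export
spawn <- function(state, config, region, dt = config$dt, grid = NULL) {
  acc <- state$spawn_accum + config$spawn_rate * dt
  n_new <- floor(acc)
  state$spawn_accum <- acc - n_new
  n_add <- min(n_new, config$max_alive - n_alive(state))
  if (n_add <= 0L) return(state)
  old_rng <- get0(".Random.seed", envir = globalenv())
  assign(".Random.seed", state$rng, envir = globalenv())
  pos <- sample_region(region, n_add)
  state$rng <- get(".Random.seed", envir = globalenv())
  if (!is.null(old_rng)) assign(".Random.seed", old_rng, envir = globalenv())
  vel <- if (is.null(grid)) matrix(0, n_add, 3L) else
    sample_velocity(grid, pos)
  dead <- which(!state$alive)
  reuse <- head(dead, n_add)
  if (length(reuse) > 0L) {
    take <- seq_along(reuse)
    state$positions[reuse, ] <- pos[take, , drop = FALSE]
    state$velocities[reuse, ] <- vel[take, , drop = FALSE]
    state$ages[reuse] <- 0
    state$alive[reuse] <- TRUE
  }
  n_app <- n_add - length(reuse)
  if (n_app > 0L) {
    app <- seq(n_add - n_app + 1L, n_add)
    state$positions <- rbind(state$positions, pos[app, , drop = FALSE])
    state$velocities <- rbind(state$velocities, vel[app, , drop = FALSE])
    state$ages <- c(state$ages, numeric(n_app))
    state$alive <- c(state$alive, rep(TRUE, n_app))
  }
  state
}

#' Sample a velocity grid at arbitrary positions
#'
#' Trilinear interpolation between the eight surrounding voxel centers;
#' coordinates outside the grid are clamped to the edge.
#'
#' @param grid A [velocity_grid()].
#' @param points `n x 3` positions (m).
#' @param mode `"trilinear"` (default) or `"nearest"`.
#' @return `n x 3` velocities (m/s).
#' @export
sample_velocity <- function(grid, points, mode = c("trilinear", "nearest")) {
  mode <- match.arg(mode)
  points <- as_points3(points)
  sp <- grid$spec
  d <- sp$dims
  u <- sweep(sweep(points, 2L, sp$origin), 2L, sp$step, "/")
  u[, 1L] <- clamp(u[, 1L], 0, d[1L] - 1L)
  u[, 2L] <- clamp(u[, 2L], 0, d[2L] - 1L)
  u[, 3L] <- clamp(u[, 3L], 0, d[3L] - 1L)
  if (mode == "nearest") {
    i <- round(u)
    lin <- i[, 1L] + d[1L] * (i[, 2L] + d[2L] * i[, 3L]) + 1L
    return(grid$vectors[lin, , drop = FALSE])
  }
  i0 <- matrix(0, nrow(u), 3L)
  for (a in 1:3) i0[, a] <- pmax(pmin(floor(u[, a]), d[a] - 2L), 0L)
  f <- clamp(u - i0, 0, 1)
  out <- matrix(0, nrow(points), 3L)
  for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
    w <- (if (cx) f[, 1L] else 1 - f[, 1L]) *
         (if (cy) f[, 2L] else 1 - f[, 2L]) *
         (if (cz) f[, 3L] else 1 - f[, 3L])
    ix <- pmin(i0[, 1L] + cx, d[1L] - 1L)
    iy <- pmin(i0[, 2L] + cy, d[2L] - 1L)
    iz <- pmin(i0[, 3L] + cz, d[3L] - 1L)
    lin <- ix + d[1L] * (iy + d[2L] * iz) + 1L
    out <- out + grid$vectors[lin, , drop = FALSE] * w
  }
  out
}

#' Advance the particle population one time step
#'
#' The "update" stage: every alive particle is moved by the configured
#' integrator (explicit Euler or classical RK4) sampling the trilinearly
#' interpolated velocity field, and its age grows by `dt`. Particles whose
#' age exceeds the lifetime, or that land in a voxel with exactly zero
#' velocity (outside the lumen), are killed.
#'
#' @param state A [particle_state()].
#' @param grid A [velocity_grid()].
#' @param config A [particle_config()].
#' @return The updated `particle_state`.
#' @export
advect_step <- function(state, grid, config) {
  idx <- which(state$alive)
  if (length(idx) > 0L) {
    p <- state$positions[idx, , drop = FALSE]
    dt <- config$dt
    if (config$integrator == "euler") {
      v1 <- sample_velocity(grid, p)
      pnew <- p + dt * v1
    } else {
      k1 <- sample_velocity(grid, p)
      k2 <- sample_velocity(grid, p + (dt / 2) * k1)
      k3 <- sample_velocity(grid, p + (dt / 2) * k2)
      k4 <- sample_velocity(grid, p + dt * k3)
      pnew <- p + (dt / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    vnew <- sample_velocity(grid, pnew)
    vvox <- sample_velocity(grid, pnew, mode = "nearest")
    state$positions[idx, ] <- pnew
    state$velocities[idx, ] <- vnew
    state$ages[idx] <- state$ages[idx] + dt
    dead <- state$ages[idx] > config$lifetime | rowSums(abs(vvox)) == 0
    state$alive[idx[dead]] <- FALSE
  }
  state
}

#' Drop dead particles from the state arrays
#' @param state A [particle_state()].
#' @return A compacted `particle_state` (alive particles only).
#' @export
compact_particles <- function(state) {
  keep <- state$alive
  state$positions <- state$positions[keep, , drop = FALSE]
  state$velocities <- state$velocities[keep, , drop = FALSE]
  state$ages <- state$ages[keep]
  state$alive <- state$alive[keep]
  state
}

#' Velocity color scale
#'
#' @param kind `"rainbow"` (blue -> cyan -> green -> yellow -> red) or
#'   `"heated_body"` (black -> red -> orange -> yellow -> white).
#' @param vmin,vmax Speed range in m/s mapped onto the scale; speeds are
#'   clamped to it. `vmin < vmax` required.
#' @return Object of class `color_scale`.
#' @export
color_scale <- function(kind = c("rainbow", "heated_body"), vmin = 0,
                        vmax = 1) {
  kind <- match.arg(kind)
  if (!(vmin < vmax)) stop("vmin must be < vmax", call. = FALSE)
  structure(list(kind = kind, vmin = vmin, vmax = vmax),
            class = "color_scale")
}

# Stops at t = 0, 0.25, 0.5, 0.75, 1 with linear interpolation between.
.color_stops <- list(
  rainbow = rbind(c(0, 0, 1),    # blue
                  c(0, 1, 1),    # cyan
                  c(0, 1, 0),    # green
                  c(1, 1, 0),    # yellow
                  c(1, 0, 0)),   # red
  heated_body = rbind(c(0, 0, 0),      # black
                      c(1, 0, 0),      # red
                      c(1, 0.5, 0),    # orange
                      c(1, 1, 0),      # yellow
                      c(1, 1, 1)))     # white

eval_color_scale <- function(kind, t) {
  stops <- .color_stops[[kind]]
  t <- clamp(t, 0, 1)
  seg <- pmin(floor(t * 4) + 1, 4)
  f <- t * 4 - (seg - 1)
  stops[seg, , drop = FALSE] * (1 - f) + stops[seg + 1, , drop = FALSE] * f
}

#' Color alive particles by speed
#'
#' Speed is clamped to `[vmin, vmax]`, normalized, and mapped through the
#' documented piecewise-linear scale.
#'
#' @param state A [particle_state()].
#' @param scale A [color_scale()].
#' @return `n_alive x 3` RGB matrix in \[0, 1\].
#' @export
color_by_velocity <- function(state, scale) {
  v <- state$velocities[state$alive, , drop = FALSE]
  speed <- sqrt(rowSums(v * v))
  t <- (clamp(speed, scale$vmin, scale$vmax) - scale$vmin) /
    (scale$vmax - scale$vmin)
  out <- eval_color_scale(scale$kind, t)
  colnames(out) <- c("r", "g", "b")
  out
}

#' View-angle ghosting opacity per mesh vertex
#'
#' The ghosted-view weight that lets interior flow show through the vessel
#' wall while keeping the silhouette: `alpha = alpha_min + (1 - alpha_min) *
#' (1 - |n.v|)^k`, with `n` the unit vertex normal and `v` the unit
#' direction from the vertex to the viewpoint. Faces seen edge-on
#' (silhouette, `|n.v| = 0`) are opaque; faces seen head-on fade to
#' `alpha_min`. Vertices with degenerate normals get `alpha_min`.
#'
#' @param mesh A [surface_mesh()].
#' @param view_point Numeric length-3 viewpoint (m).
#' @param k Falloff exponent (> 0; default 2).
#' @param alpha_min Minimum opacity in \[0, 1) (default 0.05).
#' @return Numeric vector of per-vertex opacities in \[`alpha_min`, 1\].
#' @export
ghost_opacity <- function(mesh, view_point, k = 2, alpha_min = 0.05) {
  if (k <= 0) stop("k must be > 0", call. = FALSE)
  if (alpha_min < 0 || alpha_min >= 1)
    stop("alpha_min must be in [0, 1)", call. = FALSE)
  n <- vertex_normals(mesh)
  v <- unit_rows(sweep(-mesh$vertices, 2L, as.numeric(view_point), "+"))
  degen <- rowSums(n * n) == 0 | rowSums(v * v) == 0
  dot <- abs(rowSums(n * v))
  alpha <- alpha_min + (1 - alpha_min) * (1 - clamp(dot, 0, 1))^k
  alpha[degen] <- alpha_min
  alpha
}

#' Export alive particles as a VTK PolyData snapshot
#'
#' The "output" stage, written to disk instead of a renderer: a legacy
#' ASCII VTK point cloud with per-point velocity vectors, speed scalars and
#' RGB colors, alive particles only.
#'
#' @param state A [particle_state()].
#' @param colors `n_alive x 3` RGB matrix (e.g. from [color_by_velocity()]);
#'   defaults to white.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_snapshot <- function(state, colors = NULL, path) {
  keep <- state$alive
  pos <- state$positions[keep, , drop = FALSE]
  vel <- state$velocities[keep, , drop = FALSE]
  n <- nrow(pos)
  if (is.null(colors)) colors <- matrix(1, n, 3L)
  if (nrow(colors) != n)
    stop("colors must have one row per alive particle", call. = FALSE)
  speed <- sqrt(rowSums(vel * vel))
  con <- file(path, "w")
  on.exit(close(con))
  fmt3 <- function(m) if (n == 0L) character(0) else
    sprintf("%.12g %.12g %.12g", m[, 1L], m[, 2L], m[, 3L])
  writeLines(c("# vtk DataFile Version 3.0", "avmflow particle snapshot",
               "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d double", n), fmt3(pos),
               sprintf("VERTICES %d %d", n, 2L * n),
               if (n > 0L) sprintf("1 %d", seq_len(n) - 1L) else character(0),
               sprintf("POINT_DATA %d", n),
               "VECTORS velocity double", fmt3(vel),
               "SCALARS speed double 1", "LOOKUP_TABLE default",
               if (n > 0L) sprintf("%.12g", speed) else character(0),
               "COLOR_SCALARS rgb 3", fmt3(colors)), con)
  invisible(path)
}
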