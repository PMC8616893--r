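test_that("spawn accumulates rate*dt with floor semantics and respects the cap", {
  disc <- spawn_disc(c(0, 0, 0), c(1, 0, 0), 1e-3)
  cfg <- particle_config(spawn_rate = 1000, max_alive = 150, lifetime = 1,
                         dt = 0.1, seed = 2L)
  st <- particle_state(cfg)
  st <- spawn(st, cfg, disc)               # 1000 * 0.1 = 100 exactly
  expect_identical(n_alive(st), 100L)
  expect_true(all(st$ages[st$alive] == 0))
  st <- spawn(st, cfg, disc)               # 100 more, capped at 150
  expect_identical(n_alive(st), 150L)

  # zero rate adds nothing
  cfg0 <- particle_config(spawn_rate = 0, dt = 0.1, lifetime = 1, seed = 2L)
  st0 <- spawn(particle_state(cfg0), cfg0, disc)
  expect_identical(n_alive(st0), 0L)

  # fractional accumulation: 2.5/s at dt 0.2 -> 0,1,0,1 particles per call
  cfgf <- particle_config(spawn_rate = 2.5, dt = 0.2, lifetime = 1, seed = 2L)
  stf <- particle_state(cfgf)
  counts <- integer(4)
  for (i in 1:4) { stf <- spawn(stf, cfgf, disc); counts[i] <- n_alive(stf) }
  expect_identical(counts, c(0L, 1L, 1L, 2L))
})

test_that("disc spawning places particles uniformly on the disc plane", {
  disc <- spawn_disc(c(1e-3, 0, 0), c(1, 0, 0), 2e-3)
  cfg <- particle_config(spawn_rate = 5e4, dt = 0.1, lifetime = 1, seed = 5L)
  st <- spawn(particle_state(cfg), cfg, disc)
  p <- st$positions
  expect_true(all(abs(p[, 1L] - 1e-3) < 1e-12))          # in the disc plane
  rad <- sqrt(p[, 2L]^2 + p[, 3L]^2)
  expect_true(all(rad <= 2e-3 + 1e-12))
  # uniform in area: median radius ~ R/sqrt(2)
  expect_equal(median(rad), 2e-3 / sqrt(2), tolerance = 0.05)
})

test_that("spawning and the full trace are deterministic per seed", {
  disc <- spawn_disc(c(0, 0, 0), c(0, 0, 1), 1e-3)
  g <- uniform_grid(c(0.01, 0, 0), half = 0.01, step = 1e-3)
  run <- function() {
    cfg <- particle_config(spawn_rate = 1e4, dt = 0.01, lifetime = 5, seed = 77L)
    st <- particle_state(cfg)
    for (i in 1:5) {
      st <- spawn(st, cfg, disc, grid = g)
      st <- advect_step(st, g, cfg)
    }
    st
  }
  a <- run(); b <- run()
  expect_identical(a$positions, b$positions)
  expect_identical(a$ages, b$ages)
  expect_identical(a$alive, b$alive)
})

test_that("euler displacement in a uniform field is exact", {
  g <- uniform_grid(c(1, 0, 0), half = 0.5, step = 0.1)
  cfg <- particle_config(integrator = "euler", dt = 0.1, lifetime = 10, seed = 1L)
  st <- seeded_particles(rbind(c(0, 0, 0), c(0.1, 0.2, -0.1)), cfg)
  st2 <- advect_step(st, g, cfg)
  expect_identical(st2$positions - st$positions,
                   matrix(rep(c(0.1, 0, 0), each = 2L), 2L, 3L))
  expect_identical(st2$ages, c(0.1, 0.1))
})

test_that("zero field leaves positions unchanged while ages advance", {
  sp <- grid_spec(c(-0.5, -0.5, -0.5), 0.1, c(11L, 11L, 11L))
  g <- velocity_grid(sp)
  cfg <- particle_config(dt = 0.25, lifetime = 1, seed = 1L)
  st <- seeded_particles(c(0.1, 0.1, 0.1), cfg)
  st2 <- advect_step(st, g, cfg)
  expect_identical(st2$positions, st$positions)
  expect_identical(st2$ages, 0.25)
  # a zero-velocity voxel means outside the lumen: the particle is killed
  expect_false(st2$alive)
})

test_that("RK4 preserves the orbital radius on a solid rotation to 1e-6", {
  g <- rotation_grid(omega = 1, half = 0.01, step = 5e-4)
  cfg <- particle_config(integrator = "rk4", dt = 0.01, lifetime = 100, seed = 1L)
  r0 <- 5e-3
  st <- seeded_particles(c(r0, 0, 0), cfg)
  for (i in seq_len(628L)) st <- advect_step(st, g, cfg)   # one revolution
  r_end <- sqrt(sum(st$positions[1L, 1:2]^2))
  expect_lt(abs(r_end - r0) / r0, 1e-6)
  expect_true(st$alive)
})

test_that("RK4 converges at higher order than Euler on the rotation field", {
  g <- rotation_grid(omega = 1, half = 0.01, step = 5e-4)
  r0 <- 6e-3
  err_after <- function(integrator, dt, t_total = 1) {
    cfg <- particle_config(integrator = integrator, dt = dt, lifetime = 100,
                           seed = 1L)
    st <- seeded_particles(c(r0, 0, 0), cfg)
    for (i in seq_len(round(t_total / dt))) st <- advect_step(st, g, cfg)
    exact <- r0 * c(cos(t_total), sin(t_total), 0)
    sqrt(sum((st$positions[1L, ] - exact)^2))
  }
  e_eul <- c(err_after("euler", 0.02), err_after("euler", 0.01))
  e_rk4 <- c(err_after("rk4", 0.02), err_after("rk4", 0.01))
  expect_gt(e_eul[1L] / e_eul[2L], 1.7)   # ~O(dt): halving dt halves the error
  expect_lt(e_eul[1L] / e_eul[2L], 2.3)
  expect_gt(e_rk4[1L] / e_rk4[2L], 10)    # ~O(dt^4): ratio ~16
  expect_lt(e_rk4[2L], e_eul[2L] / 100)
})

test_that("age invariant: particles past their lifetime are killed", {
  g <- uniform_grid(c(0.001, 0, 0), half = 0.5, step = 0.1)
  cfg <- particle_config(spawn_rate = 100, dt = 0.1, lifetime = 0.25, seed = 3L)
  disc <- spawn_disc(c(0, 0, 0), c(1, 0, 0), 0.01)
  st <- particle_state(cfg)
  for (i in 1:6) {
    st <- spawn(st, cfg, disc)
    st <- advect_step(st, g, cfg)
    expect_true(all(st$ages[st$alive] <= cfg$lifetime + 1e-15))
  }
  # lifetime 0.25 at dt 0.1: nobody survives more than 3 steps
  expect_true(all(st$ages[st$alive] <= 0.3))
  st_c <- compact_particles(st)
  expect_identical(n_alive(st_c), n_alive(st))
  expect_identical(length(st_c$alive), n_alive(st))
})

test_that("color scales hit their documented endpoints and mid-stops", {
  sc_r <- color_scale("rainbow", vmin = 0, vmax = 2)
  sc_h <- color_scale("heated_body", vmin = 0, vmax = 2)
  cfg <- particle_config(seed = 1L)
  st <- seeded_particles(rbind(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0)), cfg)
  st$velocities <- rbind(c(0, 0, 0), c(1, 0, 0), c(5, 0, 0))  # 0, mid, clamped
  cr <- color_by_velocity(st, sc_r)
  expect_equal(unname(cr[1L, ]), c(0, 0, 1))   # vmin -> blue
  expect_equal(unname(cr[2L, ]), c(0, 1, 0))   # midpoint -> green
  expect_equal(unname(cr[3L, ]), c(1, 0, 0))   # clamped at vmax -> red
  ch <- color_by_velocity(st, sc_h)
  expect_equal(unname(ch[1L, ]), c(0, 0, 0))   # vmin -> black
  expect_equal(unname(ch[3L, ]), c(1, 1, 1))   # vmax -> white
  expect_error(color_scale("rainbow", 1, 1), "vmin")
})

test_that("ghost opacity follows the view-angle formula", {
  # a flat square in the xy plane: normals along z
  mesh <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
                       rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)),
                       rep("artery", 4L))
  # viewpoint straight above the far corner vertex: |n.v| = 1 there
  a_top <- ghost_opacity(mesh, view_point = c(0, 0, 10), k = 2, alpha_min = 0.1)
  expect_equal(a_top[1L], 0.1, tolerance = 1e-9)
  # viewpoint in the mesh plane: |n.v| = 0 -> silhouette, alpha = 1
  a_side <- ghost_opacity(mesh, view_point = c(10, 0, 0), k = 2, alpha_min = 0.1)
  expect_equal(a_side[1L], 1, tolerance = 1e-9)
  # |n.v| = 0.5, k = 2, alpha_min = 0 -> 0.25
  a45 <- ghost_opacity(mesh, view_point = c(0, 0, 10), k = 2, alpha_min = 0)
  v <- c(0, sqrt(3) / 2, 0.5); v <- v / sqrt(sum(v^2))   # direction with nz = 0.5
  mesh1 <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                        matrix(c(1L, 2L, 3L), 1L), rep("vein", 3L))
  av <- ghost_opacity(mesh1, view_point = 10 * v, k = 2, alpha_min = 0)
  expect_equal(av[1L], (1 - 0.5)^2, tolerance = 1e-3)
  expect_error(ghost_opacity(mesh, c(0, 0, 1), k = 0), "k must be")
})

test_that("snapshots export alive particles only and re-read to 12 digits", {
  cfg <- particle_config(seed = 9L)
  st <- seeded_particles(matrix(runif(30, -0.01, 0.01), 10L, 3L), cfg)
  st$velocities <- matrix(rnorm(30), 10L, 3L)
  st$alive[c(2L, 5L)] <- FALSE
  f <- withr::local_tempfile(fileext = ".vtk")
  export_snapshot(st, colors = NULL, path = f)
  lines <- readLines(f)
  expect_true(any(grepl("^POINTS 8 double$", lines)))
  rt <- read_vtk_ascii(f)
  expect_equal(rt$points, st$positions[st$alive, ], tolerance = 1e-11)
  expect_equal(rt$vectors, st$velocities[st$alive, ], tolerance = 1e-11)

  # zero alive particles still yields a valid file
  st0 <- particle_state(cfg)
  f0 <- withr::local_tempfile(fileext = ".vtk")
  export_snapshot(st0, path = f0)
  expect_true(any(grepl("^POINTS 0 double$", readLines(f0))))
})
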