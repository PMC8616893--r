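# Shared fixtures: small analytic networks and fields built in code.

# Straight tube along x: one segment, r (m), L (m), given compartment.
straight_tube_network <- function(r = 1e-3, L = 0.02, compartment = "feeder") {
  seg <- vessel_segment(1L, "a", "b", r,
                        cbind(c(0, L), 0, 0), compartment)
  vascular_network(list(a = c(0, 0, 0), b = c(L, 0, 0)), list(seg), "a", "b")
}

# inlet --artery-- A ==two identical feeders== B --vein-- out.
# The feeders bow symmetrically up/down, so radii AND lengths are equal.
parallel_feeder_network <- function(r_feeder = 5e-4, bow = 2e-3) {
  nodes <- list(inlet = c(0, 0, 0), A = c(0.005, 0, 0),
                B = c(0.015, 0, 0), out = c(0.02, 0, 0))
  cl_up <- rbind(nodes$A, c(0.010, bow, 0), nodes$B)
  cl_dn <- rbind(nodes$A, c(0.010, -bow, 0), nodes$B)
  segs <- list(
    vessel_segment(1L, "inlet", "A", 1.5e-3, rbind(nodes$inlet, nodes$A), "artery"),
    vessel_segment(2L, "A", "B", r_feeder, cl_up, "feeder"),
    vessel_segment(3L, "A", "B", r_feeder, cl_dn, "feeder"),
    vessel_segment(4L, "B", "out", 1.2e-3, rbind(nodes$B, nodes$out), "vein"))
  vascular_network(nodes, segs, "inlet", "out")
}

# Three feeders with distinct diameters/path distances for the ordering
# heuristic: A small+proximal, C mid, B large+distal.
three_feeder_network <- function() {
  nodes <- list(inlet = c(0, 0, 0), hubA = c(0.010, 0, 0),
                hubC = c(0.015, 0, 0), hubB = c(0.020, 0, 0),
                N = c(0.025, 0.005, 0), out = c(0.035, 0.005, 0))
  seg <- function(id, p, d, r, comp)
    vessel_segment(id, p, d, r, rbind(nodes[[p]], nodes[[d]]), comp)
  segs <- list(
    seg(1L, "inlet", "hubA", 1.5e-3, "artery"),
    seg(2L, "hubA", "hubC", 1.4e-3, "artery"),
    seg(3L, "hubC", "hubB", 1.3e-3, "artery"),
    seg(4L, "hubA", "N", 0.25e-3, "feeder"),   # d = 0.5 mm, most proximal
    seg(5L, "hubC", "N", 0.35e-3, "feeder"),   # d = 0.7 mm
    seg(6L, "hubB", "N", 0.50e-3, "feeder"),   # d = 1.0 mm, most distal
    seg(7L, "N", "out", 1e-3, "drainer"))
  vascular_network(nodes, segs, "inlet", "out")
}

# Solid-rotation velocity grid v = omega x r about the z axis through the
# origin; linear in position, hence exact under trilinear interpolation.
rotation_grid <- function(omega = 1, half = 0.01, step = 5e-4) {
  n <- 2L * round(half / step) + 1L
  sp <- grid_spec(c(-half, -half, -half), step, c(n, n, n))
  ctr <- avmflow:::voxel_centers(sp)
  velocity_grid(sp, cbind(-omega * ctr[, 2L], omega * ctr[, 1L], 0))
}

uniform_grid <- function(v = c(1, 0, 0), half = 0.5, step = 0.1) {
  n <- 2L * round(half / step) + 1L
  sp <- grid_spec(c(-half, -half, -half), step, c(n, n, n))
  velocity_grid(sp, matrix(rep(v, each = n^3), ncol = 3L))
}

# Round a matrix through IEEE-754 single precision (VF payload precision).
as_float32 <- function(m) {
  matrix(readBin(writeBin(as.numeric(m), raw(), size = 4L),
                 "numeric", length(m), size = 4L), nrow = nrow(m))
}

# Place k particles directly (bypassing spawn) for integrator tests.
seeded_particles <- function(positions, config) {
  st <- particle_state(config)
  positions <- matrix(positions, ncol = 3L)
  st$positions <- positions
  st$velocities <- matrix(0, nrow(positions), 3L)
  st$ages <- numeric(nrow(positions))
  st$alive <- rep(TRUE, nrow(positions))
  st
}
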