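test_that("reconstructed field has the Poiseuille profile shape", {
  net <- straight_tube_network(r = 1e-3, L = 0.02)
  sol <- solve_flow(net)
  spec <- grid_spec(c(0, -1.2e-3, -1.2e-3), 1e-4, c(201L, 25L, 25L))
  g <- reconstruct_velocity_field(net, sol, spec)
  v_mean <- unname(sol$mean_velocity["1"])
  # on-axis voxel: speed 2 v_mean along +x
  on_axis <- sample_velocity(g, cbind(0.01, 0, 0), mode = "nearest")
  expect_equal(unname(on_axis[1, ]), c(2 * v_mean, 0, 0), tolerance = 1e-6)
  # voxel at d = r: zero (no slip); beyond r: outside the lumen, zero too
  at_wall <- sample_velocity(g, cbind(0.01, 1e-3, 0), mode = "nearest")
  expect_lt(abs(at_wall[1, 1]) / (2 * v_mean), 0.05)
  outside <- sample_velocity(g, cbind(0.01, 2e-3, 0), mode = "nearest")
  expect_identical(unname(outside[1, ]), c(0, 0, 0))
})

test_that("grid-summed cross-sectional flux matches Q within 5% at step <= r/5", {
  r <- 1e-3
  net <- straight_tube_network(r = r, L = 0.02)
  sol <- solve_flow(net)
  Q <- unname(sol$segment_flow["1"])
  for (step in c(r / 5, r / 10)) {
    g <- reconstruct_velocity_field(net, sol, default_grid_spec(net, step))
    d <- g$spec$dims
    vx <- array(g$vectors[, 1L], dim = d)
    mid <- round(d[1L] / 2)
    flux <- sum(vx[mid, , ]) * step^2
    expect_lt(abs(flux - Q) / Q, 0.05)
  }
})

test_that("oversized grids are rejected before allocation", {
  expect_error(grid_spec(c(0, 0, 0), 1e-5, c(70000L, 4L, 4L)), "16-bit")
})

test_that("point resampling takes per-voxel means and ignores nothing silently", {
  sp <- grid_spec(c(0, 0, 0), 1e-3, c(4L, 4L, 4L))
  # one sample exactly at a voxel center
  g1 <- resample_points_to_grid(cbind(1e-3, 2e-3, 3e-3), cbind(1, 2, 3), sp)
  lin <- 1L + 4L * (2L + 4L * 3L) + 1L
  expect_equal(g1$vectors[lin, ], c(1, 2, 3))
  # two samples in one voxel average
  g2 <- resample_points_to_grid(rbind(c(0, 0, 0), c(1e-4, 0, 0)),
                                rbind(c(1, 0, 0), c(0, 1, 0)), sp)
  expect_equal(g2$vectors[1L, ], c(0.5, 0.5, 0))
  # no samples -> all zero
  g0 <- resample_points_to_grid(matrix(0, 0, 3), matrix(0, 0, 3), sp)
  expect_true(all(g0$vectors == 0))
  # out-of-bounds samples are counted, not fatal
  g3 <- resample_points_to_grid(rbind(c(0, 0, 0), c(1, 1, 1)),
                                rbind(c(1, 0, 0), c(9, 9, 9)), sp)
  expect_identical(attr(g3, "n_outside"), 1L)
  expect_equal(g3$vectors[1L, ], c(1, 0, 0))
})

test_that("resampling is order-independent", {
  sp <- grid_spec(c(0, 0, 0), 1e-3, c(5L, 5L, 5L))
  set.seed(17)
  pts <- matrix(runif(300, 0, 4e-3), 100L, 3L)
  vec <- matrix(rnorm(300), 100L, 3L)
  perm <- sample.int(100L)
  g_a <- resample_points_to_grid(pts, vec, sp)
  g_b <- resample_points_to_grid(pts[perm, ], vec[perm, ], sp)
  expect_equal(g_a$vectors, g_b$vectors)
})

test_that("VF files follow the exact binary layout and round-trip bit-exactly", {
  sp <- grid_spec(c(0, 0, 0), 2e-4, c(2L, 2L, 2L))
  set.seed(4)
  g <- velocity_grid(sp, as_float32(matrix(rnorm(24), 8L, 3L)))
  f <- withr::local_tempfile(fileext = ".vf")
  write_vf(g, f)
  expect_identical(file.info(f)$size, 4 + 6 + 8 * 12)        # 106 bytes
  con <- file(f, "rb")
  expect_identical(rawToChar(readBin(con, "raw", 4L)), "VF_F")
  expect_identical(readBin(con, "integer", 3L, size = 2L, signed = FALSE,
                           endian = "little"), c(2L, 2L, 2L))
  close(con)
  g2 <- read_vf(f, origin = sp$origin, step = sp$step)
  expect_identical(g2$vectors, g$vectors)                    # bit-exact
  expect_identical(g2$spec$dims, sp$dims)

  # larger asymmetric grid: size formula 10 + 12 nx ny nz
  sp3 <- grid_spec(c(0, 0, 0), 2e-4, c(7L, 3L, 5L))
  g3 <- velocity_grid(sp3, as_float32(matrix(rnorm(7 * 3 * 5 * 3), ncol = 3L)))
  f3 <- withr::local_tempfile(fileext = ".vf")
  write_vf(g3, f3)
  expect_identical(file.info(f3)$size, 10 + 12 * 7 * 3 * 5)
  expect_identical(read_vf(f3)$vectors, g3$vectors)
})

test_that("VF payload order is x-fastest, then y, then z", {
  sp <- grid_spec(c(0, 0, 0), 1e-3, c(2L, 2L, 1L))
  vec <- rbind(c(1, 0, 0), c(2, 0, 0), c(3, 0, 0), c(4, 0, 0))
  f <- withr::local_tempfile(fileext = ".vf")
  write_vf(velocity_grid(sp, vec), f)
  con <- file(f, "rb"); on.exit(close(con))
  invisible(readBin(con, "raw", 10L))
  payload <- readBin(con, "numeric", 12L, size = 4L, endian = "little")
  expect_equal(payload, c(1, 0, 0, 2, 0, 0, 3, 0, 0, 4, 0, 0))
})

test_that("malformed VF files are rejected with diagnostics", {
  f <- withr::local_tempfile(fileext = ".vf")
  con <- file(f, "wb")
  writeBin(charToRaw("XXXX"), con)
  writeBin(as.integer(c(1L, 1L, 1L)), con, size = 2L, endian = "little")
  writeBin(numeric(3L), con, size = 4L, endian = "little")
  close(con)
  expect_error(read_vf(f), "magic 'XXXX'")

  f2 <- withr::local_tempfile(fileext = ".vf")
  sp <- grid_spec(c(0, 0, 0), 1e-3, c(2L, 2L, 2L))
  write_vf(velocity_grid(sp), f2)
  # truncate half the payload
  full <- readBin(f2, "raw", file.info(f2)$size)
  writeBin(full[seq_len(10L + 48L)], f3 <- withr::local_tempfile())
  expect_error(read_vf(f3), "expected 106 bytes, file has 58")
})

test_that("legacy ASCII VTK point/vector files parse and round-trip", {
  # minimal hand-written legacy file with one point
  f <- withr::local_tempfile(fileext = ".vtk")
  writeLines(c("# vtk DataFile Version 3.0", "one point", "ASCII",
               "DATASET POLYDATA", "POINTS 1 float", "0.5 1.5 -2.0",
               "POINT_DATA 1", "VECTORS velocity float", "1.0 0.0 0.0"), f)
  smp <- read_vtk_ascii(f)
  expect_equal(smp$points, cbind(0.5, 1.5, -2.0))
  expect_equal(smp$vectors, cbind(1, 0, 0))

  set.seed(23)
  pts <- matrix(runif(60), 20L, 3L)
  vec <- matrix(rnorm(60), 20L, 3L)
  f2 <- withr::local_tempfile(fileext = ".vtk")
  write_vtk_points(pts, vec, f2)
  rt <- read_vtk_ascii(f2)
  expect_equal(rt$points, pts, tolerance = 1e-11)
  expect_equal(rt$vectors, vec, tolerance = 1e-11)
})

test_that("inconsistent or unsupported VTK inputs raise format errors", {
  f <- withr::local_tempfile(fileext = ".vtk")
  # 10 declared points but only 9 vector rows
  writeLines(c("# vtk DataFile Version 3.0", "bad", "ASCII",
               "DATASET POLYDATA", "POINTS 10 float",
               sprintf("%g %g %g", 1:10, 1:10, 1:10),
               "POINT_DATA 10", "VECTORS velocity float",
               sprintf("%g 0 0", 1:9)), f)
  expect_error(read_vtk_ascii(f), "truncated")

  f2 <- withr::local_tempfile(fileext = ".vtk")
  writeLines(c("# vtk DataFile Version 3.0", "no vectors", "ASCII",
               "DATASET POLYDATA", "POINTS 1 float", "0 0 0"), f2)
  expect_error(read_vtk_ascii(f2), "VECTORS")

  f3 <- withr::local_tempfile(fileext = ".vtk")
  writeLines(c("# vtk DataFile Version 3.0", "bin", "BINARY",
               "DATASET POLYDATA"), f3)
  expect_error(read_vtk_ascii(f3), "unsupported")
})

test_that("structured-points export declares the grid spec verbatim", {
  sp <- grid_spec(c(1e-3, 2e-3, 3e-3), 5e-4, c(3L, 2L, 2L))
  f <- withr::local_tempfile(fileext = ".vtk")
  write_vtk_structured_points(velocity_grid(sp), f)
  lines <- readLines(f)
  expect_true("DIMENSIONS 3 2 2" %in% lines)
  expect_true(any(grepl("^SPACING 0.0005 0.0005 0.0005$", lines)))
})
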