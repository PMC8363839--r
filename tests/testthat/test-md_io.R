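test_that("CSV trajectory dialect round-trips coordinates and box", {
  g <- gen_bilayer_trajectory(n_lipids = 20, pops_frac = 0.2, n_frames = 3,
                              seed = 7)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(g$traj, path)
  back <- read_trajectory_csv(path)
  expect_lt(max(abs(back$x - g$traj$x)), 1e-6)
  expect_lt(max(abs(back$y - g$traj$y)), 1e-6)
  expect_lt(max(abs(back$z - g$traj$z)), 1e-6)
  expect_equal(back$box, g$traj$box, tolerance = 1e-9)
  expect_identical(back$tags, g$traj$tags)
  expect_equal(back$time, g$traj$time)
})

test_that("GRO and CSV routes give the same trajectory", {
  # coordinates exact at GRO's 3-decimal precision so the routes agree exactly
  set.seed(3)
  n <- 6
  xyz <- round(matrix(runif(3 * n, 0, 9), n, 3), 3)
  tags <- c("POPC-P", "POPC-P", "POPS-P", "POPS-P", "TFP-N", "TFP-N")
  res <- sub("-.*", "", tags); atom <- sub(".*-", "", tags)
  gro <- c("toy bilayer frame", sprintf("%5d", n),
           sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", seq_len(n), res, atom,
                   seq_len(n), xyz[, 1], xyz[, 2], xyz[, 3]),
           "  10.00000  10.00000  10.00000")
  gro_path <- withr::local_tempfile(fileext = ".gro")
  writeLines(gro, gro_path)
  t_gro <- read_trajectory(gro_path)

  csv_path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(t_gro, csv_path)
  t_csv <- read_trajectory(csv_path)
  expect_equal(t_csv$x, t_gro$x)
  expect_equal(t_csv$y, t_gro$y)
  expect_equal(t_csv$z, t_gro$z)
  expect_identical(t_csv$tags, t_gro$tags)

  expect_equal(length(select_particles(t_gro, "POPC-P|POPS-P")), 4L)
  expect_error(subset_particles(t_gro, "name P"), "selection error")
})

test_that("unsupported formats are rejected with a format error", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines("junk", f)
  expect_error(read_trajectory(f), "format error")
  g <- withr::local_tempfile(fileext = ".gro")
  writeLines("junk", g)  # exists but unparseable
  expect_error(read_trajectory("no/such/file.gro"), "format error")
  x <- withr::local_tempfile(fileext = ".xtc")
  writeLines("", x)
  s <- withr::local_tempfile(fileext = ".pdb")
  writeLines("", s)
  expect_error(read_trajectory(s, x), "XTC/TRR")
})

test_that("leaflet assignment recovers generative labels and rejects degenerate input", {
  g <- gen_bilayer_trajectory(seed = 11)
  a <- assign_leaflets(g$traj, selection = "POPC-P|POPS-P")
  lab <- g$truth$leaflet
  expect_setequal(a$upper, which(lab == "upper" & g$truth$species != "TFP"))
  expect_setequal(a$lower, which(lab == "lower" & g$truth$species != "TFP"))

  # invariant under rigid z translation of the whole system
  shifted <- g$traj
  shifted$z <- shifted$z + 3.7
  a2 <- assign_leaflets(shifted, selection = "POPC-P|POPS-P")
  expect_identical(a2$upper, a$upper)
  expect_identical(a2$lower, a$lower)

  flat <- particle_trajectory(matrix(runif(8), 1), matrix(runif(8), 1),
                              matrix(0, 1, 8), time = 0, box = c(5, 5, 5),
                              tags = rep("P", 8))
  expect_error(assign_leaflets(flat), "ambiguous-leaflet")

  two <- particle_trajectory(matrix(c(1, 2), 1), matrix(c(1, 2), 1),
                             matrix(c(1, -1), 1), time = 0, box = c(5, 5, 5),
                             tags = c("P", "P"))
  a3 <- assign_leaflets(two)
  expect_identical(a3$upper, 1L)
  expect_identical(a3$lower, 2L)
})

test_that("lateral unwrapping follows the minimum-image convention", {
  L <- 10
  # particle crossing +x boundary: 0.1 -> L - 0.1 is a -0.2 step
  tr <- particle_trajectory(matrix(c(0.1, L - 0.1), 2, 1),
                            matrix(0.5, 2, 1), matrix(1, 2, 1),
                            time = c(0, 1), box = c(L, L, L), tags = "P")
  u <- unwrap_lateral(tr)
  expect_equal(u$x[2, 1] - u$x[1, 1], -0.2)

  # stationary particles: identity
  st <- particle_trajectory(matrix(2, 5, 3), matrix(3, 5, 3),
                            matrix(1, 5, 3), time = 0:4, box = c(L, L, L),
                            tags = rep("P", 3))
  expect_equal(unwrap_lateral(st)$x, st$x)

  # constant-velocity drift wrapped many times unwraps to an exact line
  t <- 0:200
  xtrue <- 0.3 + 0.37 * t
  wrapped <- xtrue - L * floor(xtrue / L)
  dr <- particle_trajectory(matrix(wrapped, ncol = 1),
                            matrix(0.5, length(t), 1),
                            matrix(1, length(t), 1), time = t,
                            box = c(L, L, L), tags = "P")
  u <- unwrap_lateral(dr)
  expect_equal(u$x[, 1], xtrue, tolerance = 1e-12)

  # unwrap then re-wrap reproduces the original wrapped coordinates
  g <- gen_brownian(n = 50, D = 2e-2, dt = 0.1, n_frames = 80, wrap = TRUE,
                    seed = 5)
  rw <- wrap_lateral(unwrap_lateral(g$traj))
  expect_equal(rw$x, g$traj$x, tolerance = 1e-12)
  expect_equal(rw$y, g$traj$y, tolerance = 1e-12)
})

test_that("triclinic boxes and malformed trajectories are rejected", {
  gro <- c("frame", "    1",
           sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 1L, "POPC", "P", 1L,
                   1, 1, 1),
           "  10.0  10.0  10.0  0.0  0.0  1.5  0.0  0.0  0.0")
  p <- withr::local_tempfile(fileext = ".gro")
  writeLines(gro, p)
  expect_error(read_trajectory(p), "triclinic")
  expect_error(particle_trajectory(matrix(1), matrix(1), matrix(1),
                                   time = 0, box = c(-1, 5, 5), tags = "P"),
               "positive")
  expect_error(particle_trajectory(matrix(1, 2, 1), matrix(1, 2, 1),
                                   matrix(1, 2, 1), time = c(1, 1),
                                   box = c(5, 5, 5), tags = "P"),
               "strictly increasing")
})
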