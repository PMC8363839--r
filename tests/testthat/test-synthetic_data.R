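test_that("generators are seed-deterministic", {
  amp <- data.frame(m = 1, n = 0, a_cos = 0.2, a_sin = 0)
  a <- gen_surface_points(50, amplitudes = amp, noise_sd = 0.1, seed = 5)
  b <- gen_surface_points(50, amplitudes = amp, noise_sd = 0.1, seed = 5)
  expect_identical(a$points, b$points)

  t1 <- gen_bilayer_trajectory(n_frames = 4, n_tfp = 24, seed = 6)
  t2 <- gen_bilayer_trajectory(n_frames = 4, n_tfp = 24, seed = 6)
  expect_identical(t1$traj$x, t2$traj$x)
  expect_identical(t1$traj$z, t2$traj$z)

  i1 <- gen_afm_image(noise_sd = 0.3, seed = 7)
  i2 <- gen_afm_image(noise_sd = 0.3, seed = 7)
  expect_identical(i1$image$z, i2$image$z)

  # generate() dispatch reproduces the direct call
  spec <- synthetic_spec("brownian", n = 20, D = 4e-3, n_frames = 10, seed = 8)
  expect_identical(generate(spec)$traj$x,
                   gen_brownian(n = 20, D = 4e-3, n_frames = 10, seed = 8)$traj$x)
})

test_that("default bilayer composition matches the study system", {
  g <- gen_bilayer_trajectory(seed = 1)
  expect_identical(sum(g$truth$species == "POPS"), 104L)
  expect_identical(sum(g$truth$species == "POPC"), 416L)
  expect_identical(sum(g$truth$species == "POPS" &
                         g$truth$leaflet == "upper"), 52L)
  # TFP dose ratios
  expect_equal(round(tfp_lipid_ratio(24, 520), 1), 4.6)
  expect_equal(round(tfp_lipid_ratio(48, 520), 1), 9.2)
  g24 <- gen_bilayer_trajectory(n_tfp = 24, n_frames = 2, seed = 1)
  expect_identical(sum(g24$traj$tags == "TFP"), 24L)

  expect_error(gen_bilayer_trajectory(n_lipids = 521), "parameter error")
  expect_error(gen_bilayer_trajectory(n_tfp = 3), "parameter error")
})

test_that("surface generator satisfies its closed forms", {
  flat <- gen_surface_points(100, seed = 2)
  expect_true(all(flat$points$z == 0))
  expect_true(all(flat$H_fn(flat$points$x, flat$points$y) == 0))

  amp <- data.frame(m = c(1, 0), n = c(0, 2), a_cos = c(0.3, 0),
                    a_sin = c(0, 0.1))
  g <- gen_surface_points(200, amplitudes = amp, noise_sd = 0, seed = 3)
  expect_lt(max(abs(g$points$z - g$surface_fn(g$points$x, g$points$y))),
            1e-12)
  # analytic H agrees with finite differences of the surface closed form
  expect_equal(g$H_fn(g$points$x[1:20], g$points$y[1:20]),
               fd_mean_curvature(g$surface_fn, g$points$x[1:20],
                                 g$points$y[1:20]),
               tolerance = 1e-6)
  expect_error(gen_surface_points(10, noise_sd = -1), "parameter error")
})

test_that("Brownian steps have variance 2 D dt per axis", {
  D <- 6e-3; dt <- 0.1
  g <- gen_brownian(n = 1e5, D = D, dt = dt, n_frames = 2, seed = 4)
  vx <- var(g$traj$x[2, ] - g$traj$x[1, ])
  vy <- var(g$traj$y[2, ] - g$traj$y[1, ])
  expect_lt(abs(vx - 2 * D * dt) / (2 * D * dt), 0.02)
  expect_lt(abs(vy - 2 * D * dt) / (2 * D * dt), 0.02)

  expect_true(all(gen_brownian(n = 10, D = 0, n_frames = 5,
                               seed = 1)$traj$x[1, ] ==
                  gen_brownian(n = 10, D = 0, n_frames = 5,
                               seed = 1)$traj$x[5, ]))
})

test_that("wrapped Brownian output unwraps to the never-wrapped path", {
  free <- gen_brownian(n = 30, D = 2e-2, dt = 0.1, n_frames = 150, seed = 9)
  wrapped <- gen_brownian(n = 30, D = 2e-2, dt = 0.1, n_frames = 150,
                          wrap = TRUE, seed = 9)
  un <- unwrap_lateral(wrapped$traj)
  # unwrapped path equals the free path up to the image of the start point
  offx <- un$x[1, ] - free$traj$x[1, ]
  expect_lt(max(abs(sweep(un$x, 2, offx) - free$traj$x)), 1e-9)
})

test_that("AFM image generator geometry is exact", {
  g <- gen_afm_image(nx = 100, ny = 100, height = 4,
                     holes = list(list(center = c(50, 50), radius = 20)),
                     tilt = c(0, 0), noise_sd = 0, seed = 1)
  expect_identical(sort(unique(as.vector(g$image$z))), c(0, 4))
  frac <- mean(g$image$z == 0)
  analytic <- pi * 20^2 / 1e4
  expect_lt(abs(frac - analytic), (2 * pi * 20 + 1) / 1e4)  # rim discretization
  expect_error(gen_afm_image(nx = 30, ny = 30,
                             holes = list(list(center = c(15, 15),
                                               radius = 20))),
               "geometry error")
})

test_that("flat bilayers have thickness identically d0", {
  g <- gen_bilayer_trajectory(n_frames = 3, undulation = NULL, d0 = 4,
                              seed = 10)
  a <- assign_leaflets(g$traj, selection = "POPC-P|POPS-P")
  th <- average_fields(thickness_series(g$traj, a), window = 1)
  expect_lt(max(abs(th$values - 4)), 1e-9)
})

test_that("the pipeline recovers generator ground truth end to end", {
  # thickness d0 within 1%
  g <- gen_bilayer_trajectory(n_frames = 40, d0 = 4, seed = 12)
  a <- assign_leaflets(g$traj, selection = "POPC-P|POPS-P")
  th <- average_fields(thickness_series(g$traj, a), window = 0.4)
  expect_lt(abs(mean_thickness(th) - 4) / 4, 0.01)

  # POPS diffusion within 5% (trajectory regenerated at MSD-friendly length)
  gD <- gen_bilayer_trajectory(n_frames = 301, undulation = NULL, seed = 13)
  m <- compute_msd(unwrap_lateral(gD$traj), "POPS-P", max_lag_ns = 15,
                   assignment = assign_leaflets(gD$traj,
                                                selection = "POPC-P|POPS-P"))
  est <- fit_diffusion(m, t_max_ns = 15)
  expect_lt(abs(est$D_nm2ns - g$truth$D$POPS) / g$truth$D$POPS, 0.05)
})
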