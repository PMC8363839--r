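box <- c(13, 13)

test_that("Fourier fit recovers pure modes exactly without noise", {
  # DC-only surface
  g <- gen_surface_points(n = 60, z0 = 1.7, seed = 2)
  s <- fit_fourier_surface(g$points, box, M = 2)
  expect_equal(unname(s$a0), 1.7, tolerance = 1e-12)
  expect_lt(max(abs(c(s$a_cos, s$a_sin))), 1e-9)

  # single sine mode, amplitude 0.5
  amp <- data.frame(m = 1, n = 0, a_cos = 0, a_sin = 0.5)
  g <- gen_surface_points(n = 260, amplitudes = amp, seed = 3)
  s <- fit_fourier_surface(g$points, box, M = 2)
  j <- which(s$modes$m == 1 & s$modes$n == 0)
  expect_equal(unname(s$a_sin[j]), 0.5, tolerance = 1e-9)
  expect_lt(max(abs(c(s$a_cos, s$a_sin[-j]))), 1e-9)
  expect_lt(s$rms_residual, 1e-9)

  # periodicity: z(x + Lx, y) == z(x, y)
  xs <- runif(20, 0, 13); ys <- runif(20, 0, 13)
  expect_equal(eval_surface(s, xs + 13, ys), eval_surface(s, xs, ys),
               tolerance = 1e-12)
})

test_that("fit matches the brute-force normal-equations oracle", {
  set.seed(42)
  for (rep in 1:25) {
    M <- sample(1:2, 1)
    n <- sample((2 * (2 * M + 1)^2):64, 1)
    x <- runif(n, 0, box[1]); y <- runif(n, 0, box[2]); z <- rnorm(n)
    s <- fit_fourier_surface(data.frame(x = x, y = y, z = z), box, M = M)
    ref <- oracle_fourier_fit(x, y, z, box, M)
    expect_lt(max(abs(coef_vector(s) - ref)) / max(abs(ref)), 1e-8)
  }
})

test_that("amplitude estimates are unbiased under z-noise", {
  amp <- data.frame(m = 1, n = 0, a_cos = 0, a_sin = 0.5)
  est <- vapply(1:50, function(k) {
    g <- gen_surface_points(n = 260, amplitudes = amp, noise_sd = 0.1,
                            seed = 1000 + k)
    s <- fit_fourier_surface(g$points, box, M = 2)
    s$a_sin[which(s$modes$m == 1 & s$modes$n == 0)]
  }, numeric(1))
  sem <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.5), 3 * sem)
})

test_that("degenerate point sets raise fit errors", {
  pts <- data.frame(x = rep(1, 30), y = rep(2, 30), z = rnorm(30))
  expect_error(fit_fourier_surface(pts, box, M = 1), "fit error")
  few <- data.frame(x = runif(5), y = runif(5), z = runif(5))
  expect_error(fit_fourier_surface(few, box, M = 2), "fit error")
})

test_that("mean curvature matches analytic and finite-difference oracles", {
  # flat surface: H identically zero
  g <- gen_surface_points(n = 100, z0 = 2, seed = 1)
  s <- fit_fourier_surface(g$points, box, M = 2)
  H <- mean_curvature_field(s, grid = c(26, 26))
  expect_lt(max(abs(H$values)), 1e-9)

  # z = 0.5 sin(qx): extrema -+ 0.5 q^2 / 2
  amp <- data.frame(m = 1, n = 0, a_cos = 0, a_sin = 0.5)
  g <- gen_surface_points(n = 260, amplitudes = amp, seed = 3)
  s <- fit_fourier_surface(g$points, box, M = 2)
  H <- mean_curvature_field(s, grid = c(260, 260))
  q <- 2 * pi / 13
  expect_equal(max(H$values), 0.5 * q^2 / 2, tolerance = 1e-3)
  expect_equal(min(H$values), -0.5 * q^2 / 2, tolerance = 1e-3)

  # cross-check against central finite differences of the fitted surface
  xy <- grid_xy(c(26, 26))
  H26 <- mean_curvature_field(s, grid = c(26, 26))
  fd <- fd_mean_curvature(function(x, y) eval_surface(s, x, y), xy$x, xy$y)
  expect_equal(as.vector(H26$values), fd, tolerance = 1e-6)

  # curvature of a periodic surface has zero box average
  expect_lt(abs(mean(H$values)), 1e-10)
})

test_that("linearized and full Monge curvature agree at small slope", {
  amp <- data.frame(m = 1, n = 1, a_cos = 0.05, a_sin = 0.03)
  g <- gen_surface_points(n = 260, amplitudes = amp, seed = 8)
  s <- fit_fourier_surface(g$points, box, M = 2)
  xy <- grid_xy(c(26, 26))
  zx <- eval_surface(s, xy$x, xy$y, deriv = c(1L, 0L))
  zy <- eval_surface(s, xy$x, xy$y, deriv = c(0L, 1L))
  expect_lt(max(sqrt(zx^2 + zy^2)), 0.05)
  Hl <- mean_curvature_field(s, grid = c(26, 26), mode = "linearized")
  Hf <- mean_curvature_field(s, grid = c(26, 26), mode = "full")
  expect_lt(max(abs(Hl$values - Hf$values)) / max(abs(Hl$values)), 0.01)
})

test_that("Gaussian-bump curvature is recovered at the bump center", {
  dim <- list(A = 1, s = 2, center = c(6.5, 6.5))
  g <- gen_surface_points(n = 2000, dimple = dim, seed = 12)
  s <- fit_fourier_surface(g$points, box, M = 3)
  Hc <- eval_surface(s, 6.5, 6.5, deriv = c(2L, 0L)) / 2 +
    eval_surface(s, 6.5, 6.5, deriv = c(0L, 2L)) / 2
  fd <- fd_mean_curvature(g$surface_fn, 6.5, 6.5)
  expect_equal(fd, -dim$A / dim$s^2, tolerance = 1e-6)  # oracle sanity
  # fitted curvature matches within the mode-truncation error of the fit
  expect_equal(Hc, -dim$A / dim$s^2, tolerance = 0.05)
})

test_that("thickness fields subtract leaflet surfaces correctly", {
  flat_up <- fit_fourier_surface(
    gen_surface_points(100, z0 = 2, seed = 4)$points, box, 2)
  flat_lo <- fit_fourier_surface(
    gen_surface_points(100, z0 = -2, seed = 5)$points, box, 2)
  th <- thickness_field(flat_up, flat_lo)
  expect_equal(range(th$values), c(4, 4), tolerance = 1e-9)

  # parallel undulation cancels exactly
  amp <- data.frame(m = 1, n = 0, a_cos = 0, a_sin = 0.5)
  pts <- gen_surface_points(260, amplitudes = amp, seed = 6)$points
  up <- fit_fourier_surface(transform(pts, z = z + 2), box, 2)
  lo <- fit_fourier_surface(transform(pts, z = z - 2), box, 2)
  th <- thickness_field(up, lo, grid = c(52, 52))
  expect_lt(diff(range(th$values)), 1e-9)
  expect_equal(mean(th$values), 4, tolerance = 1e-9)

  # undulation of the upper leaflet only: 4 -+ 0.2
  amp2 <- data.frame(m = 1, n = 0, a_cos = 0, a_sin = 0.2)
  up2 <- fit_fourier_surface(
    gen_surface_points(260, amplitudes = amp2, z0 = 2, seed = 7)$points,
    box, 2)
  th2 <- thickness_field(up2, flat_lo, grid = c(260, 260))
  expect_equal(max(th2$values), 4.2, tolerance = 1e-3)
  expect_equal(min(th2$values), 3.8, tolerance = 1e-3)

  # swapped leaflets are caught
  expect_error(thickness_field(flat_lo, flat_up), "leaflet-order")
})

test_that("curvature footprint equals the area average of analytic H over the region", {
  # static Gaussian dimple; disk of radius s centered on it
  dim <- list(A = -1, s = 2, center = c(6.5, 6.5))
  g <- gen_surface_points(n = 2000, dimple = dim, seed = 13)
  s <- fit_fourier_surface(g$points, box, M = 4)
  H <- mean_curvature_field(s, grid = c(130, 130))
  fp <- curvature_footprint(list(H), region = list(center = dim$center,
                                                   radius = dim$s),
                            window = 1)
  # numeric integration oracle on a fine polar grid of the analytic H
  r <- seq(0.005, dim$s, by = 0.01)
  Hbar <- sum(vapply(r, function(ri) {
    ang <- seq(0, 2 * pi, length.out = 181)[-181]
    ri * mean(fd_mean_curvature(g$surface_fn, dim$center[1] + ri * cos(ang),
                                dim$center[2] + ri * sin(ang)))
  }, numeric(1))) * 0.01 * 2 * pi / (pi * dim$s^2)
  expect_equal(fp$footprint_mean, Hbar, tolerance = 0.02)
  expect_equal(fp$footprint_abs, abs(fp$footprint_mean))

  # flat fields average to zero over any region
  flat <- field2d(matrix(0, 26, 26), box, "nm^-1", "curvature")
  fp0 <- curvature_footprint(list(flat, flat),
                             region = list(center = c(3, 3), radius = 2))
  expect_identical(fp0$footprint_mean, 0)

  expect_error(curvature_footprint(list(flat),
                                   region = list(center = c(1, 1),
                                                 radius = 1e-6)),
               "aggregation error")
})

test_that("footprint region defaults to the protein bounding disk", {
  g <- gen_bilayer_trajectory(n_frames = 2, dimple = list(A = -1, s = 2,
                                                          center = c(6, 6)),
                              seed = 3)
  reg <- footprint_region(g$traj)
  expect_equal(reg$center, c(6, 6), tolerance = 1e-9)
  expect_equal(reg$radius, 2, tolerance = 1e-9)
  g0 <- gen_bilayer_trajectory(n_frames = 2, seed = 3)
  expect_null(footprint_region(g0$traj))
})
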