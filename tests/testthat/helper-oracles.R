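# Independent oracles, written separately from the package internals.

# Brute-force normal-equations Fourier fit: build the trig design directly
# and solve X'X b = X'z. Mode ordering matches fourier_modes() so
# coefficient vectors are comparable.
oracle_fourier_fit <- function(x, y, z, box, M) {
  modes <- expand.grid(m = 0:M, n = -M:M)
  modes <- modes[modes$m > 0 | (modes$m == 0 & modes$n > 0), ]
  X <- matrix(1, length(x), 1)
  for (j in seq_len(nrow(modes))) {
    th <- 2 * pi * (modes$m[j] * x / box[1] + modes$n[j] * y / box[2])
    X <- cbind(X, cos(th), sin(th))
  }
  as.numeric(solve(t(X) %*% X, t(X) %*% z))
}

coef_vector <- function(surface) {
  K <- nrow(surface$modes)
  out <- numeric(1 + 2 * K)
  out[1] <- surface$a0
  out[2 * seq_len(K)] <- surface$a_cos
  out[2 * seq_len(K) + 1] <- surface$a_sin
  out
}

# Double-loop multi-origin lateral MSD (no COM removal).
oracle_msd <- function(X, Y, origin_step, max_lag) {
  nf <- nrow(X)
  origins <- seq(1, nf, by = origin_step)
  msd <- numeric(max_lag + 1)
  for (L in seq_len(max_lag)) {
    acc <- 0; cnt <- 0
    for (o in origins) {
      if (o + L > nf) next
      acc <- acc + mean((X[o + L, ] - X[o, ])^2 + (Y[o + L, ] - Y[o, ])^2)
      cnt <- cnt + 1
    }
    msd[L + 1] <- acc / cnt
  }
  msd
}

# Central finite-difference mean curvature of an analytic height function.
fd_mean_curvature <- function(f, x, y, h = 1e-4) {
  zxx <- (f(x + h, y) - 2 * f(x, y) + f(x - h, y)) / h^2
  zyy <- (f(x, y + h) - 2 * f(x, y) + f(x, y - h)) / h^2
  (zxx + zyy) / 2
}

# Frame-averaged curvature field estimator used in recovery checks:
# independent noisy samplings of one static surface, fitted per frame,
# curvature fields averaged (the time-average the analysis pipeline uses).
averaged_curvature <- function(gen_one, M, n_frames, grid = c(26, 26),
                               box = c(13, 13)) {
  acc <- 0
  for (k in seq_len(n_frames)) {
    g <- gen_one(k)
    s <- fit_fourier_surface(g$points, box, M = M)
    acc <- acc + mean_curvature_field(s, grid = grid)$values
  }
  acc / n_frames
}

grid_xy <- function(grid = c(26, 26), box = c(13, 13)) {
  list(x = rep((seq_len(grid[1]) - 0.5) * box[1] / grid[1], times = grid[2]),
       y = rep((seq_len(grid[2]) - 0.5) * box[2] / grid[2], each = grid[1]))
}
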