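#' Truncated 2D Fourier representation of a leaflet surface
#'
#' A leaflet's height function z(x, y) over a periodic box (Lx, Ly) is
#' represented in the Monge gauge as a truncated real Fourier series
#'
#'   z(x, y) = a0 + sum over modes (m, n) of
#'             a_c(m,n) cos(2 pi (m x / Lx + n y / Ly)) +
#'             a_s(m,n) sin(2 pi (m x / Lx + n y / Ly))
#'
#' with |m|, |n| <= M. One of each conjugate mode pair is kept (m > 0, or
#' m = 0 and n > 0), so the surface is real by construction and periodic in
#' both directions. For the default M = 2 this is 25 real basis functions.
#'
#' @name fourier_surface
NULL

# unique wavevector index set for cutoff M: (m, n) with m > 0, or m = 0, n > 0
fourier_modes <- function(M) {
  g <- expand.grid(m = 0:M, n = -M:M)
  g[g$m > 0 | (g$m == 0 & g$n > 0), , drop = FALSE]
}

# design matrix of the real Fourier basis at points (x, y):
# [1, cos(theta_1), sin(theta_1), cos(theta_2), ...]
fourier_design <- function(x, y, box, M) {
  modes <- fourier_modes(M)
  K <- nrow(modes)
  X <- matrix(0, length(x), 1 + 2 * K)
  X[, 1] <- 1
  for (j in seq_len(K)) {
    th <- 2 * pi * (modes$m[j] * x / box[1] + modes$n[j] * y / box[2])
    X[, 2 * j] <- cos(th)
    X[, 2 * j + 1] <- sin(th)
  }
  X
}

#' Fit a leaflet surface as a 2D Fourier series
#'
#' Linear least squares of the sampled heights on the truncated real Fourier
#' basis over the periodic box. With the default mode cutoff `M = 2` the
#' basis has 25 functions, well determined by the ~260 phosphorus atoms of
#' one leaflet of a ~13 nm patch; larger M starts fitting thermal noise at
#' protein-relevant scales.
#'
#' @param points matrix or data frame with columns `x`, `y`, `z` (nm).
#' @param box lateral box `(Lx, Ly)` in nm.
#' @param M mode cutoff (default 2).
#' @return object of class `fourier_surface`: coefficients (`a0`, and per
#'   mode cos/sin amplitudes in nm), the mode table, box, M, RMS residual
#'   and the number of points fitted.
#' @export
fit_fourier_surface <- function(points, box, M = 2) {
  pts <- as.data.frame(points)
  stopifnot(all(c("x", "y", "z") %in% names(pts)))
  if (any(box[1:2] <= 0)) stop("fit error: box must be positive", call. = FALSE)
  X <- fourier_design(pts$x, pts$y, box, M)
  if (nrow(X) < ncol(X))
    stop(sprintf("fit error: %d points cannot determine %d coefficients",
                 nrow(X), ncol(X)), call. = FALSE)
  fit <- lm.fit(X, pts$z)
  if (fit$rank < ncol(X))
    stop("fit error: rank-deficient design (points degenerate in x-y)",
         call. = FALSE)
  modes <- fourier_modes(M)
  cf <- unname(fit$coefficients)
  structure(list(a0 = cf[1],
                 a_cos = cf[2 * seq_len(nrow(modes))],
                 a_sin = cf[2 * seq_len(nrow(modes)) + 1],
                 modes = modes, box = box[1:2], M = M,
                 rms_residual = sqrt(mean(fit$residuals^2)),
                 n_points = nrow(X)),
            class = "fourier_surface")
}

#' @export
print.fourier_surface <- function(x, ...) {
  cat(sprintf("fourier_surface: M = %d (%d basis functions), box %.3g x %.3g nm\n",
              x$M, 1 + 2 * nrow(x$modes), x$box[1], x$box[2]))
  cat(sprintf("  mean height a0 = %.4g nm, RMS residual %.4g nm (%d points)\n",
              x$a0, x$rms_residual, x$n_points))
  invisible(x)
}

#' Evaluate a fitted surface (or its derivatives) at points
#'
#' Derivatives are analytic: differentiating cos/sin of
#' theta = kx*x + ky*y simply multiplies by powers of the wavevector and
#' shifts the phase by pi/2 per derivative order.
#'
#' @param surface a [fit_fourier_surface()] result.
#' @param x,y coordinates (nm); recycled to common length.
#' @param deriv integer pair `(p, q)`: order of the x and y derivative.
#'   `c(0,0)` evaluates z itself.
#' @return numeric vector of z (nm) or its (p,q)-derivative (nm^(1-p-q)).
#' @export
eval_surface <- function(surface, x, y, deriv = c(0L, 0L)) {
  p <- deriv[1]; q <- deriv[2]
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  out <- if (p == 0 && q == 0) rep(surface$a0, n) else numeric(n)
  kx <- 2 * pi * surface$modes$m / surface$box[1]
  ky <- 2 * pi * surface$modes$n / surface$box[2]
  shift <- (p + q) * pi / 2
  for (j in seq_len(nrow(surface$modes))) {
    fac <- kx[j]^p * ky[j]^q
    if (fac == 0 && (p + q) > 0) next
    th <- kx[j] * x + ky[j] * y
    out <- out + fac * (surface$a_cos[j] * cos(th + shift) +
                        surface$a_sin[j] * sin(th + shift))
  }
  out
}
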