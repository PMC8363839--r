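#' Synthetic inputs with retained ground truth
#'
#' Every input class the analysis pipeline consumes can be generated
#' synthetically with known ground truth: analytic surfaces sampled at
#' phosphorus-atom density, full bilayer trajectories (two leaflets, POPC /
#' POPS / TFP composition, thermal undulations, lateral Brownian motion),
#' plain 2D Brownian ensembles, and AFM topographs of a bilayer with holes.
#' All generators are seed-deterministic: the same spec yields bit-identical
#' output.
#'
#' @name synthetic_data
NULL

# run expr under a fixed RNG seed without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Full parameterisation of a synthetic input
#'
#' A light record of generator kind + parameters + seed, storable as YAML,
#' that fully determines the generated data. [generate()] dispatches it to
#' the matching `gen_*` function.
#'
#' @param kind one of `"surface"`, `"bilayer_traj"`, `"brownian"`,
#'   `"afm_image"`.
#' @param ... parameters forwarded to the generator.
#' @param seed RNG seed (integer).
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(kind = c("surface", "bilayer_traj", "brownian",
                                    "afm_image"), ..., seed = 1) {
  kind <- match.arg(kind)
  structure(list(kind = kind, params = list(...), seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @rdname synthetic_spec
#' @param spec a `synthetic_spec`.
#' @export
generate <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  fn <- switch(spec$kind, surface = gen_surface_points,
               bilayer_traj = gen_bilayer_trajectory,
               brownian = gen_brownian, afm_image = gen_afm_image)
  do.call(fn, c(spec$params, list(seed = spec$seed)))
}

# Helfrich-like undulation amplitudes: per-mode Gaussian cos/sin amplitudes
# with sd proportional to 1/q^2, scaled so the expected spatial RMS of the
# surface equals `rms`. Returns sd per unique mode.
undulation_sds <- function(modes, box, rms) {
  q2 <- (2 * pi * modes$m / box[1])^2 + (2 * pi * modes$n / box[2])^2
  w <- 1 / q2^2
  # spatial mean of z^2 is sum_j (a_c^2 + a_s^2)/2; with a ~ N(0, s_j^2) the
  # expectation is sum_j s_j^2, so scale s_j = c/q_j^2 with c^2 sum w = rms^2
  sqrt(w * rms^2 / sum(w))
}

# linearized mean curvature of a Gaussian bump A exp(-r^2 / 2 s^2)
dimple_H <- function(dx, dy, A, s) {
  r2 <- dx^2 + dy^2
  0.5 * A * exp(-r2 / (2 * s^2)) * (r2 / s^4 - 2 / s^2)
}

#' Sample points from a known analytic surface
#'
#' Draws `n` points uniformly in the lateral box on
#' z = sum of Fourier modes (+ optional Gaussian dimple) with optional i.i.d.
#' Gaussian height noise, and returns closed forms for the surface and its
#' linearised mean curvature so recovery can be checked exactly.
#'
#' @param n number of points (default 260, one leaflet of a 520-lipid patch).
#' @param box lateral box `(Lx, Ly)` in nm.
#' @param amplitudes data frame with columns `m`, `n`, `a_cos`, `a_sin` (nm);
#'   `NULL` for a flat surface.
#' @param z0 constant offset (nm).
#' @param dimple `NULL` or `list(A, s, center)`: Gaussian bump of signed
#'   amplitude `A` nm and width `s` nm.
#' @param noise_sd sd of i.i.d. Gaussian z-noise (nm, >= 0).
#' @param seed RNG seed.
#' @return list with `points` (data frame x, y, z), `surface_fn(x, y)`,
#'   `H_fn(x, y)` (linearised analytic mean curvature), and `spec`.
#' @export
gen_surface_points <- function(n = 260, box = c(13, 13), amplitudes = NULL,
                               z0 = 0, dimple = NULL, noise_sd = 0, seed = 1) {
  if (noise_sd < 0)
    stop("parameter error: noise_sd must be >= 0", call. = FALSE)
  surface_fn <- function(x, y) {
    z <- rep(z0, length(x))
    if (!is.null(amplitudes))
      for (j in seq_len(nrow(amplitudes))) {
        th <- 2 * pi * (amplitudes$m[j] * x / box[1] +
                        amplitudes$n[j] * y / box[2])
        z <- z + amplitudes$a_cos[j] * cos(th) + amplitudes$a_sin[j] * sin(th)
      }
    if (!is.null(dimple))
      z <- z + dimple$A * exp(-((x - dimple$center[1])^2 +
                                (y - dimple$center[2])^2) / (2 * dimple$s^2))
    z
  }
  H_fn <- function(x, y) {
    H <- numeric(length(x))
    if (!is.null(amplitudes))
      for (j in seq_len(nrow(amplitudes))) {
        kx <- 2 * pi * amplitudes$m[j] / box[1]
        ky <- 2 * pi * amplitudes$n[j] / box[2]
        th <- kx * x + ky * y
        H <- H - (kx^2 + ky^2) / 2 *
          (amplitudes$a_cos[j] * cos(th) + amplitudes$a_sin[j] * sin(th))
      }
    if (!is.null(dimple))
      H <- H + dimple_H(x - dimple$center[1], y - dimple$center[2],
                        dimple$A, dimple$s)
    H
  }
  pts <- with_seed(seed, {
    x <- stats::runif(n, 0, box[1])
    y <- stats::runif(n, 0, box[2])
    data.frame(x = x, y = y,
               z = surface_fn(x, y) +
                 if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0)
  })
  list(points = pts, surface_fn = surface_fn, H_fn = H_fn,
       spec = synthetic_spec("surface", n = n, box = box,
                             amplitudes = amplitudes, z0 = z0,
                             dimple = dimple, noise_sd = noise_sd,
                             seed = seed))
}

#' Generate a synthetic bilayer trajectory
#'
#' Emulates the membrane patch of the study conditions: 520 lipids at 80:20
#' POPC:POPS split equally between two leaflets of a ~13 x 13 nm periodic
#' box, headgroups at +- d0/2 around a midplane that can carry thermal
#' undulations (per-mode Gaussian amplitudes proportional to 1/q^2, redrawn
#' each frame) and a static Gaussian dimple standing in for a bound protein.
#' Lipids and TFP molecules perform lateral Brownian motion with per-species
#' diffusion constants. Ground truth (leaflet labels, d0, D per species,
#' per-frame surface) is returned alongside.
#'
#' @param n_lipids total lipid count (default 520).
#' @param pops_frac POPS fraction of lipids (default 0.20).
#' @param n_tfp TFP molecule count, one of the study doses 0 / 24 / 48 (any
#'   even count is accepted).
#' @param box box `(Lx, Ly, Lz)` in nm.
#' @param d0 phosphate-to-phosphate bilayer thickness in nm (default 4.0,
#'   typical of fluid POPC).
#' @param D named list/vector of lateral diffusion constants in nm^2/ns for
#'   `POPC`, `POPS`, `TFP`. Defaults: POPC 1.0e-2, POPS 9.9e-3 (the untreated
#'   bilayer value), TFP 5e-3.
#' @param n_frames number of stored frames.
#' @param dt frame spacing in ns (default 0.1 = 100 ps).
#' @param undulation `NULL` for a flat midplane, or `list(M, rms,
#'   fluctuating)`: mode cutoff, target RMS roughness (nm), and whether
#'   amplitudes are redrawn every frame (thermal) or frozen (static).
#' @param dimple `NULL` or `list(A, s, center)` applied to the upper leaflet;
#'   when present, 12 static `"PROT"`-tagged marker particles are placed on a
#'   ring of radius `s` so that footprint auto-detection works.
#' @param seed RNG seed.
#' @return list with `traj` (a wrapped [particle_trajectory()]),
#'   `truth` (species, leaflet per particle, `d0`, `D`, per-frame undulation
#'   coefficients, `mid_fn(frame)` closure) and `spec`.
#' @export
gen_bilayer_trajectory <- function(n_lipids = 520, pops_frac = 0.2,
                                   n_tfp = 0, box = c(13, 13, 13), d0 = 4,
                                   D = list(POPC = 1.0e-2, POPS = 9.9e-3,
                                            TFP = 5e-3),
                                   n_frames = 101, dt = 0.1,
                                   undulation = list(M = 2, rms = 0.2,
                                                     fluctuating = TRUE),
                                   dimple = NULL, seed = 1) {
  per_leaf <- n_lipids / 2
  pops_per_leaf <- n_lipids * pops_frac / 2
  if (per_leaf != round(per_leaf) || pops_per_leaf != round(pops_per_leaf))
    stop("parameter error: per-leaflet lipid counts must be integers",
         call. = FALSE)
  if (n_tfp %% 2 != 0)
    stop("parameter error: TFP count must split evenly between leaflets",
         call. = FALSE)
  species_leaf <- c(rep("POPS", pops_per_leaf),
                    rep("POPC", per_leaf - pops_per_leaf))
  species <- c(species_leaf, species_leaf,
               rep("TFP", n_tfp))
  leaflet <- c(rep("upper", per_leaf), rep("lower", per_leaf),
               rep(c("upper", "lower"), length.out = n_tfp))
  np <- length(species)
  tags <- ifelse(species == "TFP", "TFP", paste0(species, "-P"))
  modes <- if (!is.null(undulation)) fourier_modes(undulation$M) else NULL
  out <- with_seed(seed, {
    X <- Y <- matrix(0, n_frames, np)
    X[1, ] <- stats::runif(np, 0, box[1])
    Y[1, ] <- stats::runif(np, 0, box[2])
    sig <- sqrt(2 * dt * unlist(D)[species])
    if (n_frames > 1) for (i in 2:n_frames) {
      X[i, ] <- X[i - 1, ] + stats::rnorm(np, 0, sig)
      Y[i, ] <- Y[i - 1, ] + stats::rnorm(np, 0, sig)
    }
    coefs <- NULL
    if (!is.null(modes)) {
      sds <- undulation_sds(modes, box, undulation$rms)
      ndraw <- if (isTRUE(undulation$fluctuating)) n_frames else 1L
      coefs <- array(stats::rnorm(2 * nrow(modes) * ndraw,
                                  sd = rep(sds, each = 2)),
                     dim = c(2, nrow(modes), ndraw))
    }
    list(X = X, Y = Y, coefs = coefs)
  })
  mid_fn <- function(frame) {
    function(x, y) {
      z <- rep(box[3] / 2, length(x))
      if (!is.null(out$coefs)) {
        k <- if (dim(out$coefs)[3] > 1) frame else 1L
        for (j in seq_len(nrow(modes))) {
          th <- 2 * pi * (modes$m[j] * x / box[1] + modes$n[j] * y / box[2])
          z <- z + out$coefs[1, j, k] * cos(th) + out$coefs[2, j, k] * sin(th)
        }
      }
      z
    }
  }
  Xw <- out$X - box[1] * floor(out$X / box[1])
  Yw <- out$Y - box[2] * floor(out$Y / box[2])
  Z <- matrix(0, n_frames, np)
  off <- ifelse(leaflet == "upper", d0 / 2, -d0 / 2)
  # TFP sits below the headgroups, toward the bilayer core
  off[species == "TFP"] <- off[species == "TFP"] * 0.6
  for (i in seq_len(n_frames)) {
    mid <- mid_fn(i)(Xw[i, ], Yw[i, ])
    Z[i, ] <- mid + off
    if (!is.null(dimple)) {
      up <- leaflet == "upper"
      dx <- Xw[i, up] - dimple$center[1]
      dy <- Yw[i, up] - dimple$center[2]
      Z[i, up] <- Z[i, up] + dimple$A * exp(-(dx^2 + dy^2) / (2 * dimple$s^2))
    }
  }
  if (!is.null(dimple)) {
    ang <- 2 * pi * (0:11) / 12
    px <- dimple$center[1] + dimple$s * cos(ang)
    py <- dimple$center[2] + dimple$s * sin(ang)
    Xw <- cbind(Xw, matrix(px, n_frames, 12, byrow = TRUE))
    Yw <- cbind(Yw, matrix(py, n_frames, 12, byrow = TRUE))
    Z <- cbind(Z, matrix(box[3] / 2 + d0 / 2 + 1, n_frames, 12))
    tags <- c(tags, rep("PROT", 12))
    species <- c(species, rep("PROT", 12))
    leaflet <- c(leaflet, rep(NA, 12))
  }
  traj <- particle_trajectory(Xw, Yw, Z, time = (seq_len(n_frames) - 1) * dt,
                              box = box, tags = tags,
                              source = "synthetic bilayer")
  list(traj = traj,
       truth = list(species = species, leaflet = leaflet, d0 = d0, D = D,
                    undulation_coefs = out$coefs, modes = modes,
                    dimple = dimple, mid_fn = mid_fn),
       spec = synthetic_spec("bilayer_traj", n_lipids = n_lipids,
                             pops_frac = pops_frac, n_tfp = n_tfp, box = box,
                             d0 = d0, D = D, n_frames = n_frames, dt = dt,
                             undulation = undulation, dimple = dimple,
                             seed = seed))
}

#' Generate a 2D Brownian ensemble
#'
#' Independent lateral random walks with per-axis step variance 2 D dt — the
#' ground truth for the MSD/Einstein-relation estimators. Returned unwrapped
#' by default; `wrap = TRUE` stores wrapped coordinates instead (to exercise
#' [unwrap_lateral()]).
#'
#' @param n number of particles.
#' @param D diffusion constant in nm^2/ns (note 1e-3 nm^2/ns = 1e-8 cm^2/s).
#' @param dt frame spacing (ns).
#' @param n_frames number of frames.
#' @param box box `(Lx, Ly, Lz)` in nm.
#' @param wrap store wrapped coordinates.
#' @param tag particle tag.
#' @param seed RNG seed.
#' @return list with `traj`, `truth` (`D_nm2ns`, `D_cm2s`) and `spec`.
#' @export
gen_brownian <- function(n = 1000, D = 5e-3, dt = 0.1, n_frames = 501,
                         box = c(13, 13, 13), wrap = FALSE, tag = "TRACER",
                         seed = 1) {
  if (D < 0 || dt <= 0)
    stop("parameter error: need D >= 0 and dt > 0", call. = FALSE)
  XY <- with_seed(seed, {
    x0 <- stats::runif(n, 0, box[1])
    y0 <- stats::runif(n, 0, box[2])
    sig <- sqrt(2 * D * dt)
    dx <- matrix(stats::rnorm((n_frames - 1) * n, 0, sig), n_frames - 1, n)
    dy <- matrix(stats::rnorm((n_frames - 1) * n, 0, sig), n_frames - 1, n)
    cumx <- matrix(apply(dx, 2, cumsum), n_frames - 1, n)
    cumy <- matrix(apply(dy, 2, cumsum), n_frames - 1, n)
    list(X = rbind(x0, sweep(cumx, 2, x0, `+`)),
         Y = rbind(y0, sweep(cumy, 2, y0, `+`)))
  })
  X <- unname(XY$X); Y <- unname(XY$Y)
  if (n_frames == 1) { X <- X[1, , drop = FALSE]; Y <- Y[1, , drop = FALSE] }
  Z <- matrix(box[3] / 2, n_frames, n)
  if (wrap) {
    X <- X - box[1] * floor(X / box[1])
    Y <- Y - box[2] * floor(Y / box[2])
  }
  traj <- particle_trajectory(X, Y, Z, time = (seq_len(n_frames) - 1) * dt,
                              box = box, tags = rep(tag, n),
                              source = "synthetic brownian",
                              unwrapped = !wrap)
  list(traj = traj,
       truth = list(D_nm2ns = D, D_cm2s = nm2ns_to_cm2s(D)),
       spec = synthetic_spec("brownian", n = n, D = D, dt = dt,
                             n_frames = n_frames, box = box, wrap = wrap,
                             tag = tag, seed = seed))
}

#' Generate a synthetic AFM topograph
#'
#' Substrate at 0, bilayer plateau at `height`, circular holes down to the
#' substrate, optional background tilt plane and Gaussian pixel noise.
#'
#' @param nx,ny image size in pixels.
#' @param pixel_size nm per pixel.
#' @param height bilayer height above substrate (nm).
#' @param holes list of `list(center = c(x, y) px, radius = r px)`.
#' @param tilt background plane slope `(a, b)` in nm per pixel along x and y.
#' @param noise_sd Gaussian pixel noise sd (nm).
#' @param seed RNG seed.
#' @return list with `image` (a [height_image()]), `truth` (`height`) and
#'   `spec`.
#' @export
gen_afm_image <- function(nx = 200, ny = 200, pixel_size = 2, height = 4,
                          holes = list(list(center = c(100, 100),
                                            radius = 30)),
                          tilt = c(0, 0), noise_sd = 0, seed = 1) {
  for (h in holes)
    if (2 * h$radius > min(nx, ny))
      stop("geometry error: hole larger than the image", call. = FALSE)
  z <- matrix(height, nx, ny)
  ix <- row(z); iy <- col(z)
  for (h in holes)
    z[(ix - h$center[1])^2 + (iy - h$center[2])^2 <= h$radius^2] <- 0
  z <- z + tilt[1] * ix + tilt[2] * iy
  if (noise_sd > 0)
    z <- z + with_seed(seed, matrix(stats::rnorm(nx * ny, 0, noise_sd),
                                    nx, ny))
  list(image = height_image(z, pixel_size, label = "synthetic"),
       truth = list(height = height),
       spec = synthetic_spec("afm_image", nx = nx, ny = ny,
                             pixel_size = pixel_size, height = height,
                             holes = holes, tilt = tilt, noise_sd = noise_sd,
                             seed = seed))
}
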