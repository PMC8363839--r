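#' Unit conversions for lateral diffusion constants
#'
#' Internally all diffusion constants are nm^2/ns; literature values for
#' lipids are usually quoted in cm^2/s. 1 nm^2/ns = 1e-5 cm^2/s, exactly.
#'
#' @param D numeric diffusion constant(s).
#' @return converted value(s).
#' @export
nm2ns_to_cm2s <- function(D) D * 1e-5

#' @rdname nm2ns_to_cm2s
#' @export
cm2s_to_nm2ns <- function(D) D * 1e5

#' Lateral mean-squared displacement with multiple time origins
#'
#' Computes MSD(t) = <(r(t0 + t) - r(t0))^2> over the lateral (x, y)
#' coordinates, averaged over all selected particles and over time origins t0
#' placed every `origin_spacing_ns` (default 0.1 ns = 100 ps). The
#' trajectory must be laterally unwrapped first ([unwrap_lateral()]).
#'
#' By default the lateral center-of-mass motion of the selection is removed
#' (per leaflet when an assignment is given) before displacements are taken:
#' collective leaflet drift otherwise inflates the apparent single-particle
#' diffusion. Set `remove_com = FALSE` to keep raw displacements.
#'
#' @param traj an unwrapped [particle_trajectory()].
#' @param selection tag selection (default all particles).
#' @param origin_spacing_ns spacing of time origins in ns; must be >= the
#'   frame spacing.
#' @param max_lag_ns largest lag to evaluate; default half the trajectory
#'   length.
#' @param remove_com remove the selection's lateral COM motion first.
#' @param assignment optional [assign_leaflets()] result; with
#'   `remove_com = TRUE` the COM is removed per leaflet.
#' @return object of class `msd_series`: `lags` (ns, starting at 0), `msd`
#'   (nm^2), `n_origins` per lag, `selection`.
#' @export
compute_msd <- function(traj, selection = NULL, origin_spacing_ns = 0.1,
                        max_lag_ns = NULL, remove_com = TRUE,
                        assignment = NULL) {
  if (!isTRUE(traj$unwrapped))
    stop("compute_msd needs an unwrapped trajectory; call unwrap_lateral()",
         call. = FALSE)
  nf <- n_frames(traj)
  if (nf < 2) stop("need at least 2 frames", call. = FALSE)
  dt <- diff(traj$time)
  if (max(dt) - min(dt) > 1e-9 * max(dt))
    stop("frames must be evenly spaced in time", call. = FALSE)
  dt <- dt[1]
  if (origin_spacing_ns < dt - 1e-12)
    stop(sprintf(paste("parameter error: origin spacing %.4g ns is below the",
                       "frame spacing %.4g ns"), origin_spacing_ns, dt),
         call. = FALSE)
  idx <- select_particles(traj, selection)
  X <- traj$x[, idx, drop = FALSE]
  Y <- traj$y[, idx, drop = FALSE]
  if (remove_com) {
    groups <- if (is.null(assignment)) list(seq_along(idx)) else {
      g <- lapply(c("upper", "lower"),
                  function(s) which(idx %in% assignment[[s]]))
      g[lengths(g) > 0]
    }
    for (g in groups) {
      X[, g] <- X[, g, drop = FALSE] - rowMeans(X[, g, drop = FALSE])
      Y[, g] <- Y[, g, drop = FALSE] - rowMeans(Y[, g, drop = FALSE])
    }
  }
  ostep <- max(1L, round(origin_spacing_ns / dt))
  origins <- seq.int(1L, nf, by = ostep)
  max_lag <- if (is.null(max_lag_ns)) floor((nf - 1L) / 2) else
    min(nf - 1L, round(max_lag_ns / dt))
  msd <- numeric(max_lag + 1L)
  n_or <- integer(max_lag + 1L)
  n_or[1] <- length(origins)
  for (L in seq_len(max_lag)) {
    o <- origins[origins + L <= nf]
    if (length(o) == 0) { msd[L + 1L] <- NA; next }
    dx <- X[o + L, , drop = FALSE] - X[o, , drop = FALSE]
    dy <- Y[o + L, , drop = FALSE] - Y[o, , drop = FALSE]
    msd[L + 1L] <- mean(dx * dx + dy * dy)
    n_or[L + 1L] <- length(o)
  }
  keep <- !is.na(msd)
  structure(list(lags = (0:max_lag)[keep] * dt, msd = msd[keep],
                 n_origins = n_or[keep],
                 selection = if (is.null(selection)) "all" else selection),
            class = "msd_series")
}

#' @export
print.msd_series <- function(x, ...) {
  cat(sprintf("msd_series: %d lags, 0 .. %.4g ns (selection: %s)\n",
              length(x$lags), max(x$lags), x$selection))
  invisible(x)
}

#' @export
plot.msd_series <- function(x, ...) {
  graphics::plot(x$lags, x$msd, type = "l", xlab = "lag (ns)",
                 ylab = expression(MSD ~ (nm^2)), ...)
  invisible(x)
}

#' Fit the Einstein relation to an MSD series
#'
#' Least-squares straight line through MSD(t) over lags in `(0, t_max]`
#' (lag 0 is excluded; the intercept is free by default and absorbs
#' short-time non-diffusive motion). For 2D lateral diffusion
#' MSD(t) = 4 D t, so D = slope / 4, reported in cm^2/s. The error estimate
#' follows the two-halves rule: the absolute difference between D fitted
#' over `(0, t_max/2]` and over `(t_max/2, t_max]`.
#'
#' @param msd an [compute_msd()] result.
#' @param t_max_ns upper end of the fit window in ns (default 50).
#' @param zero_intercept force the line through the origin.
#' @return object of class `diffusion_estimate`: `D` and `D_error` (cm^2/s),
#'   `D_nm2ns`, `halves` (the two half-window estimates, cm^2/s),
#'   `fit_window`, `intercept_nm2`, `n_lags`.
#' @export
fit_diffusion <- function(msd, t_max_ns = 50, zero_intercept = FALSE) {
  fit_D <- function(sel) {
    t <- msd$lags[sel]; y <- msd$msd[sel]
    if (length(t) < 2) return(NA_real_)
    co <- if (zero_intercept) c(0, sum(t * y) / sum(t * t)) else
      unname(stats::coef(stats::lm(y ~ t)))
    co[2] / 4
  }
  in_window <- msd$lags > 0 & msd$lags <= t_max_ns
  if (sum(in_window) < 3)
    stop("fit error: fewer than 3 lag points in the fit window", call. = FALSE)
  D_nm2ns <- fit_D(in_window)
  h1 <- fit_D(msd$lags > 0 & msd$lags <= t_max_ns / 2)
  h2 <- fit_D(msd$lags > t_max_ns / 2 & msd$lags <= t_max_ns)
  intercept <- if (zero_intercept) 0 else
    stats::coef(stats::lm(msd$msd[in_window] ~ msd$lags[in_window]))[1]
  structure(list(D = nm2ns_to_cm2s(D_nm2ns),
                 D_error = abs(nm2ns_to_cm2s(h1) - nm2ns_to_cm2s(h2)),
                 D_nm2ns = D_nm2ns,
                 halves = nm2ns_to_cm2s(c(h1, h2)),
                 fit_window = c(0, t_max_ns),
                 intercept_nm2 = unname(intercept),
                 n_lags = sum(in_window)),
            class = "diffusion_estimate")
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat(sprintf("D = %.4g +- %.2g cm^2/s (fit 0..%g ns, %d lags)\n",
              x$D, x$D_error, x$fit_window[2], x$n_lags))
  cat(sprintf("  halves: %.4g / %.4g cm^2/s; intercept %.3g nm^2\n",
              x$halves[1], x$halves[2], x$intercept_nm2))
  invisible(x)
}

#' Export an MSD series as a two-column CSV
#'
#' @param msd an `msd_series`.
#' @param path file path; columns `lag_ns`, `msd_nm2`.
#' @export
write_msd_csv <- function(msd, path) {
  data.table::fwrite(data.table::data.table(lag_ns = msd$lags,
                                            msd_nm2 = msd$msd), path)
  invisible(path)
}
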