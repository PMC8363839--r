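#' Mean-curvature field of a fitted leaflet surface
#'
#' In the Monge gauge the mean curvature of z(x, y) is
#'
#'   H = \[(1 + z_y^2) z_xx - 2 z_x z_y z_xy + (1 + z_x^2) z_yy\] /
#'       \[2 (1 + z_x^2 + z_y^2)^(3/2)\]
#'
#' which for the small slopes of a lipid bilayer linearises to
#' H = (z_xx + z_yy) / 2. The linearised form is the default; the full
#' expression is available as a cross-check. All derivatives are evaluated
#' analytically from the Fourier coefficients.
#'
#' Sign convention: z increases toward the upper leaflet, so an upward bulge
#' (local maximum of z) has H < 0 at its apex and an indentation (local
#' minimum) has H > 0. Because "positive/negative induced curvature" is used
#' with either sign in the literature, footprint summaries report the signed
#' value, its magnitude and the extremum.
#'
#' @param surface a [fit_fourier_surface()] result.
#' @param grid grid size `(nx, ny)`; nodes at cell centers.
#' @param mode `"linearized"` (default) or `"full"`.
#' @return a [field2d()] of kind `"curvature"` in nm^-1.
#' @export
mean_curvature_field <- function(surface, grid = c(26, 26),
                                 mode = c("linearized", "full")) {
  mode <- match.arg(mode)
  nx <- grid[1]; ny <- grid[2]
  gx <- (seq_len(nx) - 0.5) * surface$box[1] / nx
  gy <- (seq_len(ny) - 0.5) * surface$box[2] / ny
  X <- rep(gx, times = ny)
  Y <- rep(gy, each = nx)
  zxx <- eval_surface(surface, X, Y, deriv = c(2L, 0L))
  zyy <- eval_surface(surface, X, Y, deriv = c(0L, 2L))
  if (mode == "linearized") {
    H <- (zxx + zyy) / 2
  } else {
    zx <- eval_surface(surface, X, Y, deriv = c(1L, 0L))
    zy <- eval_surface(surface, X, Y, deriv = c(0L, 1L))
    zxy <- eval_surface(surface, X, Y, deriv = c(1L, 1L))
    H <- ((1 + zy^2) * zxx - 2 * zx * zy * zxy + (1 + zx^2) * zyy) /
      (2 * (1 + zx^2 + zy^2)^1.5)
  }
  field2d(matrix(H, nx, ny), surface$box, "nm^-1", "curvature",
          meta = list(mode = mode, M = surface$M))
}

#' Bilayer thickness field from the two leaflet surfaces
#'
#' Phosphorus-to-phosphorus vertical distance,
#' thickness(x, y) = z_upper(x, y) - z_lower(x, y).
#'
#' @param upper,lower fitted `fourier_surface` objects over the same box.
#' @param grid grid size `(nx, ny)`.
#' @return a [field2d()] of kind `"thickness"` in nm.
#' @export
thickness_field <- function(upper, lower, grid = c(26, 26)) {
  if (max(abs(upper$box - lower$box)) > 1e-9)
    stop("leaflet surfaces were fitted over different boxes", call. = FALSE)
  nx <- grid[1]; ny <- grid[2]
  gx <- (seq_len(nx) - 0.5) * upper$box[1] / nx
  gy <- (seq_len(ny) - 0.5) * upper$box[2] / ny
  X <- rep(gx, times = ny)
  Y <- rep(gy, each = nx)
  th <- eval_surface(upper, X, Y) - eval_surface(lower, X, Y)
  if (any(th < 0))
    stop("leaflet-order error: negative thickness (upper below lower)",
         call. = FALSE)
  field2d(matrix(th, nx, ny), upper$box, "nm", "thickness")
}

#' Per-frame leaflet surfaces of a trajectory
#'
#' Fits the selected headgroup particles of one leaflet to a Fourier surface
#' in every frame.
#'
#' @param traj a [particle_trajectory()].
#' @param idx particle indices of the leaflet (e.g. from
#'   [assign_leaflets()]).
#' @param M mode cutoff.
#' @param frames frame indices (default all).
#' @return list of `fourier_surface`, one per frame.
#' @export
surface_series <- function(traj, idx, M = 2, frames = seq_len(n_frames(traj))) {
  lapply(frames, function(i) {
    fit_fourier_surface(data.frame(x = traj$x[i, idx], y = traj$y[i, idx],
                                   z = traj$z[i, idx]),
                        box = traj$box[i, 1:2], M = M)
  })
}

#' Per-frame mean-curvature fields of a bilayer trajectory
#'
#' Fits both leaflets in every frame and returns the per-frame curvature
#' field: the average of the two leaflet curvatures when `leaflet = "both"`
#' (the curvature of the bilayer midsurface under the linearised form).
#'
#' @param traj a [particle_trajectory()].
#' @param assignment a [assign_leaflets()] result.
#' @inheritParams mean_curvature_field
#' @param M mode cutoff.
#' @param leaflet `"both"`, `"upper"` or `"lower"`.
#' @param frames frame indices (default all).
#' @return list of curvature [field2d()], one per frame.
#' @export
curvature_series <- function(traj, assignment, M = 2, grid = c(26, 26),
                             mode = "linearized", leaflet = "both",
                             frames = seq_len(n_frames(traj))) {
  lapply(frames, function(i) {
    fld <- NULL
    for (side in if (leaflet == "both") c("upper", "lower") else leaflet) {
      idx <- assignment[[side]]
      s <- fit_fourier_surface(data.frame(x = traj$x[i, idx],
                                          y = traj$y[i, idx],
                                          z = traj$z[i, idx]),
                               box = traj$box[i, 1:2], M = M)
      h <- mean_curvature_field(s, grid = grid, mode = mode)
      fld <- if (is.null(fld)) h else
        field2d((fld$values + h$values) / 2, h$box, h$units, h$kind, h$meta)
    }
    fld
  })
}

#' Per-frame thickness fields of a bilayer trajectory
#'
#' @inheritParams curvature_series
#' @return list of thickness [field2d()], one per frame.
#' @export
thickness_series <- function(traj, assignment, M = 2, grid = c(26, 26),
                             frames = seq_len(n_frames(traj))) {
  lapply(frames, function(i) {
    up <- fit_fourier_surface(data.frame(x = traj$x[i, assignment$upper],
                                         y = traj$y[i, assignment$upper],
                                         z = traj$z[i, assignment$upper]),
                              box = traj$box[i, 1:2], M = M)
    lo <- fit_fourier_surface(data.frame(x = traj$x[i, assignment$lower],
                                         y = traj$y[i, assignment$lower],
                                         z = traj$z[i, assignment$lower]),
                              box = traj$box[i, 1:2], M = M)
    thickness_field(up, lo, grid = grid)
  })
}

# node mask of a disk region under the periodic minimum-image metric
region_mask <- function(field, region) {
  if (is.null(region)) return(matrix(TRUE, nrow(field$values), ncol(field$values)))
  dx <- outer(field$x - region$center[1], rep(1, length(field$y)))
  dy <- outer(rep(1, length(field$x)), field$y - region$center[2])
  dx <- dx - field$box[1] * round(dx / field$box[1])
  dy <- dy - field$box[2] * round(dy / field$box[2])
  dx^2 + dy^2 <= region$radius^2
}

#' Protein curvature footprint
#'
#' Scalar summary of the induced mean curvature in a membrane region: the
#' average of the per-frame curvature fields over the region's grid nodes and
#' over the terminal window of frames. When several replicas are supplied,
#' the across-replica mean and standard error are reported. Because the
#' relation between the sign of H and "induced curvature" is convention-
#' dependent, both the signed region average and its magnitude are returned,
#' along with the extremum of the time-averaged field inside the region.
#'
#' @param fields a list of per-frame curvature [field2d()] (one replica), or
#'   a list of such lists (several replicas).
#' @param region `NULL` for the full box, or `list(center = c(x, y),
#'   radius = r)` in nm; the disk is taken under periodic minimum image.
#' @param window terminal fraction of frames to average (default 0.4,
#'   i.e. the last 40 percent of the run).
#' @return object of class `curvature_summary` with fields `footprint_mean`,
#'   `footprint_abs`, `footprint_extremum` (all nm^-1), `stderr`, `replicas`,
#'   `frames_used`, `region`.
#' @export
curvature_footprint <- function(fields, region = NULL, window = 0.4) {
  if (length(fields) == 0)
    stop("aggregation error: no fields supplied", call. = FALSE)
  replicas <- if (inherits(fields[[1]], "field2d")) list(fields) else fields
  per_rep <- lapply(replicas, function(fs) {
    nf <- length(fs)
    keep <- seq.int(nf - ceiling(window * nf) + 1L, nf)
    if (length(keep) == 0)
      stop("aggregation error: empty frame window", call. = FALSE)
    avg <- average_fields(fs, window = window)
    mask <- region_mask(avg, region)
    if (!any(mask))
      stop("aggregation error: region contains no grid nodes", call. = FALSE)
    vals <- avg$values[mask]
    list(mean = mean(vals), ext = vals[which.max(abs(vals))], keep = keep)
  })
  means <- vapply(per_rep, `[[`, numeric(1), "mean")
  exts <- vapply(per_rep, `[[`, numeric(1), "ext")
  structure(list(
    footprint_mean = mean(means),
    footprint_abs = abs(mean(means)),
    footprint_extremum = exts[which.max(abs(exts))],
    stderr = if (length(means) > 1)
      stats::sd(means) / sqrt(length(means)) else NA_real_,
    replicas = length(means),
    frames_used = per_rep[[1]]$keep,
    region = if (is.null(region)) "full box" else region,
    sign_convention = "z increases toward the upper leaflet"),
    class = "curvature_summary")
}

#' @export
print.curvature_summary <- function(x, ...) {
  cat(sprintf("curvature footprint: %.4g nm^-1 (|.| = %.4g, extremum %.4g)\n",
              x$footprint_mean, x$footprint_abs, x$footprint_extremum))
  cat(sprintf("  %d replica(s), frames %d..%d%s\n", x$replicas,
              min(x$frames_used), max(x$frames_used),
              if (is.na(x$stderr)) "" else sprintf(", stderr %.3g", x$stderr)))
  invisible(x)
}

#' Default protein footprint region of a trajectory
#'
#' When protein-tagged particles are present, the footprint region is the
#' protein's lateral bounding disk: centroid plus radius of gyration of the
#' protein particles in the reference frame. Otherwise `NULL` (full box).
#'
#' @param traj a [particle_trajectory()].
#' @param protein_tag tag of protein particles.
#' @param reference_frame frame used for the geometry.
#' @return `list(center, radius)` or `NULL`.
#' @export
footprint_region <- function(traj, protein_tag = "PROT", reference_frame = 1) {
  idx <- which(traj$tags == protein_tag)
  if (length(idx) == 0) return(NULL)
  cx <- mean(traj$x[reference_frame, idx])
  cy <- mean(traj$y[reference_frame, idx])
  rg <- sqrt(mean((traj$x[reference_frame, idx] - cx)^2 +
                  (traj$y[reference_frame, idx] - cy)^2))
  list(center = c(cx, cy), radius = rg)
}
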