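#' 2D number-density map of selected particles
#'
#' Per-frame 2D histogram of the lateral positions of a tag selection
#' (optionally restricted to one leaflet), averaged over the analysis window
#' and normalised to count nm^-2. Bins are half-open `[edge, edge)`
#' intervals consistent with the `[0, L)` coordinate wrapping, which makes
#' the conservation identity exact: `sum(values) * cell_area` equals the mean
#' particle count per frame of the selection.
#'
#' @param traj a [particle_trajectory()].
#' @param selection tag selection string (see [select_particles()]).
#' @param leaflet `"both"`, `"upper"` or `"lower"`; leaflet restriction
#'   requires `assignment`.
#' @param assignment a [assign_leaflets()] result (needed unless
#'   `leaflet = "both"`).
#' @param grid bin counts `(nx, ny)`; the default 26 x 26 gives ~0.5 nm bins
#'   for a 13 nm box.
#' @param window terminal fraction of frames to average (default 0.4, the
#'   same terminal window used for curvature and thickness).
#' @return a [field2d()] of kind `"density"` (count nm^-2) with metadata
#'   `selection`, `leaflet`, `frames_used`.
#' @export
density_map <- function(traj, selection = NULL,
                        leaflet = c("both", "upper", "lower"),
                        assignment = NULL, grid = c(26, 26), window = 0.4) {
  leaflet <- match.arg(leaflet)
  idx <- select_particles(traj, selection)
  if (leaflet != "both") {
    if (is.null(assignment))
      stop("leaflet-restricted maps need a leaflet assignment", call. = FALSE)
    idx <- intersect(idx, assignment[[leaflet]])
    if (length(idx) == 0)
      stop("aggregation error: selection is empty in the requested leaflet",
           call. = FALSE)
  }
  nf <- n_frames(traj)
  keep <- seq.int(nf - ceiling(window * nf) + 1L, nf)
  if (length(keep) == 0)
    stop("aggregation error: empty frame window", call. = FALSE)
  nx <- grid[1]; ny <- grid[2]
  counts <- matrix(0, nx, ny)
  box <- traj$box[keep[1], 1:2]
  for (i in keep) {
    Lx <- traj$box[i, 1]; Ly <- traj$box[i, 2]
    px <- traj$x[i, idx]; py <- traj$y[i, idx]
    px <- px - Lx * floor(px / Lx)   # wrap defensively; no-op if wrapped
    py <- py - Ly * floor(py / Ly)
    ix <- pmin(floor(px / Lx * nx), nx - 1) + 1L
    iy <- pmin(floor(py / Ly * ny), ny - 1) + 1L
    tab <- table(factor(ix, levels = seq_len(nx)),
                 factor(iy, levels = seq_len(ny)))
    counts <- counts + unclass(tab)
  }
  cell_area <- (box[1] / nx) * (box[2] / ny)
  vals <- counts / (length(keep) * cell_area)
  dimnames(vals) <- NULL
  field2d(vals, box, "count nm^-2", "density",
          meta = list(selection = if (is.null(selection)) "all" else selection,
                      leaflet = leaflet, frames_used = range(keep),
                      n_selected = length(idx)))
}
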