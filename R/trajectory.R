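#' Particle trajectory container
#'
#' A `particle_trajectory` stores time-ordered positions of a fixed set of
#' tagged particles together with the periodic box of every frame. It is the
#' universal input of the analysis functions in this package. Coordinates are
#' always in nanometres and times in nanoseconds; readers convert at the I/O
#' boundary. Boxes must be orthorhombic; wrapped coordinates live in
#' `[0, L)` per axis with the origin at the box corner.
#'
#' @param x,y,z numeric matrices of dimension `n_frames x n_particles`
#'   holding coordinates in nm.
#' @param time numeric vector of frame times in ns, strictly increasing.
#' @param box numeric matrix `n_frames x 3` of box lengths (Lx, Ly, Lz) in nm,
#'   or a length-3 vector recycled to all frames.
#' @param tags character vector of per-particle species labels (e.g.
#'   `"POPC-P"`, `"POPS-P"`, `"TFP"`).
#' @param source provenance string.
#' @param unwrapped logical; `TRUE` when lateral coordinates are continuous
#'   (image-corrected) rather than wrapped.
#'
#' @return An object of class `particle_trajectory`: a list with elements
#'   `x`, `y`, `z`, `time`, `box`, `tags`, `source`, `unwrapped`.
#' @export
particle_trajectory <- function(x, y, z, time, box, tags,
                                source = "in-memory", unwrapped = FALSE) {
  x <- as.matrix(x); y <- as.matrix(y); z <- as.matrix(z)
  nf <- nrow(x); np <- ncol(x)
  stopifnot(identical(dim(y), dim(x)), identical(dim(z), dim(x)))
  if (length(time) != nf)
    stop("time must have one entry per frame", call. = FALSE)
  if (nf > 1 && any(diff(time) <= 0))
    stop("frame times must be strictly increasing", call. = FALSE)
  if (is.null(dim(box))) box <- matrix(box, nrow = nf, ncol = 3, byrow = TRUE)
  box <- as.matrix(box)
  if (nrow(box) != nf || ncol(box) != 3)
    stop("box must be an n_frames x 3 matrix or a length-3 vector",
         call. = FALSE)
  if (any(!is.finite(box)) || any(box <= 0))
    stop("box lengths must be positive and finite", call. = FALSE)
  if (length(tags) != np)
    stop("tags must have one entry per particle", call. = FALSE)
  structure(list(x = x, y = y, z = z, time = as.numeric(time), box = box,
                 tags = as.character(tags), source = source,
                 unwrapped = isTRUE(unwrapped)),
            class = "particle_trajectory")
}

#' @export
print.particle_trajectory <- function(x, ...) {
  cat(sprintf("particle_trajectory: %d frames x %d particles\n",
              n_frames(x), n_particles(x)))
  cat(sprintf("  time: %.4g .. %.4g ns | box (frame 1): %.3g x %.3g x %.3g nm\n",
              min(x$time), max(x$time), x$box[1, 1], x$box[1, 2], x$box[1, 3]))
  cat(sprintf("  tags: %s\n",
              paste(sprintf("%s (%d)", names(table(x$tags)), table(x$tags)),
                    collapse = ", ")))
  cat(sprintf("  lateral coordinates: %s | source: %s\n",
              if (x$unwrapped) "unwrapped" else "wrapped", x$source))
  invisible(x)
}

#' @rdname particle_trajectory
#' @param traj a `particle_trajectory`.
#' @export
n_frames <- function(traj) nrow(traj$x)

#' @rdname particle_trajectory
#' @export
n_particles <- function(traj) ncol(traj$x)

#' Extract one frame
#'
#' @param traj a `particle_trajectory`.
#' @param i frame index.
#' @return list with `positions` (`n_particles x 3` matrix, nm), `box`
#'   (length-3, nm) and `time` (ns).
#' @export
traj_frame <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  list(positions = cbind(x = traj$x[i, ], y = traj$y[i, ], z = traj$z[i, ]),
       box = traj$box[i, ], time = traj$time[i])
}

#' Select particles by tag
#'
#' The selection mini-language is tag equality and tag-set union only: a
#' selection is one tag (`"POPS-P"`) or several tags joined by `|`
#' (`"POPS-P|POPC-P"`). Whitespace around tags is ignored.
#'
#' @param traj a `particle_trajectory`.
#' @param selection selection string, or `NULL` for all particles.
#' @return integer vector of particle indices.
#' @export
select_particles <- function(traj, selection = NULL) {
  if (is.null(selection)) return(seq_len(n_particles(traj)))
  tags <- trimws(strsplit(selection, "|", fixed = TRUE)[[1]])
  tags <- tags[nzchar(tags)]
  if (length(tags) == 0L)
    stop("selection error: empty selection expression", call. = FALSE)
  idx <- which(traj$tags %in% tags)
  if (length(idx) == 0L)
    stop(sprintf("selection error: '%s' matches no particles", selection),
         call. = FALSE)
  idx
}

#' Restrict a trajectory to a particle subset
#'
#' @param traj a `particle_trajectory`.
#' @param idx integer particle indices or a selection string.
#' @return a `particle_trajectory` containing only the selected particles.
#' @export
subset_particles <- function(traj, idx) {
  if (is.character(idx)) idx <- select_particles(traj, idx)
  particle_trajectory(traj$x[, idx, drop = FALSE],
                      traj$y[, idx, drop = FALSE],
                      traj$z[, idx, drop = FALSE],
                      traj$time, traj$box, traj$tags[idx],
                      source = traj$source, unwrapped = traj$unwrapped)
}

#' Assign particles to leaflets
#'
#' Splits headgroup particles into upper and lower leaflets by their z
#' coordinate relative to the median headgroup z of one reference frame. The
#' assignment is fixed for the whole trajectory: lipid flip-flop is not
#' expected on the sub-microsecond timescales this package targets, and a
#' per-frame relabelling would only inject noise.
#'
#' @param traj a `particle_trajectory`.
#' @param reference_frame frame used for the split (default 1).
#' @param selection particles to assign (selection string or indices);
#'   default all particles.
#' @param min_gap minimum z gap (nm) required between the two groups. If the
#'   particles do not separate by at least this much the bilayer geometry is
#'   ambiguous and an error is raised.
#' @return object of class `leaflet_assignment`: list with integer index sets
#'   `upper` and `lower` (indices into the trajectory's particles).
#' @export
assign_leaflets <- function(traj, reference_frame = 1, selection = NULL,
                            min_gap = 0.5) {
  idx <- if (is.character(selection) || is.null(selection))
    select_particles(traj, selection) else as.integer(selection)
  z <- traj$z[reference_frame, idx]
  zc <- stats::median(z)
  upper <- idx[z > zc]
  lower <- idx[z <= zc]
  if (length(upper) == 0L || length(lower) == 0L)
    stop("ambiguous-leaflet error: particles do not split into two leaflets",
         call. = FALSE)
  gap <- min(traj$z[reference_frame, upper]) -
    max(traj$z[reference_frame, lower])
  if (gap < min_gap)
    stop(sprintf(paste0("ambiguous-leaflet error: z gap between putative ",
                        "leaflets is %.3g nm (< min_gap = %.3g nm)"),
                 gap, min_gap), call. = FALSE)
  structure(list(upper = sort(upper), lower = sort(lower),
                 reference_frame = reference_frame),
            class = "leaflet_assignment")
}

#' @export
print.leaflet_assignment <- function(x, ...) {
  cat(sprintf("leaflet_assignment: %d upper / %d lower (reference frame %d)\n",
              length(x$upper), length(x$lower), x$reference_frame))
  invisible(x)
}

#' Unwrap lateral coordinates across periodic images
#'
#' Converts wrapped x,y coordinates into continuous trajectories by choosing,
#' for every particle and frame pair, the periodic image that minimises the
#' frame-to-frame displacement, and accumulating those displacements. This is
#' a prerequisite for mean-squared-displacement analysis. z is untouched.
#'
#' A warning (not an error) is emitted when any single-frame minimum-image
#' displacement exceeds a quarter of the box: such steps are legal but
#' suggest the trajectory is stored too sparsely for reliable unwrapping.
#'
#' @param traj a wrapped `particle_trajectory`.
#' @return a `particle_trajectory` with continuous x,y and `unwrapped = TRUE`.
#' @export
unwrap_lateral <- function(traj) {
  if (isTRUE(traj$unwrapped)) return(traj)
  nf <- n_frames(traj)
  unwrap1 <- function(w, L) {
    if (nf == 1L) return(w)
    d <- w[-1L, , drop = FALSE] - w[-nf, , drop = FALSE]
    Lm <- matrix(L[-1L], nrow = nf - 1L, ncol = ncol(w))
    d <- d - Lm * round(d / Lm)
    if (any(abs(d) > Lm / 4))
      warning(paste("undersampling: per-frame displacement exceeds box/4;",
                    "unwrapping may be unreliable"), call. = FALSE)
    out <- w
    out[-1L, ] <- matrix(w[1L, ], nrow = nf - 1L, ncol = ncol(w),
                         byrow = TRUE) + apply(d, 2L, cumsum)
    out
  }
  traj$x <- unwrap1(traj$x, traj$box[, 1])
  traj$y <- unwrap1(traj$y, traj$box[, 2])
  traj$unwrapped <- TRUE
  traj
}

#' Wrap lateral coordinates into the primary box
#'
#' Inverse of [unwrap_lateral()]: maps x,y back into `[0, L)` per frame.
#'
#' @param traj a `particle_trajectory`.
#' @return a wrapped `particle_trajectory`.
#' @export
wrap_lateral <- function(traj) {
  Lx <- traj$box[, 1]; Ly <- traj$box[, 2]
  traj$x <- traj$x - Lx * floor(traj$x / Lx)
  traj$y <- traj$y - Ly * floor(traj$y / Ly)
  traj$unwrapped <- FALSE
  traj
}
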