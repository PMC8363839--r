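#' Read a structure/trajectory into a particle_trajectory
#'
#' Supported inputs: GRO structures (single- or multi-frame, already in nm),
#' PDB structures and DCD trajectories (via the bio3d package; coordinates
#' are converted from Angstrom to nm), and the package's plain CSV trajectory
#' dialect (see [read_trajectory_csv()]). XTC/TRR are compressed binary
#' formats with no reader in this toolchain and are rejected with a format
#' error. Triclinic boxes are rejected: all analyses here assume an
#' orthorhombic periodic box.
#'
#' Particle tags are built as `"<resname>-<atomname>"` from the structure
#' file (e.g. phosphorus atoms of POPC become `"POPC-P"`), so the tag-based
#' selection language of [select_particles()] applies uniformly across
#' formats.
#'
#' @param structure_path path to a GRO, PDB or CSV file.
#' @param trajectory_path optional path to a DCD trajectory (only meaningful
#'   with a PDB/GRO structure).
#' @param selection optional tag selection applied after reading.
#' @param time_step time between stored frames in ns, used when the source
#'   format does not carry times (GRO, DCD).
#' @param box box lengths (nm) when the source does not carry them.
#' @return a [particle_trajectory()].
#' @export
read_trajectory <- function(structure_path, trajectory_path = NULL,
                            selection = NULL, time_step = 1, box = NULL) {
  if (!file.exists(structure_path))
    stop(sprintf("format error: file '%s' does not exist", structure_path),
         call. = FALSE)
  ext <- tolower(tools::file_ext(structure_path))
  if (!is.null(trajectory_path)) {
    text <- tolower(tools::file_ext(trajectory_path))
    if (text %in% c("xtc", "trr"))
      stop("format error: XTC/TRR are not supported; convert to DCD or the CSV dialect",
           call. = FALSE)
    if (text != "dcd")
      stop(sprintf("format error: unsupported trajectory format '%s'", text),
           call. = FALSE)
  }
  traj <- switch(ext,
    csv = read_trajectory_csv(structure_path, box = box),
    gro = read_gro(structure_path, time_step = time_step),
    pdb = read_pdb_structure(structure_path, box = box),
    stop(sprintf("format error: unsupported structure format '%s'", ext),
         call. = FALSE))
  if (!is.null(trajectory_path))
    traj <- read_dcd_frames(trajectory_path, traj, time_step = time_step)
  if (!is.null(selection)) traj <- subset_particles(traj, selection)
  traj
}

#' Read/write the CSV trajectory dialect
#'
#' The dialect is a flat table with header
#' `frame,time_ns,tag,x,y,z` (coordinates in nm) and optional columns
#' `box_x,box_y,box_z` carrying the per-frame box. Particle order within a
#' frame defines the particle index and must be identical in every frame.
#'
#' @param path file path.
#' @param box length-3 box (nm) used when the file has no box columns.
#' @return `read_trajectory_csv`: a [particle_trajectory()];
#'   `write_trajectory_csv`: the path, invisibly.
#' @export
read_trajectory_csv <- function(path, box = NULL) {
  if (!file.exists(path))
    stop(sprintf("format error: file '%s' does not exist", path), call. = FALSE)
  d <- data.table::fread(path, showProgress = FALSE)
  need <- c("frame", "time_ns", "tag", "x", "y", "z")
  if (!all(need %in% names(d)))
    stop(sprintf("format error: CSV trajectory needs columns %s",
                 paste(need, collapse = ",")), call. = FALSE)
  fr <- sort(unique(d$frame))
  nf <- length(fr)
  first <- d[d$frame == fr[1], ]
  np <- nrow(first)
  tags <- as.character(first$tag)
  X <- Y <- Z <- matrix(NA_real_, nf, np)
  time <- numeric(nf)
  has_box <- all(c("box_x", "box_y", "box_z") %in% names(d))
  B <- matrix(NA_real_, nf, 3)
  for (i in seq_len(nf)) {
    di <- d[d$frame == fr[i], ]
    if (nrow(di) != np)
      stop("format error: frames differ in particle count", call. = FALSE)
    if (!identical(as.character(di$tag), tags))
      stop("format error: particle ordering/tags differ between frames",
           call. = FALSE)
    X[i, ] <- di$x; Y[i, ] <- di$y; Z[i, ] <- di$z
    time[i] <- di$time_ns[1]
    if (has_box) B[i, ] <- c(di$box_x[1], di$box_y[1], di$box_z[1])
  }
  if (!has_box) {
    if (is.null(box))
      stop("format error: CSV has no box columns and no box was supplied",
           call. = FALSE)
    B <- matrix(box, nf, 3, byrow = TRUE)
  }
  particle_trajectory(X, Y, Z, time, B, tags, source = path)
}

#' @rdname read_trajectory_csv
#' @param traj a [particle_trajectory()].
#' @export
write_trajectory_csv <- function(traj, path) {
  nf <- n_frames(traj); np <- n_particles(traj)
  d <- data.table::data.table(
    frame = rep(seq_len(nf), each = np),
    time_ns = rep(traj$time, each = np),
    tag = rep(traj$tags, nf),
    x = as.vector(t(traj$x)),
    y = as.vector(t(traj$y)),
    z = as.vector(t(traj$z)),
    box_x = rep(traj$box[, 1], each = np),
    box_y = rep(traj$box[, 2], each = np),
    box_z = rep(traj$box[, 3], each = np))
  data.table::fwrite(d, path)
  invisible(path)
}

# GRO is fixed-width text: per frame a title line, an atom count, natoms atom
# records (resid 5, resname 5, atomname 5, atomnum 5, then x y z in %8.3f nm)
# and one free-format box line. Multi-frame files are concatenated blocks.
read_gro <- function(path, time_step = 1) {
  lines <- readLines(path)
  pos <- 1L
  frames <- list()
  while (pos <= length(lines) && nzchar(trimws(lines[pos]))) {
    natoms <- suppressWarnings(as.integer(trimws(lines[pos + 1L])))
    if (is.na(natoms))
      stop("format error: malformed GRO atom count", call. = FALSE)
    at <- lines[(pos + 2L):(pos + 1L + natoms)]
    resname <- trimws(substr(at, 6, 10))
    atomname <- trimws(substr(at, 11, 15))
    xyz <- do.call(rbind, lapply(at, function(s) {
      as.numeric(c(substr(s, 21, 28), substr(s, 29, 36), substr(s, 37, 44)))
    }))
    boxline <- as.numeric(strsplit(trimws(lines[pos + 2L + natoms]),
                                   "\\s+")[[1]])
    if (length(boxline) >= 9 && any(abs(boxline[4:9]) > 1e-9))
      stop("format error: triclinic box not supported", call. = FALSE)
    frames[[length(frames) + 1L]] <- list(
      tags = paste(resname, atomname, sep = "-"),
      xyz = xyz, box = boxline[1:3])
    pos <- pos + 3L + natoms
  }
  if (length(frames) == 0L)
    stop("format error: empty GRO file", call. = FALSE)
  tags <- frames[[1L]]$tags
  X <- do.call(rbind, lapply(frames, function(f) f$xyz[, 1]))
  Y <- do.call(rbind, lapply(frames, function(f) f$xyz[, 2]))
  Z <- do.call(rbind, lapply(frames, function(f) f$xyz[, 3]))
  B <- do.call(rbind, lapply(frames, function(f) f$box))
  particle_trajectory(X, Y, Z, time = (seq_along(frames) - 1) * time_step,
                      box = B, tags = tags, source = path)
}

read_pdb_structure <- function(path, box = NULL) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("format error: reading PDB requires the bio3d package", call. = FALSE)
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  tags <- paste(trimws(a$resid), trimws(a$elety), sep = "-")
  if (is.null(box)) {
    # fall back to the coordinate extent when no CRYST1 record is usable
    box <- c(max(a$x) - min(a$x), max(a$y) - min(a$y),
             max(a$z) - min(a$z)) / 10
    box[box <= 0] <- 1
  }
  particle_trajectory(matrix(a$x / 10, 1), matrix(a$y / 10, 1),
                      matrix(a$z / 10, 1), time = 0, box = box,
                      tags = tags, source = path)
}

read_dcd_frames <- function(path, structure_traj, time_step = 1) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("format error: reading DCD requires the bio3d package", call. = FALSE)
  xyz <- bio3d::read.dcd(path, cell = FALSE, verbose = FALSE)
  cell <- tryCatch(bio3d::read.dcd(path, cell = TRUE, verbose = FALSE),
                   error = function(e) NULL)
  nf <- nrow(xyz)
  np <- ncol(xyz) / 3
  if (np != n_particles(structure_traj))
    stop("format error: DCD particle count does not match structure",
         call. = FALSE)
  idx <- seq_len(np)
  X <- xyz[, 3 * idx - 2, drop = FALSE] / 10
  Y <- xyz[, 3 * idx - 1, drop = FALSE] / 10
  Z <- xyz[, 3 * idx, drop = FALSE] / 10
  if (!is.null(cell) && ncol(cell) >= 6) {
    ang <- cell[, 4:6, drop = FALSE]
    if (any(abs(ang - 90) > 1e-3))
      stop("format error: triclinic box not supported", call. = FALSE)
    B <- cell[, 1:3, drop = FALSE] / 10
  } else {
    B <- matrix(structure_traj$box[1, ], nf, 3, byrow = TRUE)
  }
  particle_trajectory(X, Y, Z, time = (seq_len(nf) - 1) * time_step, box = B,
                      tags = structure_traj$tags, source = path)
}
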