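#' Scalar field on a regular x-y grid
#'
#' Container for curvature (nm^-1), thickness (nm) and density (count nm^-2)
#' fields over the membrane plane. Grid nodes are cell centers:
#' x_i = (i - 1/2) Lx / nx, matching the half-open binning convention of the
#' density maps.
#'
#' @param values `nx x ny` numeric matrix (rows index x, columns y).
#' @param box lateral box `(Lx, Ly)` in nm.
#' @param units unit string: `"nm^-1"`, `"nm"` or `"count nm^-2"`.
#' @param kind one of `"curvature"`, `"thickness"`, `"density"`.
#' @param meta optional provenance list.
#' @return an object of class `field2d`.
#' @export
field2d <- function(values, box, units, kind, meta = list()) {
  values <- as.matrix(values)
  if (any(!is.finite(values)))
    stop("field2d values must be finite", call. = FALSE)
  nx <- nrow(values); ny <- ncol(values)
  structure(list(values = values, box = box[1:2],
                 x = (seq_len(nx) - 0.5) * box[1] / nx,
                 y = (seq_len(ny) - 0.5) * box[2] / ny,
                 units = units, kind = kind, meta = meta),
            class = "field2d")
}

#' @export
print.field2d <- function(x, ...) {
  cat(sprintf("field2d [%s]: %d x %d grid over %.3g x %.3g nm, %s\n",
              x$kind, nrow(x$values), ncol(x$values), x$box[1], x$box[2],
              x$units))
  cat(sprintf("  range: %.4g .. %.4g, mean %.4g\n", min(x$values),
              max(x$values), mean(x$values)))
  invisible(x)
}

#' @export
mean.field2d <- function(x, ...) mean(x$values)

#' @export
plot.field2d <- function(x, main = NULL, ...) {
  pal <- grDevices::hcl.colors(64, if (x$kind == "curvature") "Blue-Red"
                               else "Viridis")
  graphics::image(x$x, x$y, x$values, col = pal, asp = 1,
                  xlab = "x (nm)", ylab = "y (nm)",
                  main = if (is.null(main))
                    sprintf("%s (%s)", x$kind, x$units) else main, ...)
  invisible(x)
}

#' Average a time series of fields
#'
#' @param fields list of `field2d` on identical grids.
#' @param window terminal fraction of the series to keep (default 1 = all).
#' @return a `field2d` holding the node-wise mean over the retained frames.
#' @export
average_fields <- function(fields, window = 1) {
  stopifnot(length(fields) >= 1)
  nf <- length(fields)
  keep <- seq.int(nf - ceiling(window * nf) + 1L, nf)
  acc <- Reduce(`+`, lapply(fields[keep], function(f) f$values)) / length(keep)
  f1 <- fields[[1]]
  field2d(acc, f1$box, f1$units, f1$kind,
          meta = c(f1$meta, list(frames_used = range(keep), n_frames = nf)))
}

#' Write/read a field as a CSV matrix with a small header block
#'
#' The header is comment lines (`# key: value`) carrying box, units and kind,
#' followed by the value matrix (rows = x index).
#'
#' @param field a `field2d`.
#' @param path file path.
#' @export
write_field_csv <- function(field, path) {
  hdr <- c(sprintf("# box_nm: %.10g %.10g", field$box[1], field$box[2]),
           sprintf("# units: %s", field$units),
           sprintf("# kind: %s", field$kind))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(field$values, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_field_csv
#' @export
read_field_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) sub(sprintf("^# %s: ", key), "",
                           grep(sprintf("^# %s:", key), hdr, value = TRUE))
  vals <- as.matrix(utils::read.table(text = lines[!grepl("^#", lines)],
                                      sep = ","))
  dimnames(vals) <- NULL
  field2d(vals, as.numeric(strsplit(get("box_nm"), " ")[[1]]),
          get("units"), get("kind"))
}
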