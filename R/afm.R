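#' AFM height image container
#'
#' @param z numeric matrix of heights in nm (rows = x pixel index, columns =
#'   y pixel index).
#' @param pixel_size lateral size of one pixel in nm.
#' @param label condition label (free text).
#' @return object of class `height_image`.
#' @export
height_image <- function(z, pixel_size, label = "") {
  z <- as.matrix(z)
  if (any(!is.finite(z))) stop("heights must be finite", call. = FALSE)
  if (pixel_size <= 0) stop("pixel_size must be positive", call. = FALSE)
  structure(list(z = z, pixel_size = pixel_size, label = label),
            class = "height_image")
}

#' @export
print.height_image <- function(x, ...) {
  cat(sprintf("height_image: %d x %d px, %.3g nm/px%s\n", nrow(x$z), ncol(x$z),
              x$pixel_size,
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  cat(sprintf("  height range: %.3g .. %.3g nm\n", min(x$z), max(x$z)))
  invisible(x)
}

#' @export
plot.height_image <- function(x, ...) {
  graphics::image(seq_len(nrow(x$z)) * x$pixel_size,
                  seq_len(ncol(x$z)) * x$pixel_size, x$z,
                  col = grDevices::hcl.colors(64, "YlOrBr", rev = TRUE),
                  asp = 1, xlab = "x (nm)", ylab = "y (nm)", ...)
  invisible(x)
}

#' Read / write AFM height images
#'
#' Plain-text matrices (whitespace-separated, one row per line) and
#' greyscale TIFF (via the tiff package; values are used as nm directly
#' unless `scale` is given) are supported. The pixel size is metadata the
#' formats do not carry, so it must be supplied.
#'
#' @param path file path (`.txt`/`.dat`/`.csv` matrix or `.tif`/`.tiff`).
#' @param pixel_size nm per pixel.
#' @param scale multiplicative conversion applied to TIFF values.
#' @param label condition label.
#' @return a [height_image()].
#' @export
read_height_image <- function(path, pixel_size, scale = 1, label = "") {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the tiff package", call. = FALSE)
    z <- tiff::readTIFF(path) * scale
    if (length(dim(z)) == 3) z <- z[, , 1]
  } else {
    sep <- if (ext == "csv") "," else ""
    z <- as.matrix(utils::read.table(path, sep = sep))
    dimnames(z) <- NULL
  }
  height_image(z, pixel_size, label)
}

#' @rdname read_height_image
#' @param image a [height_image()].
#' @export
write_height_image <- function(image, path) {
  utils::write.table(image$z, path, sep = " ", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

# two-level threshold: midpoint of a 2-means split of the pixel values
two_level_threshold <- function(z) {
  v <- as.vector(z)
  if (diff(range(v)) < 1e-12) return(-Inf)  # single level: nothing below
  km <- stats::kmeans(v, centers = range(v), iter.max = 50)
  mean(km$centers)
}

#' Subtract the background tilt plane
#'
#' Scanner tilt is ubiquitous in AFM topographs. The substrate pixels (the
#' lower of the two height populations) are identified by a two-level
#' threshold, a least-squares plane is fitted through them, and the plane is
#' subtracted from the whole image, leaving the substrate at ~0.
#'
#' @param image a [height_image()].
#' @return a levelled [height_image()].
#' @export
subtract_plane <- function(image) {
  z <- image$z
  thr <- two_level_threshold(z)
  sub <- z < thr
  if (!any(sub) || all(sub)) return(image)
  ix <- row(z)[sub]; iy <- col(z)[sub]
  fit <- stats::lm.fit(cbind(1, ix, iy), z[sub])
  plane <- fit$coefficients[1] + fit$coefficients[2] * row(z) +
    fit$coefficients[3] * col(z)
  image$z <- z - plane
  image
}

# bilinear interpolation of the image at fractional pixel coordinates
bilinear <- function(z, px, py) {
  nx <- nrow(z); ny <- ncol(z)
  px <- pmin(pmax(px, 1), nx); py <- pmin(pmax(py, 1), ny)
  x0 <- pmin(floor(px), nx - 1L); y0 <- pmin(floor(py), ny - 1L)
  fx <- px - x0; fy <- py - y0
  z[cbind(x0, y0)] * (1 - fx) * (1 - fy) +
    z[cbind(x0 + 1L, y0)] * fx * (1 - fy) +
    z[cbind(x0, y0 + 1L)] * (1 - fx) * fy +
    z[cbind(x0 + 1L, y0 + 1L)] * fx * fy
}

#' Cross-sectional line profile
#'
#' Samples the image along the segment p0 -> p1 at one-pixel spacing, and at
#' each sample averages `thickness_px` parallel samples offset perpendicular
#' to the segment (the "five pixels thick" line of AFM practice), which
#' suppresses single-pixel noise and debris.
#'
#' @param image a [height_image()].
#' @param p0,p1 segment endpoints in pixel coordinates `(x, y)` (may be
#'   fractional), inside the image.
#' @param thickness_px width of the averaging band in pixels (default 5).
#' @return object of class `line_profile`: `distance_px`, `distance_nm`,
#'   `height` (nm).
#' @export
extract_profile <- function(image, p0, p1, thickness_px = 5) {
  v <- p1 - p0
  len <- sqrt(sum(v^2))
  if (len < 1e-9)
    stop("geometry error: profile endpoints coincide", call. = FALSE)
  nx <- nrow(image$z); ny <- ncol(image$z)
  if (any(c(p0, p1) < 1) || p0[1] > nx || p1[1] > nx || p0[2] > ny ||
      p1[2] > ny)
    stop("geometry error: endpoints outside the image", call. = FALSE)
  u <- v / len
  perp <- c(-u[2], u[1])
  t <- seq(0, len, by = 1)
  offs <- seq_len(thickness_px) - (thickness_px + 1) / 2
  h <- vapply(t, function(ti) {
    cx <- p0[1] + u[1] * ti + perp[1] * offs
    cy <- p0[2] + u[2] * ti + perp[2] * offs
    mean(bilinear(image$z, cx, cy))
  }, numeric(1))
  structure(list(distance_px = t, distance_nm = t * image$pixel_size,
                 height = h),
            class = "line_profile")
}

#' Step height of a two-plateau profile
#'
#' The edge is located at the maximum absolute gradient of the profile; the
#' two plateau levels are the medians of the samples on either side (a guard
#' band of `guard_px` samples around the edge is excluded when enough samples
#' remain). The step is the difference upper minus lower, reported positive.
#' Medians are used because edge-rounding pixels and debris make means
#' unreliable.
#'
#' @param profile a [extract_profile()] result or a plain numeric vector.
#' @param guard_px samples to drop on each side of the edge.
#' @param snr minimum ratio of step to plateau noise below which no step is
#'   declared.
#' @return step height in nm.
#' @export
step_height <- function(profile, guard_px = 2, snr = 5) {
  h <- if (is.list(profile)) profile$height else as.numeric(profile)
  n <- length(h)
  if (n < 4) stop("no-step error: profile too short", call. = FALSE)
  g <- diff(h)
  edge <- which.max(abs(g))
  left <- seq_len(max(1L, edge - guard_px))
  right <- seq.int(min(n, edge + 1L + guard_px), n)
  lo <- stats::median(h[left]); hi <- stats::median(h[right])
  step <- abs(hi - lo)
  noise <- stats::mad(c(h[left] - lo, h[right] - hi))
  if (step <= 0 || (noise > 0 && step < snr * noise) ||
      (noise == 0 && max(abs(g)) < 1e-9))
    stop("no-step error: no detectable step in profile", call. = FALSE)
  step
}

# connected components of a logical mask (4-neighbour flood fill)
label_components <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  lab <- matrix(0L, nx, ny)
  stack <- integer(sum(mask))
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    lab[start] <- cur
    stack[1L] <- start
    top <- 1L
    while (top > 0L) {
      p <- stack[top]
      top <- top - 1L
      i <- (p - 1L) %% nx + 1L
      j <- (p - 1L) %/% nx + 1L
      if (i > 1L) { q <- p - 1L
        if (mask[q] && lab[q] == 0L) { lab[q] <- cur; top <- top + 1L; stack[top] <- q } }
      if (i < nx) { q <- p + 1L
        if (mask[q] && lab[q] == 0L) { lab[q] <- cur; top <- top + 1L; stack[top] <- q } }
      if (j > 1L) { q <- p - nx
        if (mask[q] && lab[q] == 0L) { lab[q] <- cur; top <- top + 1L; stack[top] <- q } }
      if (j < ny) { q <- p + nx
        if (mask[q] && lab[q] == 0L) { lab[q] <- cur; top <- top + 1L; stack[top] <- q } }
    }
  }
  lab
}

#' Bilayer height from an AFM topograph
#'
#' Reproduces the standard SLB height measurement: the image is levelled
#' ([subtract_plane()]), holes down to the substrate are detected by a
#' two-level threshold, and `n_lines` cross-sections are drawn across the
#' hole edges (radially from the hole center, perpendicular to the boundary
#' of a circular hole). Each profile yields one [step_height()]; the
#' estimate aggregates them. Line placement is deterministic: the same image
#' always gives the same lines.
#'
#' @param image a [height_image()].
#' @param lines optional list of `list(p0 = c(x, y), p1 = c(x, y))` pixel
#'   segments; when given, auto-detection is skipped.
#' @param n_lines number of auto-placed lines (default 10).
#' @param thickness_px band width for [extract_profile()].
#' @param level subtract the background plane first (default TRUE).
#' @return object of class `step_estimate`: per-line `heights` (nm), `mean`,
#'   `sd`, `sem`, `n_lines`, and the `lines` used.
#' @export
bilayer_height <- function(image, lines = NULL, n_lines = 10,
                           thickness_px = 5, level = TRUE) {
  if (level) image <- subtract_plane(image)
  if (is.null(lines)) {
    thr <- two_level_threshold(image$z)
    holes <- label_components(image$z < thr)
    if (max(holes) == 0L)
      stop("no-step error: no holes detected and no lines given",
           call. = FALSE)
    sizes <- tabulate(holes[holes > 0L])
    hole <- which.max(sizes)
    sel <- holes == hole
    cx <- mean(row(image$z)[sel]); cy <- mean(col(image$z)[sel])
    r <- sqrt(sum(sel) / pi)
    nx <- nrow(image$z); ny <- ncol(image$z)
    lines <- list()
    for (k in seq_len(n_lines)) {
      ang <- 2 * pi * (k - 1) / n_lines
      dir <- c(cos(ang), sin(ang))
      p0 <- c(cx, cy) + dir * r * 0.25
      p1 <- c(cx, cy) + dir * r * 2.2
      p0 <- pmin(pmax(p0, 1), c(nx, ny))
      p1 <- pmin(pmax(p1, 1), c(nx, ny))
      if (sqrt(sum((p1 - p0)^2)) >= r)
        lines[[length(lines) + 1L]] <- list(p0 = p0, p1 = p1)
    }
    if (length(lines) == 0L)
      stop("no-step error: could not place any edge-crossing line",
           call. = FALSE)
  }
  heights <- vapply(lines, function(ln) {
    step_height(extract_profile(image, ln$p0, ln$p1,
                                thickness_px = thickness_px))
  }, numeric(1))
  structure(list(heights = heights, mean = mean(heights),
                 sd = stats::sd(heights),
                 sem = stats::sd(heights) / sqrt(length(heights)),
                 n_lines = length(heights), lines = lines,
                 label = image$label),
            class = "step_estimate")
}

#' @export
print.step_estimate <- function(x, ...) {
  cat(sprintf("bilayer height: %.3f +- %.3f nm (sd; n = %d lines)%s\n",
              x$mean, x$sd, x$n_lines,
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  invisible(x)
}
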