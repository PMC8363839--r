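#' Area per lipid
#'
#' Lateral box area divided by the number of lipids per leaflet. Depends only
#' on (Lx, Ly) and the count, never on particle coordinates.
#'
#' @param box a length-2+ vector `(Lx, Ly, ...)` in nm, or a frame from
#'   [traj_frame()].
#' @param lipids_per_leaflet lipid count per leaflet (> 0).
#' @return area per lipid in nm^2.
#' @export
area_per_lipid <- function(box, lipids_per_leaflet) {
  if (is.list(box)) box <- box$box
  if (lipids_per_leaflet <= 0)
    stop("parameter error: lipids_per_leaflet must be positive", call. = FALSE)
  box[1] * box[2] / lipids_per_leaflet
}

#' TFP-to-lipid ratio
#'
#' @param n_tfp number of intercalated TFP molecules.
#' @param n_lipids total lipid count of the bilayer.
#' @return ratio in percent.
#' @export
tfp_lipid_ratio <- function(n_tfp, n_lipids) 100 * n_tfp / n_lipids

#' Mean bilayer thickness
#'
#' Area-weighted average of a thickness field: on the uniform grids used here
#' this is the plain mean over nodes.
#'
#' @param field a thickness [field2d()].
#' @return mean thickness in nm.
#' @export
mean_thickness <- function(field) {
  stopifnot(inherits(field, "field2d"), field$kind == "thickness")
  mean(field$values)
}

#' Per-condition summary record
#'
#' @param label condition name (e.g. `"0TFP"`, `"24TFP"`, `"48TFP"`).
#' @param apl area per lipid (nm^2).
#' @param mean_thickness mean P-P thickness (nm).
#' @param footprint optional [curvature_footprint()] summary.
#' @param D optional [fit_diffusion()] estimate.
#' @return object of class `condition_summary`.
#' @export
condition_summary <- function(label, apl, mean_thickness,
                              footprint = NULL, D = NULL) {
  stopifnot(apl > 0, mean_thickness > 0)
  structure(list(label = label, apl = apl, mean_thickness = mean_thickness,
                 footprint = footprint, D = D),
            class = "condition_summary")
}

#' Dose-effect trend report across conditions
#'
#' Checks whether scalar metrics are strictly monotone across conditions
#' ordered by dose (the order of `summaries`). Strict inequalities are used,
#' optionally slackened by `tolerance`.
#'
#' @param summaries list of [condition_summary()] in increasing-dose order.
#' @param expected named character vector mapping metric name (`"apl"`,
#'   `"mean_thickness"`, ...) to `"increasing"` or `"decreasing"`.
#' @param tolerance slack allowed on each pairwise comparison (default 0:
#'   strict ordering).
#' @return object of class `trend_report`: per metric the observed values,
#'   the observed ordering permutation, and a pass/fail verdict; plus a
#'   `to_json`-able list structure.
#' @export
dose_trend_report <- function(summaries,
                              expected = c(mean_thickness = "decreasing",
                                           apl = "increasing"),
                              tolerance = 0) {
  if (length(summaries) < 2)
    stop("input error: need at least 2 conditions", call. = FALSE)
  labels <- vapply(summaries, `[[`, character(1), "label")
  if (anyDuplicated(labels))
    stop("input error: duplicate condition labels", call. = FALSE)
  res <- lapply(names(expected), function(metric) {
    v <- vapply(summaries, function(s) as.numeric(s[[metric]]), numeric(1))
    d <- diff(v)
    pass <- if (expected[[metric]] == "increasing") all(d > -tolerance)
            else all(d < tolerance)
    list(metric = metric, direction = expected[[metric]],
         values = stats::setNames(v, labels),
         observed_order = labels[order(v)], pass = pass)
  })
  names(res) <- names(expected)
  structure(list(conditions = labels, trends = res), class = "trend_report")
}

#' @export
print.trend_report <- function(x, ...) {
  cat("dose-effect trends over:", paste(x$conditions, collapse = " -> "), "\n")
  for (t in x$trends)
    cat(sprintf("  %s expected %s: %s  [%s]\n", t$metric, t$direction,
                paste(sprintf("%.4g", t$values), collapse = ", "),
                if (t$pass) "pass" else
                  paste("FAIL; observed", paste(t$observed_order,
                                                collapse = " < "))))
  invisible(x)
}

#' Serialise a trend report (or any summary record) to JSON
#'
#' @param x object to serialise.
#' @param path optional output path; when `NULL` the JSON string is returned.
#' @export
to_json <- function(x, path = NULL) {
  x <- unclass(x)
  if (is.null(path))
    jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    invisible(path)
  }
}
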