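#' Suitability class scheme
#'
#' Four IPCC-style habitat classes cut at 0.2 / 0.5 / 0.7 on the logistic
#' suitability scale: 0 unsuitable `[0, 0.2)`, 1 marginally suitable
#' `[0.2, 0.5)`, 2 moderately suitable `[0.5, 0.7)`, 3 most suitable
#' `[0.7, 1]`. Boundaries are assigned upward (half-open convention).
#'
#' @param cuts strictly increasing thresholds inside (0,1).
#' @return a `suitability_classes` object.
#' @export
suitability_classes <- function(cuts = c(0.2, 0.5, 0.7)) {
  if (length(cuts) != 3 || any(diff(cuts) <= 0) || any(cuts <= 0) ||
      any(cuts >= 1))
    stop("cuts must be 3 strictly increasing values inside (0,1)")
  structure(list(cuts = cuts,
                 labels = c("unsuitable", "marginal", "moderate", "most")),
            class = "suitability_classes")
}

#' Classify continuous suitability
#'
#' @param suit continuous [grid_layer()] with values in `[0,1]`.
#' @param classes a [suitability_classes()].
#' @return categorical [grid_layer()] with codes 0-3; mask propagated.
#' @export
classify_suitability <- function(suit, classes = suitability_classes()) {
  v <- suit$values
  vv <- v[!is.na(v)]
  if (length(vv) && (min(vv) < 0 || max(vv) > 1))
    stop("suitability values outside [0,1]")
  out <- matrix(NA_real_, nrow(v), ncol(v))
  out[!is.na(v)] <- findInterval(vv, classes$cuts)
  grid_layer(out, suit$cellsize, suit$origin, suit$crs_tag, "categorical")
}

#' Per-class habitat area table
#'
#' Areas in km2 per suitability class; the total suitable area is the sum
#' of classes 1-3 (marginal + moderate + most). Percentages of the total
#' are reported to 1 decimal (half away from zero).
#'
#' @param classified categorical [grid_layer()] with codes 0-3, or `NULL`
#'   when `areas` is given directly.
#' @param cellsize cell edge in metres (taken from the layer if omitted).
#' @param areas optional named numeric `c(marginal=, moderate=, most=)`
#'   in km2, bypassing the raster count (used to ingest published tables).
#' @param scenario tag carried in the output.
#' @return an `area_table`: data.frame with columns `class`, `label`,
#'   `area_km2`, `pct_of_total`; total in the `total_km2` attribute.
#' @export
area_table <- function(classified = NULL, cellsize = NULL, areas = NULL,
                       scenario = "present") {
  labels <- c("unsuitable", "marginal", "moderate", "most")
  if (is.null(areas)) {
    v <- classified$values[!is.na(classified$values)]
    if (length(setdiff(unique(v), 0:3)))
      stop(sprintf("unknown class label(s): %s",
                   paste(setdiff(unique(v), 0:3), collapse = ", ")))
    if (is.null(cellsize)) cellsize <- classified$cellsize
    counts <- vapply(0:3, function(k) sum(v == k), 0)
    a <- counts * cellsize^2 / 1e6
  } else {
    need <- c("marginal", "moderate", "most")
    if (!all(need %in% names(areas)))
      stop("areas must name marginal, moderate and most")
    a <- c(if ("unsuitable" %in% names(areas)) areas[["unsuitable"]] else 0,
           areas[["marginal"]], areas[["moderate"]], areas[["most"]])
  }
  total <- sum(a[2:4])
  pct <- if (total > 0) round_half_up(100 * a / total, 1) else rep(NA_real_, 4)
  pct[1] <- NA_real_  # class 0 is not part of the suitable total
  out <- data.frame(class = 0:3, label = labels, area_km2 = a,
                    pct_of_total = pct, stringsAsFactors = FALSE)
  structure(out, class = c("area_table", "data.frame"),
            total_km2 = total, scenario = scenario)
}

#' @export
print.area_table <- function(x, ...) {
  cat(sprintf("<area_table> scenario '%s', total suitable %.0f km2\n",
              attr(x, "scenario"), attr(x, "total_km2")))
  print.data.frame(x)
  invisible(x)
}

#' Load a published habitat-area table
#'
#' Reads a CSV with a `category` column (`marginal`, `moderate`, `most`)
#' and one column per scenario, as shipped in
#' `system.file("extdata", "table3_areas.csv", package = "ecocorridor")`.
#'
#' @param path CSV path.
#' @param scenario column name to load.
#' @return an [area_table()].
#' @export
load_area_table <- function(path, scenario) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!(scenario %in% names(d)))
    stop(sprintf("no scenario column '%s' in %s", scenario, path))
  a <- stats::setNames(d[[scenario]], d$category)
  area_table(areas = a, scenario = scenario)
}

#' Habitat-area change between two scenarios
#'
#' @param a,b [area_table()]s under the same class scheme (`a` the
#'   baseline).
#' @return list: `abs_change` = total(b) - total(a) in km2 (negative for
#'   a loss), `pct_change` = `100 * (total(a) - total(b)) / total(a)`
#'   (positive for a loss), reported to 2 decimals.
#' @export
scenario_delta <- function(a, b) {
  ta <- attr(a, "total_km2"); tb <- attr(b, "total_km2")
  if (ta == 0) stop("baseline total area is zero")
  list(abs_change = tb - ta,
       pct_change = round_half_up(100 * (ta - tb) / ta, 2))
}

#' Suitability-weighted habitat centroid
#'
#' Centre of mass of the suitable area: cell centres weighted by the
#' continuous suitability over cells of class >= 1 (or unit weights with
#' `weighted = FALSE`), plus the equally weighted mean elevation.
#'
#' @param suit continuous suitability [grid_layer()].
#' @param classified matching categorical class layer.
#' @param dem optional DEM layer for the mean-elevation component.
#' @param weighted weight by suitability (default) or binary.
#' @return a `habitat_centroid`: list with `x`, `y`, `mean_elevation`.
#' @export
habitat_centroid <- function(suit, classified, dem = NULL, weighted = TRUE) {
  sel <- !is.na(classified$values) & classified$values >= 1
  if (!any(sel)) stop("no suitable cells (class >= 1)")
  w <- if (weighted) suit$values[sel] else rep(1, sum(sel))
  cc <- cell_centers(suit)
  idx <- which(sel, arr.ind = TRUE)
  xs <- cc$x[idx[, 2]]; ys <- cc$y[idx[, 1]]
  me <- if (!is.null(dem)) {
    z <- dem$values[sel]
    sum(w * z, na.rm = TRUE) / sum(w[!is.na(z)])
  } else NA_real_
  structure(list(x = sum(w * xs) / sum(w), y = sum(w * ys) / sum(w),
                 mean_elevation = me), class = "habitat_centroid")
}

#' Displacement between two habitat centroids
#'
#' @param c1,c2 [habitat_centroid()]s (from, to).
#' @return list: `distance` m, `bearing` degrees clockwise from north
#'   (`NaN` for zero displacement), `elevation_change` = c2 - c1 in m.
#' @export
centroid_shift <- function(c1, c2) {
  dx <- c2$x - c1$x; dy <- c2$y - c1$y
  d <- sqrt(dx^2 + dy^2)
  bearing <- if (d == 0) NaN else (atan2(dx, dy) * 180 / pi) %% 360
  list(distance = d, bearing = bearing,
       elevation_change = c2$mean_elevation - c1$mean_elevation)
}

# round half away from zero, matching how printed percentages are rounded
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
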