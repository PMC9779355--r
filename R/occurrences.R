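#' Construct an occurrence set
#'
#' Species presence points in projected (metric) coordinates.
#'
#' @param x,y numeric coordinate vectors in metres.
#' @param source_tag character vector (recycled) labelling the provenance
#'   of each point (e.g. "gbif", "uav").
#' @param crs_tag CRS label.
#' @return object of class `occurrence_set`: a data.frame with columns
#'   `x`, `y`, `source`.
#' @export
occurrence_set <- function(x, y, source_tag = "unknown", crs_tag = "local") {
  if (length(x) != length(y)) stop("x and y must have equal length")
  d <- data.frame(x = as.numeric(x), y = as.numeric(y),
                  source = rep_len(as.character(source_tag), length(x)),
                  stringsAsFactors = FALSE)
  structure(d, class = c("occurrence_set", "data.frame"), crs_tag = crs_tag)
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf("<occurrence_set> %d points (crs '%s')\n", nrow(x),
              attr(x, "crs_tag")))
  if (nrow(x)) print.data.frame(utils::head(x, 6))
  invisible(x)
}

#' Load occurrence points from CSV
#'
#' Expects header columns `x`, `y` and optionally `source`. Exact duplicate
#' coordinates are collapsed. Coordinates that look like geographic
#' lon/lat (|x| <= 180 and |y| <= 90) are refused unless `force = TRUE`,
#' because thinning distances are computed in projected metres.
#'
#' @param path CSV path.
#' @param force allow coordinates in the lon/lat-looking range.
#' @param crs_tag CRS label.
#' @return an [occurrence_set()].
#' @export
load_points <- function(path, force = FALSE, crs_tag = "local") {
  if (!file.exists(path)) stop(sprintf("cannot read points '%s': no such file", path))
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("x", "y"), names(d))
  if (length(miss))
    stop(sprintf("points file '%s' is missing column(s): %s", path,
                 paste(miss, collapse = ", ")))
  for (col in c("x", "y")) {
    v <- d[[col]]
    if (!is.numeric(v)) {
      vv <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(vv) & !is.na(v) & v != "")
      if (length(bad))
        stop(sprintf("points file '%s': non-numeric %s at data row %d ('%s')",
                     path, col, bad[1], v[bad[1]]))
      d[[col]] <- vv
    }
  }
  bad <- which(is.na(d$x) | is.na(d$y))
  if (length(bad))
    stop(sprintf("points file '%s': missing coordinate at data row %d",
                 path, bad[1]))
  if (!force && nrow(d) && all(abs(d$x) <= 180) && all(abs(d$y) <= 90))
    stop(sprintf(paste0("points file '%s' looks like lon/lat degrees; project ",
                        "to metres first or pass force = TRUE"), path))
  if (!("source" %in% names(d))) d$source <- "unknown"
  keep <- !duplicated(d[, c("x", "y")])
  occurrence_set(d$x[keep], d$y[keep], d$source[keep], crs_tag = crs_tag)
}

#' Save occurrence points to CSV
#'
#' @param occ an [occurrence_set()].
#' @param path output CSV path.
#' @param kept optional logical audit vector written as a `kept` column.
#' @return `path`, invisibly.
#' @export
save_points <- function(occ, path, kept = NULL) {
  d <- as.data.frame(occ)
  if (!is.null(kept)) d$kept <- kept
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Spatially thin occurrence points
#'
#' Greedy randomized thinning against spatial autocorrelation: points are
#' visited in a seeded random order and accepted only if at least
#' `min_dist` metres from every previously accepted point. The retained
#' set is maximal (no discarded point could be re-added) and all pairwise
#' distances are >= `min_dist`. Deterministic given `seed`.
#'
#' @param occ an [occurrence_set()].
#' @param min_dist minimum pairwise distance in metres (default 100, the
#'   conventional cut against duplicate sightings of the same group).
#' @param seed integer seed for the visiting order.
#' @return thinned [occurrence_set()].
#' @export
thin <- function(occ, min_dist = 100, seed = 1L) {
  if (!is.numeric(min_dist) || min_dist <= 0) stop("min_dist must be > 0")
  n <- nrow(occ)
  if (n == 0L) return(occ)
  ord <- with_seed(seed, sample.int(n))
  acc <- integer(0)
  ax <- numeric(0); ay <- numeric(0)
  for (i in ord) {
    if (!length(acc) ||
        min((ax - occ$x[i])^2 + (ay - occ$y[i])^2) >= min_dist^2) {
      acc <- c(acc, i)
      ax <- c(ax, occ$x[i]); ay <- c(ay, occ$y[i])
    }
  }
  acc <- sort(acc)
  occurrence_set(occ$x[acc], occ$y[acc], occ$source[acc],
                 crs_tag = attr(occ, "crs_tag"))
}

# evaluate expr under a local RNG seed without disturbing the global stream
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
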