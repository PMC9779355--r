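#' Build a resistance scheme from fitted response curves
#'
#' The coupling between the suitability model and the resistance surface:
#' each factor's marginal response is sampled on an `n_points` grid and
#' each point is assigned one of five resistance levels
#' (10, 20, 30, 40, 50) by suitability quintile — the most suitable fifth
#' of the response gets resistance 10, the least suitable fifth 50.
#' Consecutive equal-level points are merged into intervals (the interval
#' set of a factor may be non-contiguous). The per-factor weights are the
#' model's percent contributions. A flat (uninformative) response yields
#' a single all-range level-30 interval with a warning.
#'
#' @param model a `maxent_model`.
#' @param contributions named per-variable weights (e.g. from
#'   [percent_contribution()]); defaults to the model's own contributions.
#' @param n_levels number of resistance levels (fixed 5-level ladder).
#' @param n_points response-curve sample points.
#' @return a `resistance_scheme`: per factor a data.frame of bins
#'   (`resistance`, `lower`, `upper` for continuous; `resistance`, `code`
#'   for categorical) plus a named weight vector.
#' @export
scheme_from_response <- function(model, contributions = NULL, n_levels = 5,
                                 n_points = 100) {
  if (n_levels != 5) stop("the resistance ladder is fixed at 5 levels")
  if (is.null(contributions)) contributions <- percent_contribution(model)
  bins <- list()
  for (v in model$vars) {
    rc <- response_curve(model, v, n_points = n_points)
    flat <- (max(rc$suitability) - min(rc$suitability)) < 1e-9
    if (model$kinds[[v]] == "categorical") {
      lev <- if (flat) rep(30, nrow(rc)) else quintile_levels(rc$suitability)
      if (flat) warning(sprintf("flat response for '%s': all-level-30 scheme", v))
      bins[[v]] <- data.frame(resistance = lev, code = rc$value)
    } else {
      if (flat) {
        warning(sprintf("flat response for '%s': all-level-30 scheme", v))
        bins[[v]] <- data.frame(resistance = 30, lower = rc$value[1],
                                upper = rc$value[nrow(rc)])
        next
      }
      lev <- quintile_levels(rc$suitability)
      # merge consecutive equal levels into intervals split at midpoints
      run_end <- c(which(diff(lev) != 0), length(lev))
      run_start <- c(1, utils::head(run_end, -1) + 1)
      mid <- (rc$value[utils::head(run_end, -1)] +
              rc$value[utils::head(run_end, -1) + 1]) / 2
      lower <- c(rc$value[1], mid)
      upper <- c(mid, rc$value[nrow(rc)])
      bins[[v]] <- data.frame(resistance = lev[run_start],
                              lower = lower, upper = upper)
    }
  }
  resistance_scheme(bins, contributions[model$vars])
}

# map suitabilities to the 10..50 ladder by descending-suitability quintile
quintile_levels <- function(s) {
  n <- length(s)
  r <- rank(-s, ties.method = "first")
  10 * ceiling(5 * r / n)
}

#' Construct a resistance scheme
#'
#' @param bins named list; per continuous factor a data.frame with
#'   columns `resistance`, `lower`, `upper` (intervals `(lower, upper]`,
#'   the lowest closed), per categorical factor columns `resistance`,
#'   `code` (or `label`).
#' @param weights named non-negative weights (normalized to sum 1 when
#'   the surface is built).
#' @return a `resistance_scheme`.
#' @export
resistance_scheme <- function(bins, weights) {
  if (is.null(names(bins)) || is.null(names(weights)))
    stop("bins and weights must be named by factor")
  miss <- setdiff(names(bins), names(weights))
  if (length(miss))
    stop(sprintf("no weight for factor(s): %s", paste(miss, collapse = ", ")))
  if (any(weights < 0)) stop("weights must be non-negative")
  for (v in names(bins)) {
    b <- bins[[v]]
    if (!all(b$resistance %in% c(10, 20, 30, 40, 50)))
      stop(sprintf("factor '%s': resistance values must be in {10,20,30,40,50}", v))
  }
  structure(list(bins = bins, weights = weights[names(bins)]),
            class = "resistance_scheme")
}

#' @export
print.resistance_scheme <- function(x, ...) {
  cat(sprintf("<resistance_scheme> %d factors, weight total %.3f\n",
              length(x$bins), sum(x$weights)))
  for (v in names(x$bins))
    cat(sprintf("  %-6s weight %.3f, %d bin(s)\n", v, x$weights[[v]],
                nrow(x$bins[[v]])))
  invisible(x)
}

# resistance level of raw values under one factor's bins
lookup_resistance <- function(vals, b, factor_name) {
  out <- rep(NA_real_, length(vals))
  if ("code" %in% names(b)) {
    for (i in seq_len(nrow(b))) out[vals == b$code[i]] <- b$resistance[i]
  } else {
    lo_min <- min(b$lower)
    for (i in seq_len(nrow(b))) {
      hit <- (vals > b$lower[i] | (b$lower[i] == lo_min & vals >= lo_min)) &
        vals <= b$upper[i]
      out[hit] <- b$resistance[i]
    }
  }
  bad <- which(is.na(out) & !is.na(vals))
  if (length(bad))
    stop(sprintf("factor '%s': value %g falls in no resistance interval",
                 factor_name, vals[bad[1]]))
  out
}

#' Contribution-weighted resistance surface
#'
#' `R(x) = sum_f w_f r_f(x)` with the weights normalized to sum 1, so the
#' surface lies in `[10, 50]` and is invariant to uniform weight
#' rescaling. A cell value covered by no interval of its factor is an
#' error (schemes must cover the observed range).
#'
#' @param stack an [env_stack()] containing every scheme factor.
#' @param scheme a [resistance_scheme()].
#' @return continuous [grid_layer()]; joint mask propagated.
#' @export
resistance_surface <- function(stack, scheme) {
  miss <- setdiff(names(scheme$bins), names(stack$layers))
  if (length(miss))
    stop(sprintf("stack is missing scheme factor(s): %s",
                 paste(miss, collapse = ", ")))
  w <- scheme$weights
  if (sum(w) <= 0) stop("scheme weights sum to zero")
  w <- w / sum(w)
  ref <- stack_ref(stack)
  ok <- joint_valid_mask(stack_subset(stack, names(scheme$bins)))
  cells <- which(ok)
  acc <- numeric(length(cells))
  for (v in names(scheme$bins)) {
    vals <- stack$layers[[v]]$values[cells]
    acc <- acc + w[[v]] * lookup_resistance(vals, scheme$bins[[v]], v)
  }
  out <- matrix(NA_real_, nrow(ref$values), ncol(ref$values))
  out[cells] <- acc
  grid_layer(out, ref$cellsize, ref$origin, ref$crs_tag, "continuous")
}

#' Identify ecological source patches
#'
#' 8-connected components of the most-suitable class (code 3) with area
#' at least `min_area_km2`. These are the corridor endpoints: large,
#' aggregated cores of top-class habitat.
#'
#' @param classified categorical [grid_layer()] with codes 0-3.
#' @param min_area_km2 minimum patch area (default 10 km2).
#' @param cellsize cell edge in metres (taken from the layer if omitted).
#' @return a `source_patches` list: per patch `id`, `cells` (linear
#'   indices), `area_km2`, `centroid` (x, y). Empty (with a warning) if
#'   no patch qualifies.
#' @export
identify_sources <- function(classified, min_area_km2 = 10, cellsize = NULL) {
  if (is.null(cellsize)) cellsize <- classified$cellsize
  v <- classified$values
  m3 <- matrix(NA_integer_, nrow(v), ncol(v))
  m3[!is.na(v) & v == 3] <- 1L
  lab <- cpp_label_components(m3, TRUE)
  ids <- setdiff(unique(as.integer(lab)), 0L)
  cc <- cell_centers(classified)
  patches <- list()
  for (id in ids) {
    cells <- which(lab == id)
    area <- length(cells) * cellsize^2 / 1e6
    if (area < min_area_km2) next
    idx <- which(lab == id, arr.ind = TRUE)
    patches[[length(patches) + 1L]] <- list(
      id = length(patches) + 1L, cells = cells, area_km2 = area,
      centroid = c(x = mean(cc$x[idx[, 2]]), y = mean(cc$y[idx[, 1]])))
  }
  if (!length(patches))
    warning("no source patch reaches the minimum area")
  structure(patches, class = "source_patches")
}

#' Cost-distance field from a source patch
#'
#' Dijkstra shortest accumulated cost over the 8-connected lattice with
#' step cost `d(a,b) * (R_a + R_b) / 2` (`d` = cellsize, or sqrt(2) times
#' it diagonally) — the discrete form of accumulating distance times
#' resistance. Source cells cost 0.
#'
#' @param resistance continuous [grid_layer()], strictly positive on
#'   valid cells.
#' @param source_cells integer linear (column-major) indices of the
#'   source cells.
#' @param diagonal use 8-connectivity (default) or 4.
#' @return a `cost_distance_field`: `cost` [grid_layer()] (Inf where
#'   unreachable), `pred` predecessor-index matrix (backlinks, -1 none).
#' @export
cost_distance <- function(resistance, source_cells, diagonal = TRUE) {
  v <- resistance$values
  if (any(v[!is.na(v)] <= 0))
    stop("resistance must be strictly positive (degenerate metric)")
  if (!length(source_cells)) stop("empty source patch")
  res <- cpp_cost_distance(v, as.integer(source_cells) - 1L,
                           resistance$cellsize, diagonal)
  cost <- res$cost
  cost[is.na(v)] <- NA_real_
  structure(list(
    cost = grid_layer(cost, resistance$cellsize, resistance$origin,
                      resistance$crs_tag, "continuous"),
    pred = res$pred + 1L), class = "cost_distance_field")
}

#' Least-cost corridors between all source-patch pairs
#'
#' For each unordered pair, the corridor is the backlink trace from the
#' cheapest cell of patch b in patch a's cost field, snapped to cell
#' centres. Pairs severed by the mask are reported as disconnected, not
#' errors.
#'
#' @param resistance continuous resistance [grid_layer()].
#' @param sources a `source_patches` object (>= 2 patches).
#' @param diagonal 8-connectivity (default) or 4.
#' @return a `corridor_set`: list of corridors (`from`, `to`,
#'   `total_cost`, `path` data.frame of x/y, `connected`) plus the
#'   sources.
#' @export
least_cost_corridors <- function(resistance, sources, diagonal = TRUE) {
  if (length(sources) < 2) stop("need at least 2 source patches")
  nr <- nrow(resistance$values)
  cc <- cell_centers(resistance)
  corridors <- list()
  for (i in seq_len(length(sources) - 1)) {
    fld <- cost_distance(resistance, sources[[i]]$cells, diagonal)
    for (j in (i + 1):length(sources)) {
      bc <- sources[[j]]$cells
      costs <- fld$cost$values[bc]
      if (all(!is.finite(costs))) {
        corridors[[length(corridors) + 1L]] <- list(
          from = sources[[i]]$id, to = sources[[j]]$id,
          total_cost = Inf, path = NULL, connected = FALSE)
        next
      }
      end <- bc[which.min(costs)]
      path_cells <- trace_backlinks(fld$pred, end)
      rr <- ((path_cells - 1L) %% nr) + 1L
      ccol <- ((path_cells - 1L) %/% nr) + 1L
      corridors[[length(corridors) + 1L]] <- list(
        from = sources[[i]]$id, to = sources[[j]]$id,
        total_cost = min(costs, na.rm = TRUE),
        path = data.frame(x = cc$x[ccol], y = cc$y[rr],
                          cell = path_cells),
        connected = TRUE)
    }
  }
  structure(list(corridors = corridors, sources = sources),
            class = "corridor_set")
}

trace_backlinks <- function(pred, end) {
  path <- end
  cur <- end
  for (safety in seq_len(length(pred) + 1L)) {
    nxt <- pred[cur]
    if (nxt == 0L) break  # source cell (stored pred -1 + 1)
    path <- c(path, nxt)
    cur <- nxt
  }
  rev(path)
}

#' @export
print.corridor_set <- function(x, ...) {
  ok <- vapply(x$corridors, function(cr) cr$connected, TRUE)
  cat(sprintf("<corridor_set> %d source patches, %d corridors (%d connected)\n",
              length(x$sources), length(x$corridors), sum(ok)))
  invisible(x)
}
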