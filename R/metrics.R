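#' Landscape pattern metrics
#'
#' Computes six landscape-level indices on a categorical raster, following
#' the standard FRAGSTATS definitions:
#' \describe{
#'   \item{NP}{number of patches: 8-connected components over all classes.}
#'   \item{PD}{patch density, patches per 100 ha: `NP / A * 1e6` with `A`
#'     the landscape area in m2.}
#'   \item{LSI}{landscape shape index `0.25 * E / sqrt(A)` with `E` the
#'     total edge length including the landscape boundary (toggleable).}
#'   \item{CONTAG}{contagion, percent: `(1 + sum p_ik ln p_ik / (2 ln m))
#'     * 100` with `p_ik = P_i g_ik / sum_k g_ik`, `g` the double-count
#'     4-adjacency matrix; `0 ln 0 = 0`.}
#'   \item{DIVISION}{`1 - sum_patches (a / A)^2`.}
#'   \item{SHEI}{Shannon evenness `-sum P_i ln P_i / ln m`.}
#' }
#' CONTAG and SHEI are undefined for a single-class landscape (m = 1) and
#' reported as `NaN` with a warning. Natural logarithms throughout.
#'
#' @param classified categorical [grid_layer()].
#' @param cellsize cell edge in metres (taken from the layer if omitted).
#' @param boundary_edge count the landscape (and nodata) boundary as edge
#'   for LSI (the raster total-edge convention; default `TRUE`).
#' @return a `metrics_report`: one-row data.frame with NP, PD, LSI,
#'   CONTAG, DIVISION, SHEI, m (classes present) and A (landscape m2).
#' @export
landscape_metrics <- function(classified, cellsize = NULL,
                              boundary_edge = TRUE) {
  if (is.null(cellsize)) cellsize <- classified$cellsize
  v <- classified$values
  ok <- !is.na(v)
  n_valid <- sum(ok)
  if (!n_valid) stop("empty raster: no valid cells")
  A <- n_valid * cellsize^2
  classes <- sort(unique(v[ok]))
  m <- length(classes)
  P_i <- vapply(classes, function(k) sum(v[ok] == k), 0) / n_valid
  # patches (8-connectivity over all classes)
  vi <- matrix(NA_integer_, nrow(v), ncol(v))
  vi[ok] <- as.integer(v[ok])
  lab <- cpp_label_components(vi, TRUE)
  NP <- max(lab)
  patch_sizes <- tabulate(lab[lab > 0])
  PD <- NP / A * 1e4 * 1e2
  # edges (4-adjacency)
  adj <- adjacency_counts(vi)
  internal_diff <- adj$diff_edges          # unordered cross-class pairs
  boundary <- adj$boundary_edges           # valid cell faces on grid/nodata
  E <- (internal_diff + if (boundary_edge) boundary else 0) * cellsize
  LSI <- 0.25 * E / sqrt(A)
  DIVISION <- 1 - sum((patch_sizes / n_valid)^2)
  if (m == 1) {
    warning("single-class landscape: CONTAG and SHEI undefined (NaN)")
    CONTAG <- NaN
    SHEI <- NaN
  } else {
    g <- adj$g[as.character(classes), as.character(classes), drop = FALSE]
    gs <- rowSums(g)
    termsum <- 0
    for (i in seq_len(m)) {
      if (gs[i] == 0) next
      p <- P_i[i] * g[i, ] / gs[i]
      termsum <- termsum + sum(ifelse(p > 0, p * log(p), 0))
    }
    CONTAG <- (1 + termsum / (2 * log(m))) * 100
    SHEI <- -sum(ifelse(P_i > 0, P_i * log(P_i), 0)) / log(m)
  }
  out <- data.frame(NP = NP, PD = PD, LSI = LSI, CONTAG = CONTAG,
                    DIVISION = DIVISION, SHEI = SHEI, m = m, A = A)
  structure(out, class = c("metrics_report", "data.frame"))
}

# 4-adjacency bookkeeping: double-count class adjacency matrix g,
# single-count cross-class edges, and boundary faces of valid cells.
adjacency_counts <- function(vi) {
  nr <- nrow(vi); nc <- ncol(vi)
  classes <- sort(unique(vi[!is.na(vi)]))
  k <- length(classes)
  g <- matrix(0, k, k, dimnames = list(classes, classes))
  idx <- function(x) match(x, classes)
  diff_edges <- 0
  pair_tally <- function(a, b) {
    okp <- !is.na(a) & !is.na(b)
    if (!any(okp)) return(invisible(NULL))
    ta <- idx(a[okp]); tb <- idx(b[okp])
    tt <- table(factor(ta, levels = seq_len(k)),
                factor(tb, levels = seq_len(k)))
    g <<- g + unclass(tt) + t(unclass(tt))
    diff_edges <<- diff_edges + sum(ta != tb)
    invisible(NULL)
  }
  if (nc > 1) pair_tally(vi[, -nc], vi[, -1])
  if (nr > 1) pair_tally(vi[-nr, ], vi[-1, ])
  # boundary faces: valid cell faces meeting the grid edge or a nodata cell
  okm <- !is.na(vi)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- okm
  boundary <- sum(okm & !pad[1:nr, 2:(nc + 1)]) +         # north neighbour
    sum(okm & !pad[3:(nr + 2), 2:(nc + 1)]) +             # south
    sum(okm & !pad[2:(nr + 1), 1:nc]) +                   # west
    sum(okm & !pad[2:(nr + 1), 3:(nc + 2)])               # east
  list(g = g, diff_edges = diff_edges, boundary_edges = boundary)
}

#' Metrics for a set of scenario maps
#'
#' @param maps named list of categorical [grid_layer()]s (name = scenario
#'   tag).
#' @param cellsize cell edge in metres (per-layer default).
#' @return data.frame with one row per map.
#' @export
metrics_table <- function(maps, cellsize = NULL) {
  rows <- lapply(names(maps), function(nm) {
    r <- landscape_metrics(maps[[nm]], cellsize)
    cbind(scenario = nm, as.data.frame(r))
  })
  do.call(rbind, rows)
}
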