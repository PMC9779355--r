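#' Resample layers onto a common target geometry
#'
#' Each layer is resampled to the geometry of `target` by nearest-neighbour
#' or bilinear interpolation of cell-centre values. Categorical layers are
#' always resampled nearest-neighbour; asking for bilinear on a categorical
#' layer is an error. Target cells whose centre falls outside a source
#' layer's extent, or whose bilinear support includes a nodata cell, are
#' masked — no fill values are invented.
#'
#' @param layers named list of `grid_layer` objects.
#' @param target `grid_layer` defining the output geometry.
#' @param resampling `"nearest"` or `"bilinear"` (continuous layers only).
#' @return an [env_stack()] on the target geometry.
#' @export
align_stack <- function(layers, target, resampling = c("nearest", "bilinear")) {
  resampling <- match.arg(resampling)
  out <- lapply(seq_along(layers), function(i) {
    l <- layers[[i]]
    if (l$kind == "categorical" && resampling == "bilinear")
      stop(sprintf("layer '%s' is categorical: bilinear resampling is not allowed",
                   names(layers)[i]))
    if (same_geometry(l, target)) return(l)
    resample_layer(l, target,
                   if (l$kind == "categorical") "nearest" else resampling)
  })
  names(out) <- names(layers)
  st <- env_stack(out)
  if (!any(joint_valid_mask(st)))
    stop("aligned layers share no valid cells (disjoint extents?)")
  st
}

resample_layer <- function(l, target, method) {
  tc <- cell_centers(target)
  cs <- l$cellsize
  # fractional source index of each target centre (1-based cell coordinates)
  fx <- (tc$x - l$origin[1]) / cs + 0.5
  fy <- (l$origin[2] - tc$y) / cs + 0.5
  nr <- nrow(l$values); ncl <- ncol(l$values)
  out <- matrix(NA_real_, nrow(target$values), ncol(target$values))
  if (method == "nearest") {
    ci <- round(fx); ri <- round(fy)
    okc <- ci >= 1 & ci <= ncl; okr <- ri >= 1 & ri <= nr
    for (r in which(okr))
      out[r, okc] <- l$values[ri[r], ci[okc]]
  } else {
    c0 <- floor(fx); r0 <- floor(fy)
    wx <- fx - c0; wy <- fy - r0
    for (r in seq_len(nrow(out))) {
      r0r <- r0[r]
      if (r0r < 1 || r0r + 1 > nr) {
        # allow edge clamp when the centre sits in the outer half-cell
        next_ok <- FALSE
        if (fy[r] >= 0.5 && fy[r] <= nr + 0.5) next_ok <- TRUE
        if (!next_ok) next
      }
      ra <- max(1L, min(nr, r0r)); rb <- max(1L, min(nr, r0r + 1L))
      for (cidx in seq_len(ncol(out))) {
        c0c <- c0[cidx]
        if (fx[cidx] < 0.5 || fx[cidx] > ncl + 0.5) next
        ca <- max(1L, min(ncl, c0c)); cb <- max(1L, min(ncl, c0c + 1L))
        v <- c(l$values[ra, ca], l$values[ra, cb],
               l$values[rb, ca], l$values[rb, cb])
        if (any(is.na(v))) next
        w <- c((1 - wx[cidx]) * (1 - wy[r]), wx[cidx] * (1 - wy[r]),
               (1 - wx[cidx]) * wy[r], wx[cidx] * wy[r])
        out[r, cidx] <- sum(w * v)
      }
    }
  }
  grid_layer(out, cellsize = target$cellsize, origin = target$origin,
             crs_tag = target$crs_tag, kind = l$kind)
}

#' Slope and aspect from a DEM
#'
#' Horn's 3x3 finite-difference gradient. Slope is `atan(|grad z|)` in
#' degrees. Aspect is the compass bearing of the downslope direction,
#' clockwise from north in `[0, 360)`; a plane dipping to the east
#' (z increasing eastward) therefore has aspect 270. Flat cells get the
#' sentinel aspect `-1` (no direction is fabricated). Border cells and
#' cells with nodata in their 3x3 window are masked.
#'
#' @param dem continuous `grid_layer`, at least 3x3.
#' @return list with `slope` and `aspect` grid layers (degrees).
#' @export
slope_aspect <- function(dem) {
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 3 || nc < 3) stop("DEM must be at least 3x3")
  if (all(is.na(z))) stop("DEM is entirely masked")
  cs <- dem$cellsize
  # shifted windows: s[r][c] offsets, row +1 = south, col +1 = east
  sh <- function(dr, dc) z[(2 + dr):(nr - 1 + dr), (2 + dc):(nc - 1 + dc)]
  zNW <- sh(-1, -1); zN <- sh(-1, 0); zNE <- sh(-1, 1)
  zW  <- sh(0, -1);                   zE  <- sh(0, 1)
  zSW <- sh(1, -1);  zS <- sh(1, 0);  zSE <- sh(1, 1)
  gx <- ((zNE + 2 * zE + zSE) - (zNW + 2 * zW + zSW)) / (8 * cs)  # east
  gy <- ((zNW + 2 * zN + zNE) - (zSW + 2 * zS + zSE)) / (8 * cs)  # north
  slope_i <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  aspect_i <- (atan2(-gx, -gy) * 180 / pi) %% 360
  flat <- !is.na(slope_i) & slope_i < 1e-10
  aspect_i[flat] <- -1
  slope <- matrix(NA_real_, nr, nc); aspect <- matrix(NA_real_, nr, nc)
  slope[2:(nr - 1), 2:(nc - 1)] <- slope_i
  aspect[2:(nr - 1), 2:(nc - 1)] <- aspect_i
  list(slope = grid_layer(slope, cs, dem$origin, dem$crs_tag, "continuous"),
       aspect = grid_layer(aspect, cs, dem$origin, dem$crs_tag, "continuous"))
}

#' Euclidean distance to the nearest cell of given classes
#'
#' Centre-to-centre Euclidean distance (in metres) from every cell to the
#' nearest cell carrying one of `codes` in a categorical layer. Source
#' cells get distance 0. This is how the distance-to-water (DW),
#' distance-to-high-coverage-grassland (DH) and distance-to-road (DR)
#' predictors are built from a land-cover map.
#'
#' @param source categorical `grid_layer`.
#' @param codes integer class codes defining the source set.
#' @return continuous `grid_layer` of distances in metres; the source
#'   layer's nodata mask is propagated.
#' @export
distance_to_class <- function(source, codes) {
  if (source$kind != "categorical") stop("source layer must be categorical")
  src <- !is.na(source$values) & source$values %in% codes
  if (!any(src))
    stop(sprintf("no cells with class code(s) %s", paste(codes, collapse = ", ")))
  d <- cpp_edt(src) * source$cellsize
  d[is.na(source$values)] <- NA_real_
  grid_layer(d, source$cellsize, source$origin, source$crs_tag, "continuous")
}
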