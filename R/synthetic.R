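# Synthetic landscapes with known response structure. The generator
# emulates the inputs of an alpine habitat study at desk scale: smooth
# bioclimate-like surfaces, a DEM, a small land-cover codebook with
# water and grassland classes, derived distance layers, and presence
# points drawn from a known logistic suitability. All randomness flows
# from one spec seed through named substreams so results do not depend
# on call order.

# land-cover codebook used by the generator
#' Land-cover legend of the synthetic generator
#' @return named integer vector, label -> code.
#' @export
synthetic_lucc_legend <- function() {
  c("High coverage of grassland" = 1, "Low coverage of grassland" = 2,
    "Bareland" = 3, "Water area" = 4, "Construction land" = 5)
}

#' Specification of a synthetic landscape
#'
#' Defaults describe the stated world of the package's recovery tests:
#' an 80 x 80 km study window at 1 km resolution, four bioclimate-like
#' predictors with a 6-cell correlation length, a five-class land cover,
#' and 200 presence sites (the order of a thinned field campaign). The
#' true habitat is rare and sharply defined -- about 5% of the landscape,
#' driven by one dominant variable (a strong negative response to the
#' wet-quarter precipitation analogue) plus a weak secondary response --
#' emulating the concentrated alpine habitat and near-perfect
#' discrimination of the system this package targets.
#'
#' @param shape `(rows, cols)` grid size.
#' @param cellsize cell edge in metres.
#' @param n_continuous number of bioclimate-like predictors (1-8); named
#'   from `Bio16, Bio15, Bio3, Bio19, Bio1, Bio7, NPP, NDVI` in order.
#' @param smoothness correlation length in cells (moving-average radius).
#' @param lucc_classes number of land-cover classes (2-5, codes from
#'   [synthetic_lucc_legend()]).
#' @param true_response named coefficients of the true logistic
#'   suitability on standardized layers; `intercept` entry allowed.
#' @param n_presences number of presence points to draw.
#' @param seed master seed.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(shape = c(80, 80), cellsize = 1000,
                           n_continuous = 4, smoothness = 6,
                           lucc_classes = 5,
                           true_response = c(intercept = -9, Bio16 = -5,
                                             Bio3 = 1),
                           n_presences = 200, seed = 1L) {
  if (any(shape < 8)) stop("degenerate shape: need at least 8 x 8 cells")
  if (n_continuous < 1 || n_continuous > 8)
    stop("n_continuous must be in 1..8")
  if (lucc_classes < 2 || lucc_classes > 5)
    stop("lucc_classes must be in 2..5")
  structure(list(shape = as.integer(shape), cellsize = cellsize,
                 n_continuous = as.integer(n_continuous),
                 smoothness = as.integer(smoothness),
                 lucc_classes = as.integer(lucc_classes),
                 true_response = true_response,
                 n_presences = as.integer(n_presences),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# substream seeds: fixed offsets from the master seed, kept under 2^31
substream <- function(seed, name) {
  off <- c(landscape = 101L, lucc = 211L, dem = 307L, presences = 401L,
           splits = 503L)[[name]]
  (as.integer(seed) %% 20000000L) * 100L + off
}

# smoothed seeded noise field, rescaled to [lo, hi]
smooth_field <- function(nr, nc, radius, lo = 0, hi = 1) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (radius > 0) {
    s <- box_sum(z, radius)
    n <- box_sum(matrix(1, nr, nc), radius)
    z <- s / n
  }
  r <- range(z)
  if (r[2] > r[1]) z <- (z - r[1]) / (r[2] - r[1])
  lo + z * (hi - lo)
}

#' Generate a synthetic environmental stack
#'
#' Continuous layers are smoothed seeded noise rescaled to plausible
#' bioclimate ranges; the DEM is a smoother surface at plateau
#' elevations; LUCC is a categorical map cut from an independent smooth
#' field at fixed quantiles (grassland classes dominant, small water and
#' construction fractions); DW and DH are true distance rasters derived
#' from LUCC via [distance_to_class()].
#'
#' @param spec a [synthetic_spec()].
#' @return an [env_stack()] with the continuous layers, `DEM`, `LUCC`,
#'   `DW`, `DH`.
#' @export
make_landscape <- function(spec) {
  nr <- spec$shape[1]; nc <- spec$shape[2]
  ranges <- list(Bio16 = c(110, 408), Bio15 = c(80, 130), Bio3 = c(25, 45),
                 Bio19 = c(2, 36), Bio1 = c(-16, 8), Bio7 = c(30, 43),
                 NPP = c(0, 615), NDVI = c(0, 1))
  vars <- names(ranges)[seq_len(spec$n_continuous)]
  layers <- with_seed(substream(spec$seed, "landscape"), {
    ls <- lapply(vars, function(v)
      grid_layer(smooth_field(nr, nc, spec$smoothness,
                              ranges[[v]][1], ranges[[v]][2]),
                 spec$cellsize, kind = "continuous"))
    names(ls) <- vars
    ls
  })
  layers$DEM <- with_seed(substream(spec$seed, "dem"),
    grid_layer(smooth_field(nr, nc, max(spec$smoothness * 2, 4), 3500, 5500),
               spec$cellsize, kind = "continuous"))
  # land cover: grassland-dominated with small water/construction shares
  cuts <- switch(spec$lucc_classes - 1L,
                 c(0.5),                       # 2 classes
                 c(0.45, 0.8),                 # 3
                 c(0.4, 0.7, 0.93),            # 4
                 c(0.35, 0.65, 0.88, 0.96))    # 5
  lucc_field <- with_seed(substream(spec$seed, "lucc"),
                          smooth_field(nr, nc, spec$smoothness))
  q <- stats::quantile(lucc_field, cuts)
  codes <- matrix(findInterval(lucc_field, q) + 1, nr, nc)
  layers$LUCC <- grid_layer(codes, spec$cellsize, kind = "categorical")
  dd <- refresh_distance_layers(layers$LUCC,
                                water_codes = min(4, spec$lucc_classes),
                                grass_codes = 1)
  layers$DW <- dd$DW
  layers$DH <- dd$DH
  env_stack(layers)
}

#' True logistic suitability of a synthetic landscape
#'
#' `plogis(b0 + sum_v beta_v z_v)` over per-layer z-scores (computed on
#' the joint-valid cells).
#'
#' @param stack an [env_stack()].
#' @param true_response named coefficients (see [synthetic_spec()]).
#' @return continuous [grid_layer()] in (0,1).
#' @export
true_suitability <- function(stack, true_response) {
  b0 <- if ("intercept" %in% names(true_response))
    true_response[["intercept"]] else 0
  vars <- setdiff(names(true_response), "intercept")
  miss <- setdiff(vars, names(stack$layers))
  if (length(miss))
    stop(sprintf("true_response names missing from stack: %s",
                 paste(miss, collapse = ", ")))
  ref <- stack_ref(stack)
  ok <- joint_valid_mask(stack)
  eta <- matrix(NA_real_, nrow(ref$values), ncol(ref$values))
  eta[ok] <- b0
  for (v in vars) {
    z <- stack$layers[[v]]$values[ok]
    eta[ok] <- eta[ok] + true_response[[v]] * (z - mean(z)) / stats::sd(z)
  }
  out <- stats::plogis(eta)
  grid_layer(out, ref$cellsize, ref$origin, ref$crs_tag, "continuous")
}

#' Draw presence points from a suitability surface
#'
#' Presence cells are sampled without replacement with probability
#' proportional to suitability; returned points sit on cell centres.
#'
#' @param stack an [env_stack()] (for geometry and the valid mask).
#' @param suitability continuous [grid_layer()] (e.g. from
#'   [true_suitability()]).
#' @param n number of presences.
#' @param seed integer seed.
#' @return an [occurrence_set()].
#' @export
sample_presences <- function(stack, suitability, n, seed = 1L) {
  ref <- stack_ref(stack)
  ok <- joint_valid_mask(stack) & !is.na(suitability$values)
  cells <- which(ok)
  w <- suitability$values[cells]
  if (n == 0) return(occurrence_set(numeric(0), numeric(0), "synthetic"))
  if (sum(w) <= 0) stop("zero total suitability: nothing to sample from")
  pick <- with_seed(seed, sample(cells, n, prob = w,
                                 replace = n > length(cells)))
  nr <- nrow(ref$values)
  rr <- ((pick - 1L) %% nr) + 1L
  ccol <- ((pick - 1L) %/% nr) + 1L
  cc <- cell_centers(ref)
  occurrence_set(cc$x[ccol], cc$y[rr], "synthetic", crs_tag = ref$crs_tag)
}

#' One-call synthetic workspace
#'
#' Generates the stack, the true suitability and the presence sample of
#' a spec, with presence randomness drawn from the spec's `presences`
#' substream.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `stack`, `true_suit`, `presences`, `spec`.
#' @export
make_synthetic_workspace <- function(spec = synthetic_spec()) {
  stack <- make_landscape(spec)
  ts <- true_suitability(stack, spec$true_response)
  pres <- sample_presences(stack, ts, spec$n_presences,
                           seed = substream(spec$seed, "presences"))
  list(stack = stack, true_suit = ts, presences = pres, spec = spec)
}
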