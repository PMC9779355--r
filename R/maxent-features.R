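# Feature expansion for the maximum-entropy model.
#
# Continuous variables are rescaled to [0,1] by their background min/max
# (prediction-time values are clamped to that range before expansion, the
# stock guard against hinge extrapolation artifacts). Feature classes:
#   linear      u
#   quadratic   u^2
#   product     u_a * u_b                    (pairs of continuous variables)
#   hinge       forward  max(0, (u-k)/(1-k)) and
#               reverse  max(0, (k-u)/k)     at background-quantile knots
#   categorical one 0/1 indicator per code observed in the background

#' Maximum-entropy model configuration
#'
#' @param feature_classes subset of `c("linear","quadratic","product",
#'   "hinge","categorical")`. Products are only formed when at least two
#'   continuous variables are present; categorical indicators only for
#'   categorical layers.
#' @param n_background number of background cells to sample (all valid
#'   cells if fewer are available).
#' @param reg_multiplier multiplier on the default L1 penalties.
#' @param convergence_tol stop when one full coordinate-descent cycle
#'   improves the regularized gain by less than this (default 1e-5).
#' @param max_iterations maximum number of coordinate-descent cycles.
#' @param test_fraction fraction of presences held out per replicate.
#' @param n_replicates number of evaluation replicates.
#' @param n_hinge_knots number of background-quantile hinge knots per
#'   variable (forward and reverse hinges share the knot set).
#' @param seed integer seed governing background sampling and splits.
#' @return a `maxent_config` list.
#' @export
maxent_config <- function(feature_classes = c("linear", "quadratic", "product",
                                              "hinge", "categorical"),
                          n_background = 10000, reg_multiplier = 1.0,
                          convergence_tol = 1e-5, max_iterations = 500,
                          test_fraction = 0.25, n_replicates = 10,
                          n_hinge_knots = 30, seed = 1L) {
  feature_classes <- match.arg(feature_classes,
                               c("linear", "quadratic", "product", "hinge",
                                 "categorical"), several.ok = TRUE)
  stopifnot(n_background >= 1, reg_multiplier >= 0, convergence_tol > 0,
            max_iterations >= 1, test_fraction > 0, test_fraction < 1,
            n_replicates >= 1, n_hinge_knots >= 1)
  structure(list(feature_classes = feature_classes,
                 n_background = as.integer(n_background),
                 reg_multiplier = reg_multiplier,
                 convergence_tol = convergence_tol,
                 max_iterations = as.integer(max_iterations),
                 test_fraction = test_fraction,
                 n_replicates = as.integer(n_replicates),
                 n_hinge_knots = as.integer(n_hinge_knots),
                 seed = as.integer(seed)),
            class = "maxent_config")
}

# Build the feature dictionary from raw background values.
# bg_raw: N x V matrix (named columns); kinds: named "continuous"/"categorical"
make_feature_spec <- function(bg_raw, kinds, config) {
  vars <- colnames(bg_raw)
  cont <- vars[kinds[vars] == "continuous"]
  cat_ <- vars[kinds[vars] == "categorical"]
  scaling <- do.call(rbind, lapply(cont, function(v) {
    data.frame(var = v, min = min(bg_raw[, v]), max = max(bg_raw[, v]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(scaling))
    scaling <- data.frame(var = character(), min = numeric(), max = numeric())
  const <- scaling$var[scaling$max - scaling$min <= 0]
  cont <- setdiff(cont, const)
  feats <- list()
  add <- function(var, kind, var2 = NA_character_, knot = NA_real_,
                  code = NA_real_) {
    feats[[length(feats) + 1L]] <<- list(var = var, kind = kind, var2 = var2,
                                         knot = knot, code = code)
  }
  fc <- config$feature_classes
  for (v in cont) {
    if ("linear" %in% fc) add(v, "linear")
    if ("quadratic" %in% fc) add(v, "quadratic")
    if ("hinge" %in% fc) {
      u <- scale01(bg_raw[, v], scaling, v)
      probs <- seq(0, 1, length.out = config$n_hinge_knots + 2L)
      knots <- unique(stats::quantile(u, probs[-c(1, length(probs))],
                                      names = FALSE, type = 7))
      for (k in knots[knots < 1]) add(v, "hinge_fwd", knot = k)
      for (k in knots[knots > 0]) add(v, "hinge_rev", knot = k)
    }
  }
  if ("product" %in% fc && length(cont) >= 2) {
    for (i in seq_len(length(cont) - 1))
      for (j in (i + 1):length(cont))
        add(cont[i], "product", var2 = cont[j])
  }
  if ("categorical" %in% fc) {
    for (v in cat_) {
      for (cd in sort(unique(bg_raw[, v]))) add(v, "categorical", code = cd)
    }
  }
  list(features = feats, scaling = scaling, vars = vars, kinds = kinds[vars],
       const_vars = const)
}

scale01 <- function(v, scaling, var) {
  r <- scaling[scaling$var == var, ]
  if (r$max <= r$min) return(rep(0, length(v)))
  pmin(1, pmax(0, (v - r$min) / (r$max - r$min)))
}

# Expand raw values (n x V, named cols) into the feature matrix (n x J).
expand_features <- function(raw, spec) {
  n <- nrow(raw)
  J <- length(spec$features)
  out <- matrix(0, n, J)
  u_cache <- list()
  getu <- function(v) {
    if (is.null(u_cache[[v]])) u_cache[[v]] <<- scale01(raw[, v], spec$scaling, v)
    u_cache[[v]]
  }
  for (j in seq_len(J)) {
    f <- spec$features[[j]]
    out[, j] <- switch(f$kind,
      linear = getu(f$var),
      quadratic = getu(f$var)^2,
      product = getu(f$var) * getu(f$var2),
      hinge_fwd = pmax(0, (getu(f$var) - f$knot) / (1 - f$knot)),
      hinge_rev = pmax(0, (f$knot - getu(f$var)) / f$knot),
      categorical = as.numeric(raw[, f$var] == f$code),
      stop("unknown feature kind"))
  }
  out
}

feature_labels <- function(spec) {
  vapply(spec$features, function(f) {
    switch(f$kind,
           linear = f$var,
           quadratic = paste0(f$var, "^2"),
           product = paste0(f$var, "*", f$var2),
           hinge_fwd = sprintf("h+(%s,%.4g)", f$var, f$knot),
           hinge_rev = sprintf("h-(%s,%.4g)", f$var, f$knot),
           categorical = sprintf("%s==%g", f$var, f$code))
  }, "")
}

# Default per-feature-class L1 base penalties, interpolated in the number
# of presence samples (published defaults of the reference implementation).
base_beta <- function(kind, m) {
  interp <- function(ss, bb) {
    if (m <= ss[1]) return(bb[1])
    if (m >= ss[length(ss)]) return(bb[length(bb)])
    stats::approx(ss, bb, xout = m)$y
  }
  switch(kind,
    linear = interp(c(10, 30, 100), c(1.0, 0.2, 0.05)),
    quadratic = interp(c(0, 10, 17, 30, 100), c(1.3, 0.8, 0.5, 0.25, 0.05)),
    product = interp(c(0, 10, 17, 30, 100), c(2.6, 1.6, 0.9, 0.55, 0.05)),
    hinge_fwd = 0.5,
    hinge_rev = 0.5,
    categorical = interp(c(0, 10, 17, 33), c(0.65, 0.5, 0.25, 0.05)),
    stop("unknown feature kind"))
}

# Per-feature penalty: beta_class(m) * s_j / sqrt(m), s_j the presence-sample
# standard deviation of the feature (floored to avoid zero penalties).
feature_penalties <- function(spec, Fp, reg_multiplier) {
  m <- nrow(Fp)
  s <- apply(Fp, 2, stats::sd)
  if (m < 2) s[] <- 0
  s <- pmax(s, 0.05)
  kinds <- vapply(spec$features, function(f) f$kind, "")
  b <- vapply(kinds, base_beta, 0, m = m)
  reg_multiplier * b * s / sqrt(max(m, 1))
}
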