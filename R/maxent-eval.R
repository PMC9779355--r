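#' Predict suitability from a fitted maximum-entropy model
#'
#' `raw` output is the Gibbs probability of each cell relative to the
#' training background (raw values over the training background cells sum
#' to 1). `logistic` output is the standard calibration
#' `e^H q / (1 + e^H q)` with `q` the raw value and `H` the entropy of
#' the fitted background distribution, for which an uninformative
#' (background-uniform) model scores 0.5 everywhere. Out-of-range values
#' are clamped to the training range before feature evaluation.
#'
#' @param object a `maxent_model`.
#' @param stack an [env_stack()] containing every model variable.
#' @param type `"logistic"` (default) or `"raw"`.
#' @param ... unused.
#' @return a continuous [grid_layer()].
#' @export
predict.maxent_model <- function(object, stack, type = c("logistic", "raw"),
                                 ...) {
  type <- match.arg(type)
  miss <- setdiff(object$vars, names(stack$layers))
  if (length(miss))
    stop(sprintf("stack is missing model variable(s): %s",
                 paste(miss, collapse = ", ")))
  sub <- stack_subset(stack, object$vars)
  ok <- joint_valid_mask(sub)
  cells <- which(ok)
  raw_vals <- stack_matrix(sub, cells)
  eta <- model_eta(object, raw_vals)
  ref <- stack_ref(sub)
  out <- matrix(NA_real_, nrow(ref$values), ncol(ref$values))
  if (type == "raw") {
    out[cells] <- exp(eta - object$lse_bg)
  } else {
    out[cells] <- stats::plogis(object$H + eta - object$lse_bg)
  }
  grid_layer(out, ref$cellsize, ref$origin, ref$crs_tag, "continuous")
}

model_eta <- function(model, raw_vals) {
  spec <- list(features = model$features, scaling = model$scaling,
               vars = model$vars, kinds = model$kinds)
  Fm <- expand_features(raw_vals, spec)
  as.numeric(Fm %*% model$lambda)
}

# logistic score at given cells of a stack
score_cells <- function(model, stack, cells) {
  sub <- stack_subset(stack, model$vars)
  raw_vals <- stack_matrix(sub, cells)
  eta <- model_eta(model, raw_vals)
  stats::plogis(model$H + eta - model$lse_bg)
}

#' Rank-based AUC
#'
#' Probability that a random positive outranks a random negative
#' (ties count half), i.e. the Mann-Whitney statistic.
#'
#' @param pos,neg numeric score vectors.
#' @return AUC in `[0,1]`.
#' @export
auc_rank <- function(pos, neg) {
  np <- length(pos); nn <- length(neg)
  if (!np || !nn) stop("auc_rank needs non-empty score vectors")
  r <- rank(c(pos, neg))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Replicated train/test evaluation
#'
#' Repeats a seeded random presence split `config$n_replicates` times
#' (default 10), fits on the training share, and scores the held-out
#' presences against the model's background cells by rank AUC.
#'
#' @param presences an [occurrence_set()].
#' @param stack an [env_stack()].
#' @param config a [maxent_config()]; `test_fraction` (default 0.25) sets
#'   the held-out share.
#' @return list with `auc_mean`, `auc_sd` and a per-replicate data frame.
#' @export
evaluate_replicates <- function(presences, stack, config = maxent_config()) {
  n <- nrow(presences)
  n_test <- round(config$test_fraction * n)
  if (n_test < 1) stop("test split is empty; too few presences")
  if (n - n_test < 2) stop("training split too small")
  per <- lapply(seq_len(config$n_replicates), function(k) {
    seed_k <- config$seed + k
    test_idx <- with_seed(seed_k * 2L + 1L, sample.int(n, n_test))
    train <- occurrence_set(presences$x[-test_idx], presences$y[-test_idx],
                            presences$source[-test_idx],
                            crs_tag = attr(presences, "crs_tag"))
    cfg <- config
    cfg$seed <- seed_k
    model <- fit_maxent(train, stack, cfg)
    ref <- stack_ref(stack)
    rc <- points_to_cells(ref, presences$x[test_idx], presences$y[test_idx])
    test_cells <- rc[, "row"] + (rc[, "col"] - 1L) * nrow(ref$values)
    pos <- score_cells(model, stack, test_cells)
    neg <- score_cells(model, stack, model$bg_cells)
    data.frame(replicate = k, auc = auc_rank(pos, neg),
               gain = model$gain, converged = model$converged)
  })
  per <- do.call(rbind, per)
  list(auc_mean = mean(per$auc), auc_sd = stats::sd(per$auc), per_rep = per)
}

#' Percent contribution of each variable
#'
#' Training-path attribution: every accepted coordinate-ascent gain
#' increment is credited to the updated feature's source variable
#' (product features split evenly between their two variables); negative
#' tallies are clamped at zero and the result is normalized to sum to 100.
#'
#' @param model a `maxent_model`.
#' @return named numeric vector of percentages summing to 100.
#' @export
percent_contribution <- function(model) {
  tally <- stats::setNames(numeric(length(model$vars)), model$vars)
  gp <- model$gain_path
  if (nrow(gp)) {
    for (i in seq_len(nrow(gp))) {
      f <- model$features[[gp$feature[i]]]
      if (f$kind == "product") {
        tally[f$var] <- tally[f$var] + gp$delta_gain[i] / 2
        tally[f$var2] <- tally[f$var2] + gp$delta_gain[i] / 2
      } else {
        tally[f$var] <- tally[f$var] + gp$delta_gain[i]
      }
    }
  }
  tally <- pmax(tally, 0)
  if (sum(tally) <= 0) return(stats::setNames(rep(100 / length(tally),
                                                  length(tally)), model$vars))
  100 * tally / sum(tally)
}

#' Jackknife variable-importance test
#'
#' Refits the model once with only each variable and once without it,
#' reporting the training gain of each refit and the training AUC of the
#' single-variable model. With a one-variable stack the "without" model
#' is the featureless null model, whose gain is 0.
#'
#' @param presences an [occurrence_set()].
#' @param stack an [env_stack()].
#' @param config a [maxent_config()].
#' @return data.frame with columns `var`, `gain_with_only`,
#'   `gain_without`, `auc_with_only`, plus the full-model gain as the
#'   `full_gain` attribute.
#' @export
jackknife_importance <- function(presences, stack, config = maxent_config()) {
  vars <- names(stack$layers)
  full <- fit_maxent(presences, stack, config)
  rows <- lapply(vars, function(v) {
    only <- fit_maxent(presences, stack_subset(stack, v), config)
    pos <- score_cells(only, stack, only$presence_cells)
    neg <- score_cells(only, stack, only$bg_cells)
    gain_without <- if (length(vars) > 1) {
      fit_maxent(presences, stack_subset(stack, setdiff(vars, v)),
                 config)$gain
    } else 0
    data.frame(var = v, gain_with_only = only$gain,
               gain_without = gain_without,
               auc_with_only = auc_rank(pos, neg),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "full_gain") <- full$gain
  out
}

#' Marginal response curve of one variable
#'
#' Sweeps the variable across its background range (or its observed
#' category codes) with every other continuous variable held at its
#' background mean and every other categorical variable at its background
#' mode, returning the logistic suitability along the sweep.
#'
#' @param model a `maxent_model`.
#' @param variable variable name in the model.
#' @param n_points number of sweep points for continuous variables.
#' @return data.frame with columns `value` and `suitability`.
#' @export
response_curve <- function(model, variable, n_points = 100) {
  if (!(variable %in% model$vars))
    stop(sprintf("model has no variable '%s'", variable))
  bs <- model$bg_summary
  sweep_vals <- if (bs[[variable]]$kind == "categorical") {
    bs[[variable]]$levels
  } else {
    seq(bs[[variable]]$min, bs[[variable]]$max, length.out = n_points)
  }
  raw <- matrix(0, length(sweep_vals), length(model$vars),
                dimnames = list(NULL, model$vars))
  for (v in model$vars) {
    raw[, v] <- if (v == variable) sweep_vals
                else if (bs[[v]]$kind == "categorical") bs[[v]]$mode
                else bs[[v]]$mean
  }
  eta <- model_eta(model, raw)
  data.frame(value = sweep_vals,
             suitability = stats::plogis(model$H + eta - model$lse_bg))
}

#' Pearson collinearity screen
#'
#' Computes the Pearson correlation matrix of the continuous layers over
#' the joint-valid cells. Pairs with `|r| >= threshold` are resolved in
#' descending `|r|` order by dropping the member with the lower
#' contribution. Categorical layers are exempt and always survive.
#' Constant (zero-variance) layers are excluded with a warning.
#'
#' @param stack an [env_stack()].
#' @param contributions named per-variable percentages from a pre-model
#'   fit; all-equal if `NULL`.
#' @param threshold absolute correlation above which a pair conflicts
#'   (default 0.8).
#' @return list (`variable_report`) with `pearson`, `selected`,
#'   `dropped`, `constant`, `contributions`.
#' @export
pearson_screen <- function(stack, contributions = NULL, threshold = 0.8) {
  kinds <- vapply(stack$layers, function(l) l$kind, "")
  cont <- names(kinds)[kinds == "continuous"]
  if (length(cont) < 2) stop("need at least 2 continuous variables to screen")
  cells <- which(joint_valid_mask(stack))
  M <- stack_matrix(stack_subset(stack, cont), cells)
  sds <- apply(M, 2, stats::sd)
  const <- colnames(M)[sds == 0]
  if (length(const)) {
    warning(sprintf("constant layer(s) excluded from screening: %s",
                    paste(const, collapse = ", ")))
    cont <- setdiff(cont, const)
    M <- M[, cont, drop = FALSE]
  }
  if (is.null(contributions))
    contributions <- stats::setNames(rep(100 / length(names(kinds)),
                                         length(kinds)), names(kinds))
  r <- stats::cor(M)
  pairs <- which(upper.tri(r) & abs(r) >= threshold, arr.ind = TRUE)
  dropped <- character(0)
  if (nrow(pairs)) {
    ord <- order(-abs(r[pairs]))
    for (k in ord) {
      a <- colnames(r)[pairs[k, 1]]; b <- colnames(r)[pairs[k, 2]]
      if (a %in% dropped || b %in% dropped) next
      ca <- if (a %in% names(contributions)) contributions[[a]] else 0
      cb <- if (b %in% names(contributions)) contributions[[b]] else 0
      dropped <- c(dropped, if (ca < cb) a else b)
    }
  }
  selected <- c(setdiff(cont, dropped), names(kinds)[kinds == "categorical"])
  structure(list(pearson = r, selected = selected, dropped = dropped,
                 constant = const, contributions = contributions),
            class = "variable_report")
}

#' Serialize a fitted model to a JSON text file
#' @param model a `maxent_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_maxent <- function(model, path) {
  obj <- list(
    features = lapply(model$features, function(f)
      list(var = f$var, kind = f$kind, var2 = f$var2, knot = f$knot,
           code = f$code)),
    scaling = model$scaling, vars = model$vars,
    kinds = as.list(model$kinds), lambda = model$lambda,
    lse_bg = model$lse_bg, N = model$N, Z = model$Z, H = model$H,
    gain = model$gain, converged = model$converged,
    bg_summary = model$bg_summary)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Load a serialized model
#' @param path path written by [write_maxent()].
#' @return a `maxent_model` (sufficient for prediction and response curves).
#' @export
read_maxent <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  feats <- lapply(seq_len(nrow(obj$features)), function(i) {
    f <- obj$features[i, ]
    list(var = f$var, kind = f$kind,
         var2 = if (is.na(f$var2)) NA_character_ else f$var2,
         knot = f$knot, code = f$code)
  })
  bs <- lapply(obj$bg_summary, function(b) b)
  structure(list(features = feats, scaling = obj$scaling, vars = obj$vars,
                 kinds = unlist(obj$kinds), lambda = obj$lambda,
                 lse_bg = obj$lse_bg, N = obj$N, Z = obj$Z, H = obj$H,
                 gain = obj$gain, gain_path = data.frame(),
                 converged = obj$converged, bg_summary = bs),
            class = "maxent_model")
}
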