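# Core fitting routine: maximize the regularized gain
#   G(lambda) = mean_presence eta - ln Z(lambda) - sum_j beta_j |lambda_j|
# with eta = lambda . f(x) and Z = (1/N) sum_background exp(eta), by cyclic
# coordinate ascent. Each coordinate step solves the 1-D problem exactly:
# the expected feature value under the tilted background distribution,
#   E_j(d) = sum_i w_i e^{d f_ij} f_ij / sum_i w_i e^{d f_ij},
# is increasing in d, so the stationarity condition p_j - E_j(d) = s*beta_j
# is found by a safeguarded Newton/bisection root solve on each sign branch
# of the L1 term; the candidate with the largest exact gain wins.

fit_core <- function(Fp, Fb, beta, tol, maxit) {
  N <- nrow(Fb); J <- ncol(Fb)
  pmean <- colMeans(Fp)
  lambda <- numeric(J)
  eta_b <- numeric(N)
  gain <- 0
  gain_path <- list()
  converged <- FALSE
  lam_cap <- 30
  for (cycle in seq_len(maxit)) {
    m0 <- max(eta_b)
    a <- exp(eta_b - m0)
    sa <- sum(a)
    Ew <- as.numeric(crossprod(Fb, a)) / sa
    potential <- abs(pmean - Ew) - beta
    active <- which(potential > tol * 1e-3 | lambda != 0)
    if (!length(active)) { converged <- TRUE; break }
    gain0 <- gain
    for (j in active) {
      t <- Fb[, j]
      m0 <- max(eta_b)
      a <- exp(eta_b - m0)
      res <- coord_step(lambda[j], pmean[j], t, a, beta[j], lam_cap)
      if (res$dgain > 1e-12) {
        lambda[j] <- lambda[j] + res$d
        eta_b <- eta_b + res$d * t
        gain <- gain + res$dgain
        gain_path[[length(gain_path) + 1L]] <-
          c(cycle = cycle, feature = j, delta_gain = res$dgain)
      }
    }
    # exact recompute to stop numeric drift in the incremental gain
    gain <- exact_gain(lambda, pmean, Fp, eta_b, beta)
    if (gain - gain0 < tol) { converged <- TRUE; break }
  }
  m0 <- max(eta_b)
  a <- exp(eta_b - m0)
  lse <- m0 + log(sum(a))            # log sum_bg exp(eta)
  q <- a / sum(a)                    # raw distribution over background
  H <- -sum(ifelse(q > 0, q * log(q), 0))
  gp <- if (length(gain_path)) {
    as.data.frame(do.call(rbind, gain_path))
  } else data.frame(cycle = numeric(), feature = numeric(),
                    delta_gain = numeric())
  list(lambda = lambda, eta_b = eta_b, lse_bg = lse, H = H, gain = gain,
       gain_path = gp, converged = converged, n_background = N)
}

exact_gain <- function(lambda, pmean, Fp, eta_b, beta) {
  m0 <- max(eta_b)
  sum(pmean * lambda) - (m0 + log(mean(exp(eta_b - m0)))) -
    sum(beta * abs(lambda))
}

# One exact 1-D coordinate step (see header comment).
coord_step <- function(lam, p, t, a, beta, lam_cap) {
  sa <- sum(a)
  stat <- function(d) {
    ed <- exp(d * t)
    s <- sum(a * ed)
    E <- sum(a * ed * t) / s
    V <- sum(a * ed * t^2) / s - E^2
    list(s = s, E = E, V = V)
  }
  dgain <- function(d) {
    ed <- exp(d * t)
    s <- sum(a * ed)
    d * p - log(s / sa) - beta * (abs(lam + d) - abs(lam))
  }
  dlo <- -lam_cap - lam
  dhi <- lam_cap - lam
  # monotone root solve of E(d) = target on [lo, hi]
  solve_E <- function(target, lo, hi) {
    slo <- stat(lo); shi <- stat(hi)
    if (target <= slo$E) return(lo)
    if (target >= shi$E) return(hi)
    d <- 0
    if (d < lo || d > hi) d <- (lo + hi) / 2
    for (it in 1:60) {
      st <- stat(d)
      err <- st$E - target
      if (abs(err) < 1e-11) break
      if (err > 0) hi <- d else lo <- d
      d_new <- if (st$V > 1e-14) d - err / st$V else NA_real_
      d <- if (!is.na(d_new) && d_new > lo && d_new < hi) d_new
           else (lo + hi) / 2
      if (hi - lo < 1e-12) break
    }
    d
  }
  cands <- numeric(0)
  if (beta > 0) {
    lo_p <- max(dlo, -lam)            # branch lam + d >= 0
    if (lo_p < dhi) cands <- c(cands, solve_E(p - beta, lo_p, dhi))
    hi_m <- min(dhi, -lam)            # branch lam + d <= 0
    if (dlo < hi_m) cands <- c(cands, solve_E(p + beta, dlo, hi_m))
    cands <- c(cands, -lam)           # shrink to exactly zero
  } else {
    cands <- solve_E(p, dlo, dhi)
  }
  gains <- vapply(cands, dgain, 0)
  k <- which.max(gains)
  list(d = cands[k], dgain = gains[k])
}

#' Fit a maximum-entropy species distribution model
#'
#' Presence-background Gibbs model: the fitted distribution over
#' background cells maximizes entropy subject to an L1-penalized match
#' between background feature expectations and presence feature means.
#' Fitting is cyclic coordinate ascent on the regularized gain; the run
#' stops when a full cycle improves the gain by less than
#' `config$convergence_tol` (default 1e-5) or after
#' `config$max_iterations` cycles.
#'
#' @param presences an [occurrence_set()]; every point must fall on a
#'   valid (jointly unmasked) cell of `stack`.
#' @param stack an [env_stack()] of predictors.
#' @param config a [maxent_config()].
#' @return a `maxent_model` with elements `features`, `lambda`, `scaling`,
#'   `Z`, `H`, `gain`, `gain_path`, `converged`, plus the background
#'   summaries needed for response curves and prediction.
#' @export
fit_maxent <- function(presences, stack, config = maxent_config()) {
  if (nrow(presences) < 2) stop("need at least 2 presence points")
  ref <- stack_ref(stack)
  ok <- joint_valid_mask(stack)
  rc <- points_to_cells(ref, presences$x, presences$y)
  cell <- rc[, "row"] + (rc[, "col"] - 1L) * nrow(ref$values)
  bad <- which(is.na(cell) | !ok[cbind(rc[, "row"], rc[, "col"])])
  if (length(bad))
    stop(sprintf("presence point(s) outside the valid mask: rows %s",
                 paste(utils::head(bad, 10), collapse = ", ")))
  valid <- which(ok)
  n_bg <- min(config$n_background, length(valid))
  bg <- with_seed(config$seed, sample(valid, n_bg))
  bg <- union(bg, cell)  # presence cells are part of the background
  bg_raw <- stack_matrix(stack, bg)
  p_raw <- stack_matrix(stack, cell)
  kinds <- vapply(stack$layers, function(l) l$kind, "")
  spec <- make_feature_spec(bg_raw, kinds, config)
  if (!length(spec$features))
    stop("no usable features: all variables are constant over the background")
  Fb <- expand_features(bg_raw, spec)
  Fp <- expand_features(p_raw, spec)
  if (all(apply(Fb, 2, function(v) max(v) - min(v)) <= 0))
    stop("no variance in any feature over the background")
  beta <- feature_penalties(spec, Fp, config$reg_multiplier)
  core <- fit_core(Fp, Fb, beta, config$convergence_tol,
                   config$max_iterations)
  # background per-variable summaries for response curves
  bg_summary <- lapply(colnames(bg_raw), function(v) {
    if (kinds[v] == "categorical") {
      tab <- table(bg_raw[, v])
      list(kind = "categorical",
           mode = as.numeric(names(tab)[which.max(tab)]),
           levels = as.numeric(names(tab)))
    } else {
      list(kind = "continuous", mean = mean(bg_raw[, v]),
           min = min(bg_raw[, v]), max = max(bg_raw[, v]))
    }
  })
  names(bg_summary) <- colnames(bg_raw)
  structure(list(
    features = spec$features, scaling = spec$scaling, vars = spec$vars,
    kinds = spec$kinds, lambda = core$lambda, beta = beta,
    lse_bg = core$lse_bg, N = length(bg),
    Z = exp(core$lse_bg) / length(bg), H = core$H, gain = core$gain,
    gain_path = core$gain_path, converged = core$converged,
    bg_summary = bg_summary, bg_cells = bg, presence_cells = cell,
    config = config), class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf("<maxent_model> %d features over %d variables; gain %.4f (%s)\n",
              length(x$features), length(x$vars), x$gain,
              if (x$converged) "converged" else "max iterations"))
  cat(sprintf("  N background %d, entropy H %.4f, %d non-zero coefficients\n",
              x$N, x$H, sum(x$lambda != 0)))
  invisible(x)
}
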