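#' Estimate a land-class transition matrix from two calibration maps
#'
#' Cross-tabulates the jointly valid cells of two aligned categorical
#' maps and row-normalizes the counts into per-step transition
#' probabilities. Classes with no cells at t1 get an identity row (no
#' evidence, no invented transitions).
#'
#' @param map_t1,map_t2 aligned categorical [grid_layer()]s sharing one
#'   class codebook.
#' @param step_years calendar years between the two maps (one Markov step).
#' @return a `transition_matrix`: list with `classes`, `P`, `step_years`.
#' @export
estimate_transition <- function(map_t1, map_t2, step_years) {
  if (!same_geometry(map_t1, map_t2)) stop("maps are not aligned")
  ok <- !is.na(map_t1$values) & !is.na(map_t2$values)
  v1 <- map_t1$values[ok]; v2 <- map_t2$values[ok]
  classes <- sort(union(unique(v1), unique(v2)))
  k <- length(classes)
  counts <- matrix(0, k, k, dimnames = list(classes, classes))
  tab <- table(factor(v1, levels = classes), factor(v2, levels = classes))
  counts[] <- as.numeric(tab)
  P <- counts
  for (i in seq_len(k)) {
    s <- sum(counts[i, ])
    if (s > 0) P[i, ] <- counts[i, ] / s
    else { P[i, ] <- 0; P[i, i] <- 1 }
  }
  transition_matrix(classes, P, step_years)
}

#' Construct a transition matrix
#' @param classes ordered land-class codes.
#' @param P row-stochastic k x k matrix, `P[i, j]` = probability class i
#'   becomes class j in one step.
#' @param step_years years per step.
#' @return a `transition_matrix`.
#' @export
transition_matrix <- function(classes, P, step_years = NA_real_) {
  P <- as.matrix(P)
  if (nrow(P) != length(classes) || ncol(P) != length(classes))
    stop("P must be square with one row per class")
  if (any(P < -1e-12) || any(P > 1 + 1e-12))
    stop("transition probabilities must lie in [0,1]")
  if (any(abs(rowSums(P) - 1) > 1e-9))
    stop("transition matrix rows must sum to 1")
  dimnames(P) <- list(classes, classes)
  structure(list(classes = classes, P = P, step_years = step_years),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix> %d classes, %s years per step\n",
              length(x$classes),
              if (is.na(x$step_years)) "?" else format(x$step_years)))
  print(round(x$P, 4))
  invisible(x)
}

#' Project class areas forward (Markov chain)
#'
#' `S(t+n) = S(t) P^n`: the land-use state vector advanced `n_steps`
#' whole steps. Total area is conserved.
#'
#' @param areas named numeric vector of per-class areas (km2 or cell
#'   counts), names matching the matrix classes.
#' @param tm a [transition_matrix()].
#' @param n_steps number of whole steps.
#' @return named numeric vector of projected areas.
#' @export
markov_project <- function(areas, tm, n_steps = 1) {
  if (length(areas) != length(tm$classes))
    stop("areas dimension does not match the transition matrix")
  if (!is.null(names(areas)) &&
      !identical(as.character(tm$classes), names(areas)))
    areas <- areas[as.character(tm$classes)]
  v <- matrix(as.numeric(areas), nrow = 1)
  for (i in seq_len(n_steps)) v <- v %*% tm$P
  stats::setNames(as.numeric(v), tm$classes)
}

#' Scenario adjustment of a transition matrix
#'
#' The "modified Markov" mechanism: every off-diagonal entry is scaled by
#' `multiplier` and the diagonal re-absorbs the difference, keeping rows
#' stochastic. `multiplier = 1` is a no-op; `0` freezes the landscape;
#' values > 1 accelerate change (an error if any diagonal would go
#' negative).
#'
#' @param tm a [transition_matrix()].
#' @param multiplier non-negative scale on off-diagonal transition rates.
#' @return adjusted [transition_matrix()].
#' @export
scenario_adjust <- function(tm, multiplier) {
  if (multiplier < 0) stop("multiplier must be >= 0")
  P <- tm$P * multiplier
  diag(P) <- 1 - (rowSums(P) - diag(P))
  if (any(diag(P) < -1e-12))
    stop("multiplier too large: a diagonal entry would become negative")
  diag(P) <- pmax(diag(P), 0)
  transition_matrix(tm$classes, P, tm$step_years)
}

#' Cellular-automata allocation of projected class areas
#'
#' Turns target per-class cell counts into a map: each cell's affinity
#' for a class is the fraction of same-class cells in its k x k
#' neighbourhood, optionally blended (weight 0.5) with a per-class
#' suitability layer. Classes over target shed their lowest-affinity
#' cells; classes under target claim the highest-affinity released cells.
#' Final counts match the targets exactly; ties are broken by a seeded
#' shuffle, so the result is deterministic given `seed`.
#'
#' @param current categorical [grid_layer()].
#' @param targets named per-class target cell counts; must total the
#'   number of valid cells.
#' @param suitability optional named list of continuous [grid_layer()]s
#'   (one per class) blended into the affinity score.
#' @param iterations number of reallocation sweeps (default 10).
#' @param kernel odd neighbourhood size (default 5).
#' @param seed integer seed for tie-breaking.
#' @return categorical [grid_layer()] meeting the targets exactly.
#' @export
ca_allocate <- function(current, targets, suitability = NULL,
                        iterations = 10, kernel = 5, seed = 1L) {
  if (kernel %% 2 != 1) stop("kernel size must be odd")
  v <- current$values
  ok <- !is.na(v)
  n_valid <- sum(ok)
  classes <- as.numeric(names(targets))
  if (any(is.na(classes))) stop("targets must be named by class code")
  targets <- round(as.numeric(targets))
  if (any(targets < 0) || sum(targets) != n_valid)
    stop(sprintf("infeasible targets: they must be >= 0 and total %d cells",
                 n_valid))
  names(targets) <- classes
  jitter <- with_seed(seed, stats::runif(length(v), 0, 1e-9))
  for (it in seq_len(iterations)) {
    counts <- vapply(classes, function(k) sum(v[ok] == k), 0)
    names(counts) <- classes
    if (all(counts == targets) && it > 1) break
    # per-class neighbourhood fraction
    aff <- lapply(classes, function(k) {
      frac <- box_fraction(v == k & ok, ok, kernel)
      if (!is.null(suitability) && as.character(k) %in% names(suitability))
        frac <- 0.5 * frac + 0.5 * suitability[[as.character(k)]]$values
      frac + matrix(jitter, nrow(v), ncol(v))
    })
    names(aff) <- classes
    release <- integer(0)
    for (k in as.character(classes)) {
      excess <- sum(v[ok] == as.numeric(k)) - targets[[k]]
      if (excess > 0) {
        cells <- which(ok & v == as.numeric(k))
        scores <- aff[[k]][cells]
        release <- c(release, cells[order(scores)][seq_len(excess)])
      }
    }
    if (!length(release)) break
    deficit <- targets - counts
    deficit[deficit < 0] <- 0
    # each released cell goes to its best-affinity deficit class
    cand <- do.call(cbind, lapply(as.character(classes),
                                  function(k) aff[[k]][release]))
    colnames(cand) <- classes
    cand[, deficit[colnames(cand)] == 0] <- -Inf
    ord <- order(-apply(cand, 1, max))
    for (i in ord) {
      kbest <- colnames(cand)[which.max(cand[i, ])]
      if (deficit[[kbest]] <= 0) {
        open <- names(deficit)[deficit > 0]
        kbest <- open[which.max(cand[i, open])]
      }
      v[release[i]] <- as.numeric(kbest)
      deficit[[kbest]] <- deficit[[kbest]] - 1
    }
  }
  grid_layer(v, current$cellsize, current$origin, current$crs_tag,
             "categorical")
}

# fraction of TRUE cells of `ind` among valid cells in a k x k window
box_fraction <- function(ind, ok, k) {
  h <- (k - 1) / 2
  num <- box_sum(ifelse(ind, 1, 0), h)
  den <- box_sum(ifelse(ok, 1, 0), h)
  out <- num / pmax(den, 1)
  out[!ok] <- NA_real_
  out
}

# moving-window sum by padded 2-D cumulative sums
box_sum <- function(m, h) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0, nr + 2 * h + 1, nc + 2 * h + 1)
  p[(h + 2):(h + 1 + nr), (h + 2):(h + 1 + nc)] <- m
  p <- apply(apply(p, 2, cumsum), 1, cumsum)  # transposed cumulative table
  p <- t(p)
  i1 <- (2 * h + 2):(2 * h + 1 + nr); i0 <- 1:nr
  j1 <- (2 * h + 2):(2 * h + 1 + nc); j0 <- 1:nc
  p[i1, j1] - p[i0, j1] - p[i1, j0] + p[i0, j0]
}

#' Rebuild distance predictors from a projected land-cover map
#'
#' @param projected_lucc categorical [grid_layer()].
#' @param water_codes,grass_codes class codes of water and high-coverage
#'   grassland.
#' @return list with `DW` and `DH` distance layers (metres).
#' @export
refresh_distance_layers <- function(projected_lucc, water_codes,
                                    grass_codes) {
  list(DW = distance_to_class(projected_lucc, water_codes),
       DH = distance_to_class(projected_lucc, grass_codes))
}

#' Write / read a transition matrix as CSV
#' @param tm a [transition_matrix()].
#' @param path CSV path (row label = from-class).
#' @return `path` (write) or a `transition_matrix` (read).
#' @export
write_transition <- function(tm, path) {
  d <- as.data.frame(tm$P)
  d <- cbind(from = tm$classes, d)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_transition
#' @param step_years years per step to attach on read.
#' @export
read_transition <- function(path, step_years = NA_real_) {
  d <- utils::read.csv(path, check.names = FALSE)
  classes <- d$from
  P <- as.matrix(d[, -1, drop = FALSE])
  transition_matrix(classes, P, step_years)
}
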