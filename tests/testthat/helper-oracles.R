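# Independent brute-force oracles. These deliberately share no code with
# the package internals they check.

# all-pairs nearest-source scan (centre-to-centre)
bf_distance_to_class <- function(vals, codes, cellsize) {
  nr <- nrow(vals); nc <- ncol(vals)
  src <- which(!is.na(vals) & vals %in% codes, arr.ind = TRUE)
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (is.na(vals[r, cc])) next
    out[r, cc] <- min(sqrt((src[, 1] - r)^2 + (src[, 2] - cc)^2)) * cellsize
  }
  out
}

# O(V^2) Dijkstra with average-resistance step costs
bf_cost_distance <- function(res, src_cells, cellsize, diagonal = TRUE) {
  nr <- nrow(res); nc <- ncol(res)
  n <- nr * nc
  dist <- rep(Inf, n)
  dist[src_cells] <- 0
  done <- rep(FALSE, n)
  done[is.na(res)] <- TRUE
  nbrs <- if (diagonal) {
    cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1), dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else cbind(dr = c(-1, 0, 0, 1), dc = c(0, -1, 1, 0))
  repeat {
    u <- which(!done & is.finite(dist))
    if (!length(u)) break
    u <- u[which.min(dist[u])]
    done[u] <- TRUE
    ur <- (u - 1) %% nr + 1; uc <- (u - 1) %/% nr + 1
    for (k in seq_len(nrow(nbrs))) {
      vr <- ur + nbrs[k, 1]; vc <- uc + nbrs[k, 2]
      if (vr < 1 || vr > nr || vc < 1 || vc > nc) next
      v <- vr + (vc - 1) * nr
      if (is.na(res[v])) next
      d <- sqrt(sum(nbrs[k, ]^2)) * cellsize
      alt <- dist[u] + d * (res[u] + res[v]) / 2
      if (alt < dist[v]) dist[v] <- alt
    }
  }
  matrix(dist, nr, nc)
}

# flood-fill patch count (components of equal value)
bf_count_patches <- function(vals, diagonal = TRUE) {
  nr <- nrow(vals); nc <- ncol(vals)
  seen <- matrix(FALSE, nr, nc)
  nbrs <- if (diagonal) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else cbind(c(-1, 0, 0, 1), c(0, -1, 1, 0))
  np <- 0
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (seen[r, cc] || is.na(vals[r, cc])) next
    np <- np + 1
    queue <- list(c(r, cc))
    seen[r, cc] <- TRUE
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nbrs))) {
        rr <- cur[1] + nbrs[k, 1]; c2 <- cur[2] + nbrs[k, 2]
        if (rr < 1 || rr > nr || c2 < 1 || c2 > nc) next
        if (seen[rr, c2] || is.na(vals[rr, c2])) next
        if (vals[rr, c2] != vals[cur[1], cur[2]]) next
        seen[rr, c2] <- TRUE
        queue[[length(queue) + 1]] <- c(rr, c2)
      }
    }
  }
  np
}

# 1-D unregularized maxent oracle: golden-section maximization of
# d * pmean - log(mean(exp(d * t))) over the background feature t
bf_maxent_1d <- function(pmean, t_bg) {
  obj <- function(d) d * pmean - log(mean(exp(d * t_bg)))
  stats::optimize(obj, c(-60, 60), maximum = TRUE, tol = 1e-10)$maximum
}
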