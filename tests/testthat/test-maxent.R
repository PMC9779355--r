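# stack with a single continuous variable, used for the small exact cases
one_var_stack <- function(vals, cellsize = 1000) {
  env_stack(list(V = tiny_layer(vals, cellsize)))
}

presences_at_cells <- function(stack, cells) {
  ref <- ecocorridor:::stack_ref(stack)
  nr <- nrow(ref$values)
  rr <- (cells - 1) %% nr + 1
  cc <- (cells - 1) %/% nr + 1
  centers <- cell_centers(ref)
  occurrence_set(centers$x[cc], centers$y[rr])
}

test_that("unregularized linear fit matches the 1-D convex oracle", {
  set.seed(5)
  vals <- matrix(runif(400), 20, 20)
  st <- one_var_stack(vals)
  # presences biased toward high values of V
  cells <- order(vals, decreasing = TRUE)[c(1, 3, 8, 15, 30, 50, 80, 120)]
  occ <- presences_at_cells(st, cells)
  cfg <- maxent_config(feature_classes = "linear", reg_multiplier = 0,
                       n_background = 400, convergence_tol = 1e-9,
                       max_iterations = 2000, seed = 1)
  m <- fit_maxent(occ, st, cfg)
  # oracle: golden-section maximization over the same scaled feature
  bg_u <- (vals[m$bg_cells] - m$scaling$min) / (m$scaling$max - m$scaling$min)
  p_u <- (vals[m$presence_cells] - m$scaling$min) /
    (m$scaling$max - m$scaling$min)
  lam_star <- bf_maxent_1d(mean(p_u), bg_u)
  expect_equal(m$lambda[1], lam_star, tolerance = 1e-4)
  # moment matching: E_q[f] equals the presence mean of f
  w <- exp(m$lambda[1] * bg_u)
  expect_equal(sum(w * bg_u) / sum(w), mean(p_u), tolerance = 1e-4)
})

test_that("no-signal presences give a near-null regularized model", {
  set.seed(8)
  vals <- matrix(runif(400), 20, 20)
  st <- one_var_stack(vals)
  cells <- sample(400, 60)  # uniform: no relation to V
  occ <- presences_at_cells(st, cells)
  cfg <- maxent_config(feature_classes = "linear", n_background = 400,
                       seed = 2)
  m <- fit_maxent(occ, st, cfg)
  expect_lt(max(abs(m$lambda)), 0.5)
  raw <- predict(m, st, type = "raw")
  expect_equal(max(raw$values) / min(raw$values), 1, tolerance = 0.7)
})

test_that("prediction transforms behave as constructed", {
  ws <- small_workspace()
  cfg <- fast_config(seed = 3)
  m <- fit_maxent(ws$presences, ws$stack, cfg)
  raw <- predict(m, ws$stack, type = "raw")
  # raw sums to 1 over the training background
  expect_equal(sum(raw$values[m$bg_cells]), 1, tolerance = 1e-9)
  lg <- predict(m, ws$stack, type = "logistic")
  v <- lg$values[!is.na(lg$values)]
  expect_true(all(v > 0 & v < 1))
  expect_error(predict(m, stack_subset(ws$stack, "DEM")), "missing model")

  # a null model scores exactly 0.5 everywhere
  null_m <- m
  null_m$lambda[] <- 0
  null_m$lse_bg <- log(null_m$N)
  null_m$H <- log(null_m$N)
  lg0 <- predict(null_m, ws$stack, type = "logistic")
  expect_equal(unique(lg0$values[!is.na(lg0$values)]), 0.5)
})

test_that("monotone single-variable model yields a monotone response", {
  set.seed(9)
  vals <- matrix(runif(400), 20, 20)
  st <- one_var_stack(vals)
  cells <- order(vals, decreasing = TRUE)[seq(1, 120, by = 3)]
  occ <- presences_at_cells(st, cells)
  cfg <- maxent_config(feature_classes = "linear", n_background = 400,
                       seed = 1)
  m <- fit_maxent(occ, st, cfg)
  rc <- response_curve(m, "V", n_points = 50)
  expect_true(all(diff(rc$suitability) > 0))
  expect_error(response_curve(m, "nope"), "no variable")
})

test_that("AUC is the rank statistic", {
  expect_equal(auc_rank(c(0.9, 0.6), c(0.7, 0.5)), 0.75)  # 3 of 4 pairs
  expect_equal(auc_rank(c(0.9, 0.8), c(0.2, 0.1)), 1.0)
  set.seed(1)
  a <- runif(500); b <- runif(800)
  expect_equal(auc_rank(a, b), 0.5, tolerance = 0.05)
  expect_equal(auc_rank(c(1, 1), c(1, 1)), 0.5)  # ties count half
})

test_that("replicate evaluation reports mean and sd over seeded splits", {
  ws <- small_workspace()
  cfg <- fast_config(seed = 4, n_replicates = 3)
  ev <- evaluate_replicates(ws$presences, ws$stack, cfg)
  expect_equal(nrow(ev$per_rep), 3)
  expect_true(ev$auc_mean > 0.5 && ev$auc_mean < 1)
  expect_gte(ev$auc_sd, 0)
  # deterministic given the config seed
  ev2 <- evaluate_replicates(ws$presences, ws$stack, cfg)
  expect_equal(ev$per_rep$auc, ev2$per_rep$auc)
  tiny <- occurrence_set(c(0, 1), c(0, 1))
  expect_error(evaluate_replicates(tiny, ws$stack,
                                   maxent_config(test_fraction = 0.1)),
               "empty|small")
})

test_that("percent contribution: single variable gets 100, sums to 100", {
  set.seed(10)
  vals <- matrix(runif(400), 20, 20)
  st <- one_var_stack(vals)
  occ <- presences_at_cells(st, order(vals)[1:40])
  m <- fit_maxent(occ, st, maxent_config(n_background = 400, seed = 1,
                                         n_hinge_knots = 5))
  pc <- percent_contribution(m)
  expect_equal(unname(pc["V"]), 100)
  ws <- small_workspace()
  m2 <- fit_maxent(ws$presences, ws$stack, fast_config(seed = 5))
  expect_equal(sum(percent_contribution(m2)), 100, tolerance = 0.1)
})

test_that("the dominant synthetic variable tops the contribution ranking", {
  ws <- small_workspace()
  m <- fit_maxent(ws$presences, ws$stack, fast_config(seed = 6))
  pc <- percent_contribution(m)
  expect_equal(names(which.max(pc)), "Bio16")
  expect_gt(pc[["Bio16"]], 50)
})

test_that("gain is non-decreasing along the training path", {
  ws <- small_workspace()
  m <- fit_maxent(ws$presences, ws$stack, fast_config(seed = 7))
  expect_true(all(m$gain_path$delta_gain > 0))
  expect_gt(m$gain, 0)
  expect_true(m$converged)
})

test_that("background order does not change the fit", {
  set.seed(12)
  vals <- matrix(runif(225), 15, 15)
  st <- one_var_stack(vals)
  occ <- presences_at_cells(st, order(vals)[1:25])
  cfg <- maxent_config(n_background = 225, n_hinge_knots = 5, seed = 1)
  m1 <- fit_maxent(occ, st, cfg)
  cfg2 <- cfg; cfg2$seed <- 999L  # different background shuffle, same cells
  m2 <- fit_maxent(occ, st, cfg2)
  expect_equal(sort(m1$bg_cells), sort(m2$bg_cells))
  expect_equal(m1$gain, m2$gain, tolerance = 1e-6)
  expect_equal(m1$lambda, m2$lambda, tolerance = 1e-4)
})

test_that("jackknife: with-only / without gains behave as constructed", {
  ws <- small_workspace()
  st <- stack_subset(ws$stack, c("Bio16", "Bio15"))
  cfg <- fast_config(seed = 8)
  jk <- jackknife_importance(ws$presences, st, cfg)
  expect_setequal(jk$var, c("Bio16", "Bio15"))
  # informative variable beats the uninformative one alone
  expect_gt(jk$gain_with_only[jk$var == "Bio16"],
            jk$gain_with_only[jk$var == "Bio15"])
  # dropping the noise variable barely hurts the model
  expect_equal(jk$gain_without[jk$var == "Bio15"], attr(jk, "full_gain"),
               tolerance = 0.15)
  # one-variable stack: the without-model is the null model, gain 0
  jk1 <- jackknife_importance(ws$presences, stack_subset(ws$stack, "Bio16"),
                              cfg)
  expect_equal(jk1$gain_without, 0)
})

test_that("presences off the valid mask are an error", {
  ws <- small_workspace()
  bad <- occurrence_set(c(-1e6, 1000), c(-1e6, 1000))
  expect_error(fit_maxent(bad, ws$stack, fast_config()), "outside the valid")
})

test_that("pearson_screen drops the lower-contribution member of a pair", {
  set.seed(20)
  n <- 40
  a <- matrix(rnorm(n * n), n, n)
  noise <- matrix(rnorm(n * n), n, n)
  st <- env_stack(list(A = tiny_layer(a), A2 = tiny_layer(a),
                       N = tiny_layer(noise)))
  rep <- pearson_screen(st, contributions = c(A = 60, A2 = 30, N = 10))
  expect_setequal(rep$selected, c("A", "N"))   # duplicate resolved by contribution
  expect_equal(rep$dropped, "A2")
  expect_true(all(abs(rep$pearson) <= 1 + 1e-12))

  # two independent white-noise layers both survive at threshold 0.8
  st2 <- env_stack(list(X = tiny_layer(matrix(rnorm(1e4), 100)),
                        Y = tiny_layer(matrix(rnorm(1e4), 100))))
  expect_setequal(pearson_screen(st2)$selected, c("X", "Y"))
})

test_that("pearson_screen resolves correlation chains by descending |r|", {
  # A~B strong (0.9), B~C strong (0.85), A~C weak (0.6): a feasible
  # correlation chain, drawn exactly via the Cholesky factor
  set.seed(21)
  n <- 2500
  R <- rbind(c(1, 0.9, 0.6), c(0.9, 1, 0.85), c(0.6, 0.85, 1))
  Z <- matrix(rnorm(n * 3), n, 3)
  X <- Z %*% chol(R)
  a <- X[, 1]; b <- X[, 2]; cc <- X[, 3]
  st <- env_stack(list(A = tiny_layer(matrix(a, 50)),
                       B = tiny_layer(matrix(b, 50)),
                       C = tiny_layer(matrix(cc, 50))))
  r <- stats::cor(cbind(a, b, cc))
  expect_lt(abs(r["a", "cc"]), 0.8)
  expect_gt(abs(r["a", "b"]), 0.8)
  expect_gt(abs(r["b", "cc"]), 0.8)
  rep <- pearson_screen(st, contributions = c(A = 50, B = 30, C = 20),
                        threshold = 0.8)
  # oracle: exhaustive rule evaluation on the 3 pairs
  expect_setequal(rep$selected, c("A", "C"))
  expect_equal(rep$dropped, "B")

  # constant layer is excluded with a warning
  st3 <- env_stack(list(A = tiny_layer(matrix(rnorm(100), 10)),
                        K = tiny_layer(matrix(1, 10, 10)),
                        B = tiny_layer(matrix(rnorm(100), 10))))
  expect_warning(rep3 <- pearson_screen(st3), "constant")
  expect_false("K" %in% rep3$selected)
})

test_that("model serialization round-trips predictions", {
  ws <- small_workspace()
  m <- fit_maxent(ws$presences, ws$stack, fast_config(seed = 9))
  p <- withr::local_tempfile(fileext = ".json")
  write_maxent(m, p)
  m2 <- read_maxent(p)
  s1 <- predict(m, ws$stack)
  s2 <- predict(m2, ws$stack)
  expect_equal(s1$values, s2$values, tolerance = 1e-12)
})
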