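test_that("quintile binning of a monotone response orders intervals 50..10", {
  set.seed(30)
  vals <- matrix(runif(400), 20, 20)
  st <- env_stack(list(V = tiny_layer(vals, 1000)))
  cells <- order(vals, decreasing = TRUE)[seq(1, 100, 2)]
  ref <- ecocorridor:::stack_ref(st)
  cc <- cell_centers(ref)
  rr <- (cells - 1) %% 20 + 1; cl <- (cells - 1) %/% 20 + 1
  occ <- occurrence_set(cc$x[cl], cc$y[rr])
  m <- fit_maxent(occ, st, maxent_config(feature_classes = "linear",
                                         n_background = 400, seed = 1))
  sch <- scheme_from_response(m)
  b <- sch$bins$V
  # increasing response: resistance decreases left to right, 50 first
  expect_equal(b$resistance, c(50, 40, 30, 20, 10))
  expect_true(all(diff(b$lower) > 0))
  # bins cover the background range edge to edge
  expect_equal(b$lower[1], m$bg_summary$V$min)
  expect_equal(b$upper[5], m$bg_summary$V$max)
})

test_that("a flat (null) response falls back to a level-30 scheme", {
  ws <- small_workspace()
  m <- fit_maxent(ws$presences, stack_subset(ws$stack, c("Bio16", "Bio15")),
                  fast_config(seed = 2))
  m$lambda[] <- 0  # force the null model
  w <- capture_warnings(sch <- scheme_from_response(m))
  expect_length(w, 2)  # one flat-response warning per factor
  expect_true(all(grepl("flat", w)))
  expect_equal(sch$bins$Bio16$resistance, 30)
  expect_equal(nrow(sch$bins$Bio16), 1)
})

test_that("the packaged resistance table loads verbatim", {
  p <- system.file("extdata", "table2_resistance.csv",
                   package = "ecocorridor")
  sch <- read_resistance_scheme(p)
  lucc <- sch$bins$LUCC
  expect_equal(lucc$resistance[lucc$label == "High coverage of grassland"], 10)
  expect_equal(lucc$resistance[lucc$label == "Construction land"], 50)
  expect_equal(lucc$resistance[lucc$label == "Water area"], 40)
  expect_equal(sch$weights[["LUCC"]], 32.4)
  expect_equal(sch$weights[["Bio16"]], 5.6)
  # the historical "Bo7" row label is accepted as Bio7
  expect_true("Bio7" %in% names(sch$bins))
  expect_equal(sch$bins$DW$upper, c(5000, 10000, 15000, 20000, 50000))
  # legend attaches codes to the categorical bins
  legend <- c("High coverage of grassland" = 31,
              "Low coverage of grassland" = 33, "Cropland" = 1,
              "forest" = 2, "middle coverage of grassland" = 32,
              "bareland" = 6, "Water area" = 4, "Construction land" = 5)
  sch2 <- apply_category_legend(sch, legend)
  expect_equal(sch2$bins$LUCC$code[sch2$bins$LUCC$label ==
                                     "Construction land"], 5)
  expect_error(apply_category_legend(sch, legend[-3]), "Cropland")
})

test_that("resistance_surface weights, normalizes, and checks coverage", {
  v1 <- matrix(5, 3, 3)   # all in the 30-bin
  st <- env_stack(list(A = tiny_layer(v1, 100)))
  sch <- resistance_scheme(list(A = data.frame(resistance = 30, lower = 0,
                                               upper = 10)),
                           c(A = 1))
  surf <- resistance_surface(st, sch)
  expect_true(all(surf$values == 30))

  # two factors 0.6/0.4 with bins 10/50 -> 26
  st2 <- env_stack(list(A = tiny_layer(matrix(1, 2, 2), 100),
                        B = tiny_layer(matrix(1, 2, 2), 100)))
  sch2 <- resistance_scheme(
    list(A = data.frame(resistance = 10, lower = 0, upper = 2),
         B = data.frame(resistance = 50, lower = 0, upper = 2)),
    c(A = 0.6, B = 0.4))
  expect_true(all(resistance_surface(st2, sch2)$values == 26))

  # homogeneity: scaling all weights leaves the surface unchanged
  sch3 <- resistance_scheme(sch2$bins, c(A = 60.12, B = 40.08))
  expect_equal(resistance_surface(st2, sch3)$values,
               resistance_surface(st2, sch2)$values, tolerance = 1e-9)

  # a value covered by no interval is an error naming factor and value
  sch4 <- resistance_scheme(list(A = data.frame(resistance = 10, lower = 0,
                                                upper = 0.5)), c(A = 1))
  expect_error(resistance_surface(st, sch4), "'A'.*5")
})

test_that("identify_sources finds 8-connected top-class patches", {
  v <- matrix(0, 12, 12)
  v[2:4, 2:4] <- 3            # 9 cells
  v[9:11, 9:11] <- 3          # 9 cells
  v[6, 6] <- 3                # isolated single cell
  cl <- tiny_layer(v, cellsize = 1000, kind = "categorical")
  s <- identify_sources(cl, min_area_km2 = 5)
  expect_length(s, 2)
  expect_equal(sort(vapply(s, function(p) p$area_km2, 0)), c(9, 9))
  # diagonal-touching cells form one patch under 8-connectivity
  vd <- matrix(0, 5, 5); vd[1, 1] <- 3; vd[2, 2] <- 3; vd[3, 3] <- 3
  sd <- identify_sources(tiny_layer(vd, 1000, kind = "categorical"),
                         min_area_km2 = 2)
  expect_length(sd, 1)
  expect_warning(identify_sources(cl, min_area_km2 = 1e6), "minimum area")
})

test_that("cost_distance: unit cases and the brute-force Dijkstra oracle", {
  r <- tiny_layer(matrix(10, 5, 5), cellsize = 1)
  f <- cost_distance(r, source_cells = 13)  # centre cell (3,3)
  expect_equal(f$cost$values[3, 3], 0)
  expect_equal(f$cost$values[3, 4], 10)              # orthogonal
  expect_equal(f$cost$values[4, 4], 10 * sqrt(2))    # diagonal
  expect_error(cost_distance(tiny_layer(matrix(c(1, -1, 1, 1), 2, 2)), 1),
               "positive")

  set.seed(31)
  for (i in 1:20) {
    nr <- sample(4:12, 1); nc <- sample(4:12, 1)
    res <- matrix(stats::runif(nr * nc, 1, 50), nr, nc)
    res[stats::runif(nr * nc) < 0.1] <- NA
    src <- sample(which(!is.na(res)), sample(1:2, 1))
    cs <- sample(c(1, 30), 1)
    got <- cost_distance(tiny_layer(res, cs), src)$cost$values
    want <- bf_cost_distance(res, src, cs)
    want[is.na(res)] <- NA
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("cost distances are symmetric, metric, and monotone in resistance", {
  set.seed(32)
  res <- matrix(stats::runif(100, 1, 30), 10, 10)
  lay <- tiny_layer(res, 25)
  cells <- sample(100, 3)
  f <- lapply(cells, function(s) cost_distance(lay, s)$cost$values)
  # symmetry
  expect_equal(f[[1]][cells[2]], f[[2]][cells[1]], tolerance = 1e-9)
  # triangle inequality over the triple
  expect_lte(f[[1]][cells[3]],
             f[[1]][cells[2]] + f[[2]][cells[3]] + 1e-9)
  # raising a cell's resistance never decreases any accumulated cost
  res2 <- res; res2[5, 5] <- res2[5, 5] * 10
  f2 <- cost_distance(tiny_layer(res2, 25), cells[1])$cost$values
  expect_true(all(f2 - f[[1]] >= -1e-9))
})

test_that("corridors: straight line on uniform resistance, valley capture", {
  # two single-cell sources on one row, uniform resistance
  v <- matrix(0, 9, 15)
  v[5, 1] <- 3; v[5, 15] <- 3
  cl <- tiny_layer(v, cellsize = 100, kind = "categorical")
  srcs <- identify_sources(cl, min_area_km2 = 0.005)
  res <- tiny_layer(matrix(8, 9, 15), cellsize = 100)
  cs <- least_cost_corridors(res, srcs)
  cr <- cs$corridors[[1]]
  expect_true(cr$connected)
  expect_equal(cr$total_cost, 8 * 1400)        # R x distance
  expect_true(all(cr$path$y == cell_centers(res)$y[5]))  # straight row

  # low-resistance channel through a high-resistance field
  res2 <- matrix(50, 9, 15)
  res2[2, ] <- 1                               # the valley, row 2
  res2[5, 1] <- 1; res2[5, 15] <- 1
  # connect sources to the valley cheaply on the end columns
  res2[2:5, 1] <- 1; res2[2:5, 15] <- 1
  lay2 <- tiny_layer(res2, cellsize = 100)
  cs2 <- least_cost_corridors(lay2, srcs)
  path <- cs2$corridors[[1]]$path
  rows <- (path$cell - 1) %% 9 + 1
  expect_gte(mean(rows %in% c(2, 3, 4, 5)), 0.8)
  expect_gte(sum(rows == 2), 10)               # follows the channel
  # oracle agreement on the channel grid
  want <- bf_cost_distance(res2, which(v == 3)[1], 100)
  expect_equal(cs2$corridors[[1]]$total_cost, want[5, 15], tolerance = 1e-9)

  # severed pair is reported disconnected, not an error
  res3 <- matrix(8, 9, 15); res3[, 8] <- NA
  cs3 <- least_cost_corridors(tiny_layer(res3, 100), srcs)
  expect_false(cs3$corridors[[1]]$connected)
  expect_error(least_cost_corridors(res, srcs[1]), "at least 2")
})

test_that("corridor endpoints lie in their patches and cost is symmetric", {
  set.seed(33)
  res <- matrix(stats::runif(400, 5, 40), 20, 20)
  v <- matrix(0, 20, 20); v[2:4, 2:4] <- 3; v[16:18, 16:18] <- 3
  srcs <- identify_sources(tiny_layer(v, 1000, kind = "categorical"), 5)
  lay <- tiny_layer(res, 1000)
  cs <- least_cost_corridors(lay, srcs)
  cr <- cs$corridors[[1]]
  expect_true(cr$path$cell[1] %in% srcs[[1]]$cells)
  expect_true(cr$path$cell[nrow(cr$path)] %in% srcs[[2]]$cells)
  # symmetry of patch-to-patch cost
  f_b <- cost_distance(lay, srcs[[2]]$cells)
  expect_equal(min(f_b$cost$values[srcs[[1]]$cells]), cr$total_cost,
               tolerance = 1e-9)
})
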