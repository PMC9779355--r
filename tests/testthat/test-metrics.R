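test_that("degenerate single-class landscape", {
  cl <- tiny_layer(matrix(1, 8, 8), cellsize = 100, kind = "categorical")
  expect_warning(r <- landscape_metrics(cl), "single-class")
  expect_equal(r$NP, 1)
  expect_equal(r$LSI, 1)          # square patch filling the landscape
  expect_equal(r$DIVISION, 0)
  expect_true(is.nan(r$SHEI))
  expect_true(is.nan(r$CONTAG))
  expect_equal(r$A, 64 * 100^2)
  expect_error(landscape_metrics(tiny_layer(matrix(NA_real_, 3, 3),
                                            kind = "categorical")),
               "empty")
})

test_that("2x2 checkerboard: CONTAG = 50 by hand computation", {
  cb <- tiny_layer(matrix(c(1, 2, 2, 1), 2, 2), cellsize = 30,
                   kind = "categorical")
  r <- landscape_metrics(cb)
  expect_equal(r$CONTAG, 50)
  expect_equal(r$NP, 2)  # the two diagonals join under 8-connectivity
  expect_equal(r$SHEI, 1)
})

test_that("two equal classes in two compact patches: SHEI 1, DIVISION 0.5", {
  v <- matrix(1, 10, 10); v[, 6:10] <- 2
  r <- landscape_metrics(tiny_layer(v, 100, kind = "categorical"))
  expect_equal(r$SHEI, 1)
  expect_equal(r$DIVISION, 0.5)
  expect_equal(r$NP, 2)
  expect_equal(r$PD, 2 / (100 * 100^2) * 1e6)
})

test_that("NP equals the flood-fill oracle on random rasters", {
  set.seed(40)
  for (i in 1:40) {
    nr <- sample(3:15, 1); nc <- sample(3:15, 1)
    v <- matrix(sample(1:3, nr * nc, TRUE), nr, nc)
    v[stats::runif(nr * nc) < 0.15] <- NA
    if (all(is.na(v))) v[1, 1] <- 1
    got <- suppressWarnings(
      landscape_metrics(tiny_layer(v, 50, kind = "categorical"))$NP)
    expect_equal(got, bf_count_patches(v))
  }
})

test_that("aggregation and splitting move CONTAG and DIVISION as expected", {
  # aggregation monotonicity needs m >= 3: with two equal classes both
  # perfect blocks and a perfect checkerboard sit at the 50% fixed point
  # of the contagion formula (hand computation), so the comparison is run
  # on three classes: compact bands vs maximal interspersion
  n <- 9
  bands <- matrix(rep(1:3, each = n * 3), n, n)
  inter <- matrix((row(diag(n)) + col(diag(n))) %% 3 + 1, n, n)
  r_bands <- landscape_metrics(tiny_layer(bands, 100, kind = "categorical"))
  r_inter <- landscape_metrics(tiny_layer(inter, 100, kind = "categorical"))
  expect_gt(r_bands$CONTAG, r_inter$CONTAG)
  # two-class fixed point: blocks never exceed the checkerboard's 50
  blocks <- matrix(1, 8, 8); blocks[, 5:8] <- 2
  checker <- matrix((row(diag(8)) + col(diag(8))) %% 2 + 1, 8, 8)
  r_blocks <- landscape_metrics(tiny_layer(blocks, 100, kind = "categorical"))
  r_check <- landscape_metrics(tiny_layer(checker, 100, kind = "categorical"))
  expect_equal(r_check$CONTAG, 50)
  expect_lt(r_blocks$CONTAG, 50)

  # splitting a patch raises DIVISION
  whole <- matrix(2, 9, 9); whole[5, ] <- 1
  r_split <- landscape_metrics(tiny_layer(whole, 100, kind = "categorical"))
  solid <- matrix(2, 9, 9); solid[1, ] <- 1
  r_solid <- landscape_metrics(tiny_layer(solid, 100, kind = "categorical"))
  expect_gt(r_split$DIVISION, r_solid$DIVISION)

  # SHEI is maximal at equal proportions
  uneq <- matrix(1, 10, 10); uneq[1:2, 1:5] <- 2
  r_uneq <- landscape_metrics(tiny_layer(uneq, 100, kind = "categorical"))
  eq <- matrix(1, 10, 10); eq[1:5, ] <- 2
  r_eq <- landscape_metrics(tiny_layer(eq, 100, kind = "categorical"))
  expect_lt(r_uneq$SHEI, r_eq$SHEI)
  expect_equal(r_eq$SHEI, 1)
})

test_that("shrinking, fragmenting habitat drives NP up then down, CONTAG up", {
  # constructed sequence: habitat (class 1) in a matrix (class 2)
  nr <- 30
  mk <- function(frac_keep, n_frag, seed) {
    set.seed(seed)
    v <- matrix(2, nr, nr)
    # n_frag blocks whose total area shrinks with frac_keep
    side <- max(1, round(sqrt(frac_keep * nr * nr / n_frag)))
    for (b in seq_len(n_frag)) {
      r0 <- sample(1:(nr - side), 1); c0 <- sample(1:(nr - side), 1)
      v[r0:(r0 + side - 1), c0:(c0 + side - 1)] <- 1
    }
    tiny_layer(v, 100, kind = "categorical")
  }
  maps <- list(mk(0.5, 2, 1),    # large, intact habitat
               mk(0.25, 8, 2),   # fragmenting
               mk(0.04, 3, 3))   # nearly gone
  tab <- metrics_table(list(a = maps[[1]], b = maps[[2]], c = maps[[3]]))
  np_habitat <- vapply(maps, function(m)
    bf_count_patches(ifelse(m$values == 1, 1, NA)), 0)
  expect_gt(np_habitat[2], np_habitat[1])  # fragmentation raises NP
  expect_gt(np_habitat[2], np_habitat[3])  # then loss removes patches
  expect_gt(tab$CONTAG[3], tab$CONTAG[2])  # matrix homogenizes
})

test_that("LSI grows with boundary complexity and honours the toggle", {
  solid <- matrix(1, 10, 10); solid[3:8, 3:8] <- 2
  stripes <- matrix(1, 10, 10); stripes[, seq(1, 10, 2)] <- 2
  r1 <- landscape_metrics(tiny_layer(solid, 100, kind = "categorical"))
  r2 <- landscape_metrics(tiny_layer(stripes, 100, kind = "categorical"))
  expect_gt(r2$LSI, r1$LSI)
  # without boundary edge, a full single-class square has LSI 0
  cl <- tiny_layer(matrix(1, 6, 6), 100, kind = "categorical")
  r3 <- suppressWarnings(landscape_metrics(cl, boundary_edge = FALSE))
  expect_equal(r3$LSI, 0)
})
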