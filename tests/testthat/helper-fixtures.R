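# Shared in-code fixtures. Expensive objects are built lazily and cached
# for the whole test run.

tiny_layer <- function(vals, cellsize = 1, kind = "continuous",
                       origin = NULL) {
  if (is.null(origin)) origin <- c(0, nrow(as.matrix(vals)) * cellsize)
  grid_layer(as.matrix(vals), cellsize = cellsize, origin = origin,
             kind = kind)
}

# small two-variable stack with a known gradient structure
ramp_stack <- function(n = 25, cellsize = 1000) {
  a <- matrix(rep(seq(0, 1, length.out = n), each = n), n, n)     # x ramp
  b <- matrix(rep(seq(0, 1, length.out = n), times = n), n, n)    # y ramp
  env_stack(list(A = tiny_layer(a, cellsize), B = tiny_layer(b, cellsize)))
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (!exists(key, .fixture_cache)) assign(key, build(), .fixture_cache)
  get(key, .fixture_cache)
}

# the default stated-world workspace (seed 1), shared across test files
default_workspace <- function() {
  cached("ws_default", function() make_synthetic_workspace(synthetic_spec()))
}

# a small, fast workspace for unit-level model tests
small_workspace <- function() {
  cached("ws_small", function() {
    make_synthetic_workspace(synthetic_spec(shape = c(40, 40),
                                            n_presences = 120, seed = 11))
  })
}

# fast maxent config for unit tests (fewer knots, fewer replicates)
fast_config <- function(...) {
  args <- list(n_hinge_knots = 8, n_replicates = 3)
  user <- list(...)
  args[names(user)] <- user
  do.call(maxent_config, args)
}
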