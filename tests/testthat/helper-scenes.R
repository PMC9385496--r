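# Shared fixtures, built once per test run.

# Small default-condition scene used by several suites.
small_scene <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- build_scene(scene_config(grid_shape = c(12L, 12L),
                                         seed = 101L))
    cache
  }
})

# Uniform-parameter scene: every region shares one AR(1) block, so pixel
# statistics are exchangeable.
uniform_scene_config <- function(phi0 = 0.2, phi_trend = 0,
                                 missing_fraction = 0.1,
                                 grid_shape = c(12L, 12L), seed = 1L,
                                 ...) {
  blk <- list(phi0 = phi0, phi_trend = phi_trend, phi_jitter_sd = 0,
              missing_fraction = missing_fraction)
  scene_config(grid_shape = grid_shape, seed = seed,
               region_params = list(boreal = blk, temperate = blk,
                                    arid = blk, tropical = blk),
               ...)
}

# The 14-column predictor frame with random entries, for model fixtures.
random_predictors <- function(n, seed = 1L) {
  set.seed(seed)
  X <- as.data.frame(matrix(stats::runif(n * 14L), n, 14L))
  names(X) <- unlist(predictor_groups(), use.names = FALSE)
  X
}
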