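# Small synthetic worlds used across the tests. Sizes are kept far below the
# study defaults so single tests stay fast; the full-scale conditions are
# exercised by the end-to-end recovery test.

tiny_world_spec <- function(seed = 1, ...) {
  args <- utils::modifyList(list(seed = seed, n_train_ph = 400L,
                                 n_train_ta = 300L), list(...))
  do.call(world_spec, args)
}

# all randomness off, flat annual cycle, no trend: labels reduce to the
# deterministic spatial field
silent_world_spec <- function(seed = 1, ...) {
  tiny_world_spec(
    seed = seed,
    ph_seasonal_amplitude = 0, ph_trend_per_year = 0,
    noise_sd = c(temperature = 0, salinity = 0, phosphate = 0, nitrate = 0,
                 silicate = 0, ph = 0, ta = 0),
    ...
  )
}

zero_noise_sd <- function() {
  c(temperature = 0, salinity = 0, phosphate = 0, nitrate = 0,
    silicate = 0, ph = 0, ta = 0)
}

# fabricate a constant-output linear member (prediction stub)
constant_member <- function(value, n_features) {
  dims <- riacarb:::layer_dims(n_features, integer(0))
  structure(list(layer_sizes = integer(0), dims = dims,
                 weights = rep(0, n_features + 1),
                 x_center = rep(0, n_features), x_scale = rep(1, n_features),
                 y_center = value, y_scale = 1,
                 alpha = 1, beta = 1, gamma = 0,
                 n_weights = n_features + 1, n_train = 0, seed = 0,
                 n_iter = 0, converged = TRUE),
            class = "brnn_member")
}
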