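# Shared trained fixtures, memoized so the expensive GAN training runs once
# per test session.

.fixture_env <- new.env(parent = emptyenv())

toy_sample_32 <- function() {
  if (is.null(.fixture_env$sample32))
    .fixture_env$sample32 <- make_toy_sample(
      toy_lesion_spec(size = c(32L, 32L), axes = c(8, 6), contrast = 0.8,
                      seed = 11L))
  .fixture_env$sample32
}

# small trained bundle: 32x32 fixture, 4 scales (32/25/20/16), 40 epochs per
# scale, 8 base channels -- big enough to show learning, small enough to
# train in about half a minute
toy_bundle <- function() {
  if (is.null(.fixture_env$bundle)) {
    pyr <- build_pyramid(toy_sample_32(),
                         pyramid_config(scale_factor = 0.75, min_size = 16L,
                                        max_size = 32L))
    .fixture_env$bundle <- train_pyramid(
      pyr,
      scale_model_config(n_blocks = 5L, base_channels = 8L),
      train_config(epochs_per_scale = 40L, seed = 101L))
  }
  .fixture_env$bundle
}

# tiny 2-scale training closure for determinism tests (a few seconds)
tiny_train <- function(seed) {
  s <- make_toy_sample(toy_lesion_spec(size = c(16L, 16L), axes = c(4, 3),
                                       seed = 5L))
  pyr <- build_pyramid(s, pyramid_config(0.75, 12L, 16L))
  train_pyramid(pyr, scale_model_config(n_blocks = 3L, base_channels = 8L),
                train_config(epochs_per_scale = 10L, seed = seed))
}
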