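test_that("generated samples have the right shape and are seed-reproducible", {
  b <- toy_bundle()
  g <- generate_samples(b, n_samples = 4L, start_scale = 0L, seed = 21L)
  expect_length(g, 4L)
  finest <- b$sizes[[b$n_scales]]
  for (s in g) {
    expect_identical(dim(s$grid), c(finest[1], finest[2], 4L))
    expect_true(all(s$grid >= -1 & s$grid <= 1))
  }
  g2 <- generate_samples(b, n_samples = 4L, start_scale = 0L, seed = 21L)
  expect_identical(lapply(g, `[[`, "grid"), lapply(g2, `[[`, "grid"))
  g3 <- generate_samples(b, n_samples = 4L, start_scale = 0L, seed = 22L)
  expect_false(identical(g[[1]]$grid, g3[[1]]$grid))
  expect_error(generate_samples(b, start_scale = b$n_scales), "start_scale")
})

test_that("higher start scales pin generation to the reconstruction path", {
  b <- toy_bundle()
  # with every scale on the fixed path except the finest, samples differ
  # from each other less than fully random ones do
  g_all <- generate_samples(b, 3L, start_scale = 0L, seed = 5L)
  g_top <- generate_samples(b, 3L, start_scale = b$n_scales - 1L, seed = 5L)
  spread <- function(g) mean((g[[1]]$grid - g[[2]]$grid)^2)
  expect_lt(spread(g_top), spread(g_all))
  # reconstruction is deterministic and close to the samples pinned to it
  r1 <- reconstruct(b)
  r2 <- reconstruct(b)
  expect_identical(r1$grid, r2$grid)
})

test_that("an untrained bundle reconstructs to near zeros", {
  # fresh zero-head generators: every scale is the identity on its prior,
  # which starts at zeros
  set.seed(8)
  gens <- list(init_scale_models(0L, scale_model_config(base_channels = 8L))$gen,
               init_scale_models(0L, scale_model_config(base_channels = 8L))$gen)
  bundle <- structure(list(version = "segsynth-ckpt-1", n_scales = 2L,
                           gens = gens, sigmas = c(1, 0.1),
                           z_star = array(rnorm(8 * 8 * 4), c(8L, 8L, 4L)),
                           sizes = list(c(8L, 8L), c(12L, 12L)),
                           provenance = "fresh"),
                      class = "checkpoint_bundle")
  r <- reconstruct(bundle)
  expect_equal(max(abs(r$grid)), 0)
})

test_that("binarize_generated_mask applies the sign rule to channel 4 only", {
  set.seed(9)
  grid <- array(runif(6 * 6 * 4, -1, 1), c(6L, 6L, 4L))
  s <- four_channel_sample(grid)
  out <- binarize_generated_mask(s)
  expect_identical(out$grid[, , 1:3], grid[, , 1:3])
  expect_identical(out$grid[, , 4], ifelse(grid[, , 4] >= 0, 1, -1))
  expect_setequal(unique(as.vector(out$grid[, , 4])), c(-1, 1))
})

test_that("mask diversity maps implement the population mean/sd", {
  m0 <- matrix(0, 4, 4)
  m1 <- matrix(255, 4, 4)
  dm <- mask_diversity(list(m0, m1))
  expect_true(all(dm$mean_map == 127.5))
  expect_true(all(dm$sd_map == 127.5))   # two-point population SD
  # identical masks: sd identically zero, mean equals the mask
  dm2 <- mask_diversity(replicate(10, m1, simplify = FALSE))
  expect_true(all(dm2$sd_map == 0))
  expect_true(all(dm2$mean_map == 255))
  # sd_map is nonzero iff masks differ
  m2 <- m0; m2[2, 3] <- 255
  dm3 <- mask_diversity(list(m0, m2))
  expect_identical(dm3$sd_map != 0, m2 == 255)
  expect_error(mask_diversity(list(m0)), "at least 2")
  expect_error(mask_diversity(list(m0, matrix(0, 2, 2))), "shapes")
})

test_that("masks generated from the toy bundle show diversity", {
  b <- toy_bundle()
  g <- generate_samples(b, n_samples = 10L, start_scale = 0L, seed = 31L)
  dm <- mask_diversity(lapply(g, binarize_generated_mask))
  expect_identical(dm$n, 10L)
  expect_gt(max(dm$sd_map), 0)
})
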