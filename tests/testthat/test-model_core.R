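test_that("generator is the identity on its prior at initialization", {
  set.seed(3)
  ms <- init_scale_models(0L, scale_model_config(base_channels = 8L))
  prior <- array(runif(10 * 10 * 4, -0.9, 0.9), c(10L, 10L, 4L))
  noise <- array(0, c(10L, 10L, 4L))
  expect_equal(generator_forward(ms$gen, noise, prior, 1), prior)
  # deterministic: two calls with the same inputs agree bit-exactly
  z <- array(rnorm(400), c(10L, 10L, 4L))
  expect_identical(generator_forward(ms$gen, z, prior, 0.5),
                   generator_forward(ms$gen, z, prior, 0.5))
  # output stays in the model domain and has 4 channels
  y <- generator_forward(ms$gen, 10 * z, prior, 1)
  expect_identical(dim(y), c(10L, 10L, 4L))
  expect_true(all(y >= -1 & y <= 1))
  expect_error(generator_forward(ms$gen, z, array(0, c(5, 5, 4))), "differ")
})

test_that("warm start reuses weights only when the width is unchanged", {
  set.seed(4)
  cfg <- scale_model_config(base_channels = 8L, channel_growth_every = 2L)
  m0 <- init_scale_models(0L, cfg)
  m1 <- init_scale_models(1L, cfg, prev = m0)   # width still 8 -> warm
  expect_identical(m1$gen$layers[[1]]$W, m0$gen$layers[[1]]$W)
  m2 <- init_scale_models(2L, cfg, prev = m1)   # width doubles -> fresh
  expect_identical(dim(m2$gen$layers[[1]]$W)[4], 16L)
  expect_false(isTRUE(all.equal(dim(m2$gen$layers[[1]]$W),
                                dim(m1$gen$layers[[1]]$W))))
})

test_that("critic losses and penalty match independently coded oracles", {
  set.seed(5)
  disc <- segsynth:::.make_net(c(6L, 6L, 1L), cin = 4L, k = 3L,
                               final = "linear")
  real <- array(rnorm(8 * 8 * 4, sd = 0.5), c(8L, 8L, 4L))
  fake <- array(rnorm(8 * 8 * 4, sd = 0.5), c(8L, 8L, 4L))
  for (u in c(0.2, 0.7)) {
    got <- critic_losses(disc, real, fake, gp_weight = 0.1, u = u)
    want <- oracle_critic_losses(disc, real, fake, gp_weight = 0.1, u = u)
    expect_equal(got$d_loss, want$d_loss, tolerance = 1e-6)
    expect_equal(got$g_adv_loss, want$g_adv_loss, tolerance = 1e-6)
  }
  # constant critic (zero weights): d_loss reduces to the penalty,
  # g_adv_loss to minus the constant
  dz <- disc
  for (i in seq_along(dz$layers)) dz$layers[[i]]$W[] <- 0
  dz$layers[[3]]$b <- 2.5
  l <- critic_losses(dz, real, fake, gp_weight = 0.3, u = 0.5)
  expect_equal(l$g_adv_loss, -2.5)
  expect_equal(l$d_loss, 0.3 * (0 - 1)^2)  # zero gradient -> (0-1)^2 penalty
})

test_that("gradient penalty matches closed forms for linear critics", {
  # critic with exactly unit input-gradient norm: penalty identically zero
  x <- array(0.3, c(8L, 8L, 4L))
  y <- array(-0.2, c(8L, 8L, 4L))
  d_unit <- linear_critic(sqrt(64 / 4))       # norm = w0*sqrt(C/(HW)) = 1
  expect_identical(gradient_penalty(d_unit, x, y, 0.1, u = 0.4), 0)
  # gradient norm 2, weight 0.1 -> penalty (2-1)^2 * 0.1 = 0.1
  d_two <- linear_critic(2 * sqrt(64 / 4))
  expect_equal(gradient_penalty(d_two, x, y, 0.1, u = 0.4), 0.1)
  # real == fake: penalty independent of the interpolation coefficient
  set.seed(6)
  disc <- segsynth:::.make_net(c(6L, 1L), cin = 4L, k = 3L, final = "linear")
  z <- array(rnorm(256, sd = 0.3), c(8L, 8L, 4L))
  expect_equal(gradient_penalty(disc, z, z, 1, u = 0.1),
               gradient_penalty(disc, z, z, 1, u = 0.9))
})

test_that("reconstruction loss and noise amplitude follow their formulas", {
  a <- array(0.2, c(6L, 6L, 4L))
  expect_identical(reconstruction_loss(a, a, 10), 0)
  expect_equal(reconstruction_loss(a + 0.1, a, 10), 0.1)  # 10 * 0.01
  # mask-only mismatch still contributes
  b <- a; b[, , 4] <- 0.5
  expect_gt(reconstruction_loss(b, a, 10), 0)
  expect_identical(compute_noise_amplitude(0L, a, a), 1)
  expect_identical(compute_noise_amplitude(3L, a, a, 0.1), 0)
  expect_equal(compute_noise_amplitude(1L, a + 0.2, a, 0.1), 0.02)
})

test_that("toy training improves reconstruction at every scale", {
  b <- toy_bundle()
  h <- b$history
  for (sc in unique(h$scale)) {
    hs <- h[h$scale == sc, ]
    expect_lt(hs$recon_mse[nrow(hs)], hs$recon_mse[1])
  }
  expect_true(all(is.finite(h$d_loss)))
  # noise amplitudes: 1 at the coarsest, positive and modest above
  expect_identical(b$sigmas[1], 1)
  expect_true(all(b$sigmas[-1] > 0 & b$sigmas[-1] < 1))
})

test_that("training is deterministic under a fixed seed", {
  b1 <- tiny_train(77L)
  b2 <- tiny_train(77L)
  expect_equal(b1$gens, b2$gens, tolerance = 0)
  expect_identical(b1$z_star, b2$z_star)
  b3 <- tiny_train(78L)
  expect_false(isTRUE(all.equal(b1$gens, b3$gens)))
})

test_that("checkpoint save/load round trip preserves generation bit-exactly", {
  b <- toy_bundle()
  tmp <- withr::local_tempdir()
  ck <- file.path(tmp, "ckpt")
  save_checkpoint(b, ck)
  b2 <- load_checkpoint(ck)
  g1 <- generate_samples(b, n_samples = 2L, seed = 7L)
  g2 <- generate_samples(b2, n_samples = 2L, seed = 7L)
  expect_identical(lapply(g1, `[[`, "grid"), lapply(g2, `[[`, "grid"))
  expect_identical(reconstruct(b)$grid, reconstruct(b2)$grid)
  # a bundle missing a scale must fail to load
  file.remove(file.path(ck, "scale_001.rds"))
  expect_error(load_checkpoint(ck), "missing scale 1")
  expect_error(load_checkpoint(file.path(tmp, "nowhere")), "no checkpoint")
})

test_that("a reloaded bundle reproduces samples in a fresh process", {
  skip_if_not_installed("callr")
  b <- toy_bundle()
  tmp <- withr::local_tempdir()
  ck <- file.path(tmp, "ckpt2")
  save_checkpoint(b, ck)
  here <- reconstruct(b)$grid
  there <- callr::r(function(path) {
    library(segsynth)
    reconstruct(load_checkpoint(path))$grid
  }, args = list(path = ck))
  expect_identical(here, there)
})
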