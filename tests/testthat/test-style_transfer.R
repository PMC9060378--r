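test_that("gram matrix matches the hand-computed scaling and is PSD", {
  # single-channel 2x2 one-hot feature: G[1,1] = 1/(C*H*W) = 1/4
  f <- array(0, c(2L, 2L, 1L))
  f[1, 2, 1] <- 1
  expect_identical(gram_matrix(f), matrix(0.25, 1, 1))
  expect_identical(gram_matrix(array(0, c(3, 3, 2))), matrix(0, 2, 2))
  set.seed(10)
  g <- gram_matrix(array(rnorm(5 * 4 * 3), c(5L, 4L, 3L)))
  expect_equal(g, t(g))
  expect_true(all(eigen(g, symmetric = TRUE, only.values = TRUE)$values >
                  -1e-12))
})

test_that("content and style distances vanish at their references", {
  set.seed(11)
  fx <- feature_extractor("test")
  img <- array(runif(24 * 24 * 3, -1, 1), c(24L, 24L, 3L))
  fa <- extract_features(fx, img)
  expect_identical(content_loss(fa, fa, "conv3"), 0)
  expect_identical(style_loss(fa, fa, c("conv1", "conv2", "conv3", "conv4")),
                   0)
  expect_error(content_loss(fa, fa, "conv9"), "unknown content layer")
})

test_that("losses match an independent recomputation", {
  set.seed(12)
  fx <- feature_extractor("test")
  a <- extract_features(fx, array(runif(20 * 20 * 3, -1, 1), c(20, 20, 3)))
  b <- extract_features(fx, array(runif(20 * 20 * 3, -1, 1), c(20, 20, 3)))
  # content: plain MSE over the tap
  expect_equal(content_loss(a, b, "conv2"),
               mean((a$conv2 - b$conv2)^2), tolerance = 1e-12)
  # style: sum over taps of MSE between explicitly assembled Gram matrices
  taps <- c("conv1", "conv3")
  want <- sum(vapply(taps, function(l) {
    d <- dim(a[[l]])
    Fa <- t(apply(matrix(a[[l]], d[1] * d[2], d[3]), 2, identity))
    Fb <- t(apply(matrix(b[[l]], d[1] * d[2], d[3]), 2, identity))
    Ga <- (Fa %*% t(Fa)) / prod(d)
    Gb <- (Fb %*% t(Fb)) / prod(d)
    mean((Ga - Gb)^2)
  }, 0))
  expect_equal(style_loss(a, b, taps), want, tolerance = 1e-12)
})

test_that("the feature extractor is deterministic and rejects pretrained", {
  img <- array(0.2, c(16L, 16L, 3L))
  f1 <- extract_features(feature_extractor("test", seed = 77L), img)
  f2 <- extract_features(feature_extractor("test", seed = 77L), img)
  expect_identical(f1, f2)
  expect_error(feature_extractor("pretrained"), "not bundled")
})

test_that("style == content with content init is a fixed point", {
  s <- toy_sample_32()
  img <- split_four_channel(s)$img
  out <- run_style_transfer(img, img, style_transfer_config(steps = 10L))
  expect_identical(as.vector(out), as.vector(img))
  expect_true(all(attr(out, "loss_history") == attr(out, "loss_history")[1]))
})

test_that("with zero style weight and content init the output is content", {
  set.seed(13)
  content <- array(runif(20 * 20 * 3, -1, 1), c(20L, 20L, 3L))
  style <- array(runif(20 * 20 * 3, -1, 1), c(20L, 20L, 3L))
  out <- run_style_transfer(content, style,
                            style_transfer_config(content_weight = 1,
                                                  style_weight = 0,
                                                  steps = 5L))
  expect_identical(as.vector(out), as.vector(content))
})

test_that("optimization decreases the loss and is mostly monotone", {
  set.seed(14)
  content <- split_four_channel(make_toy_sample(
    toy_lesion_spec(size = c(32L, 32L), axes = c(8, 6), seed = 41L)))$img
  style <- split_four_channel(make_toy_sample(
    toy_lesion_spec(size = c(32L, 32L), axes = c(7, 7), background = "speckle",
                    seed = 42L)))$img
  out <- run_style_transfer(content, style,
                            style_transfer_config(style_weight = 1000,
                                                  steps = 50L))
  h <- attr(out, "loss_history")
  expect_lt(h[length(h)], h[1])
  # line-search steps: non-increasing at >= 90% of recorded steps
  expect_gte(mean(diff(h) <= 1e-12), 0.9)
  expect_true(all(out >= -1 & out <= 1))
})

test_that("transfer_sample refines RGB and passes the mask through", {
  gen <- make_toy_sample(toy_lesion_spec(size = c(24L, 24L), axes = c(6, 5),
                                         seed = 51L))
  real <- make_toy_sample(toy_lesion_spec(size = c(24L, 24L), axes = c(5, 6),
                                          background = "gradient", seed = 52L))
  out <- transfer_sample(gen, real, style_transfer_config(steps = 8L))
  expect_identical(out$grid[, , 4], gen$grid[, , 4])  # bit-identical mask
  expect_false(identical(out$grid[, , 1:3], gen$grid[, , 1:3]))
  # style image of a different size is resized onto the content grid
  small_real <- make_toy_sample(toy_lesion_spec(size = c(16L, 16L),
                                                axes = c(4, 4), seed = 53L))
  out2 <- transfer_sample(gen, small_real, style_transfer_config(steps = 3L))
  expect_identical(dim(out2$grid), dim(gen$grid))
})
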