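test_that("frechet_distance matches closed forms and is symmetric", {
  a <- gaussian_stats(c(0, 0), diag(2))
  b <- gaussian_stats(c(3, 4), diag(2))
  expect_equal(frechet_distance(a, b), 25)      # identity covs: ||dmu||^2
  expect_lte(frechet_distance(a, a), 1e-8)
  set.seed(15)
  for (i in 1:5) {
    x <- gaussian_stats(rnorm(5), random_psd(5))
    y <- gaussian_stats(rnorm(5), random_psd(5))
    expect_equal(frechet_distance(x, y), frechet_distance(y, x),
                 tolerance = 1e-8)
    expect_gte(frechet_distance(x, y), 0)
    # dual-algorithm agreement with the Denman-Beavers oracle
    expect_equal(frechet_distance(x, y), oracle_frechet(x, y),
                 tolerance = 1e-6)
  }
  expect_error(frechet_distance(a, gaussian_stats(rnorm(3), diag(3))),
               "dimension")
  neg <- diag(c(1, -0.5))
  expect_error(frechet_distance(gaussian_stats(c(0, 0), neg), a),
               "positive semidefinite")
})

test_that("feature statistics recover a known Gaussian at large n", {
  set.seed(16)
  d <- 4L; n <- 2000L
  mu <- c(1, -2, 0.5, 3)
  A <- matrix(rnorm(d * d), d) / sqrt(d)
  Sigma <- A %*% t(A) + 0.2 * diag(d)
  X <- matrix(rnorm(n * d), n) %*% chol(Sigma) + rep(mu, each = n)
  st <- feature_stats(X)
  expect_identical(st$n, n)
  expect_lt(max(abs(st$mu - mu)), 4 * sqrt(max(diag(Sigma)) / n))
  expect_lt(max(abs(st$cov - (t(chol(Sigma)) %*% chol(Sigma)))), 0.15)
  expect_error(feature_stats(X[1, , drop = FALSE]), "at least 2")
})

test_that("dataset stats handle duplicates and mixed sizes", {
  be <- feature_backend()
  img <- split_four_channel(toy_sample_32())$img
  st <- dataset_feature_stats(replicate(5, img, simplify = FALSE), be)
  expect_equal(max(abs(st$cov)), 0)            # duplicated image: zero cov
  imgs <- list(img, resize_bilinear(img, 48L, 40L),
               resize_bilinear(img, 24L, 24L))
  expect_s3_class(dataset_feature_stats(imgs, be), "gaussian_stats")
  expect_error(dataset_feature_stats(list(img), be), "at least 2")
})

test_that("FID and SIFID of a dataset against itself are numerically zero", {
  be <- feature_backend()
  ds <- make_toy_dataset(5L, size = 48L, seed = 61L)
  imgs <- lapply(ds, function(s) split_four_channel(s)$img)
  expect_lte(abs(compute_fid(imgs, imgs, be)), 1e-6)
  sif <- compute_sifid(imgs, imgs, be)
  expect_lte(abs(as.numeric(sif)), 1e-6)
  expect_length(attr(sif, "per_pair"), 5L)
  expect_error(compute_sifid(imgs, imgs[1:2], be), "equal length")
})

test_that("compute_fid matches the analytic Gaussian distance", {
  # bypass images: construct feature stats directly from known Gaussians
  set.seed(17)
  a <- gaussian_stats(c(1, 2, 3), 0.5 * diag(3))
  b <- gaussian_stats(c(1, 2, 4), 2 * diag(3))
  # closed form for commuting (diagonal) covariances:
  # ||dmu||^2 + sum((sqrt(ca) - sqrt(cb))^2)
  want <- 1 + 3 * (sqrt(0.5) - sqrt(2))^2
  expect_equal(frechet_distance(a, b), want, tolerance = 1e-10)
})

test_that("reports over repeated sets carry per-set values, mean and SD", {
  be <- feature_backend()
  real <- lapply(make_toy_dataset(4L, 32L, seed = 71L),
                 function(s) split_four_channel(s)$img)
  sets <- lapply(1:3, function(k)
    lapply(make_toy_dataset(4L, 32L, seed = 80L + k),
           function(s) split_four_channel(s)$img))
  rep_fid <- fid_report(real, sets, be)
  expect_s3_class(rep_fid, "frechet_report")
  expect_length(rep_fid$per_set_values, 3L)
  expect_equal(rep_fid$mean, mean(rep_fid$per_set_values))
  expect_equal(rep_fid$sd, sd(rep_fid$per_set_values))
  rep_sif <- sifid_report(real, sets, be)
  expect_true(all(rep_sif$per_set_values > 0))
})

test_that("inception backends explain their unavailability", {
  expect_error(feature_backend("inception-pool3"), "pretrained Inception")
})

test_that("true pixel percentage equals a counting oracle", {
  set.seed(18)
  m <- matrix(sample(c(0, 255), 128 * 128, TRUE, prob = c(0.75, 0.25)),
              128L, 128L)
  expect_equal(true_pixel_percentage(m), 100 * sum(m == 255) / length(m))
  q <- matrix(0, 128, 128); q[1:64, 1:64] <- 255
  expect_identical(true_pixel_percentage(q), 25)   # 4096 / 16384
  expect_identical(true_pixel_percentage(matrix(0, 4, 4)), 0)
  expect_identical(true_pixel_percentage(matrix(c(-1, 1), 4, 4)), 50)
  expect_identical(true_pixel_percentage(q == 255),
                   true_pixel_percentage(q))
  # scale invariance under pixel-replication upscaling
  big <- q[rep(1:128, each = 2), rep(1:128, each = 2)]
  expect_identical(true_pixel_percentage(big), true_pixel_percentage(q))
  expect_error(true_pixel_percentage(matrix(c(0, 100), 2, 2)), "not binary")
})

test_that("percentage histogram bins conserve counts", {
  h <- percentage_histogram(c(2.5, 7.5))
  expect_length(h, 20L)
  expect_identical(as.integer(h[1:2]), c(1L, 1L))
  expect_identical(sum(h), 2L)
  # boundary conventions: 5 goes up, 100 stays in the last bin
  h2 <- percentage_histogram(c(0, 5, 99.999, 100))
  expect_identical(as.integer(h2[c(1, 2, 20)]), c(1L, 1L, 2L))
  set.seed(19)
  v <- runif(500, 0, 100)
  expect_identical(sum(percentage_histogram(v)), 500L)
  expect_error(percentage_histogram(c(5, 101)), "outside")
  expect_error(percentage_histogram(5, bin_width = 3), "divide")
})
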