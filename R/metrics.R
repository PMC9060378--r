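# Evaluation machinery: Frechet distances between Gaussian feature
# statistics (dataset-level FID and per-image SIFID over spatial features),
# report aggregation over repeated generated sets, and binary-mask
# distribution statistics.

#' Construct a feature backend for Frechet metrics
#'
#' The `"deterministic-test"` backend resizes images to 64 x 64 and applies
#' a small seeded random-weight CNN, yielding 16 x 16 spatial locations with
#' 16-dimensional feature vectors (SIFID) or their spatial mean (FID).  It
#' is deterministic, needs no downloads, and is the default.  The
#' `"inception-pool3"` / `"inception-early"` backends correspond to the
#' standard pretrained Inception taps; pretrained weights cannot be obtained
#' in an offline installation, so they signal an informative error.
#'
#' @param name backend name.
#' @param seed seed fixing the test backend's weights.
#' @return an object of class `feature_backend`.
#' @export
feature_backend <- function(name = c("deterministic-test", "inception-pool3",
                                     "inception-early"), seed = 123L) {
  name <- match.arg(name)
  if (name != "deterministic-test")
    stop("backend '", name, "' needs pretrained Inception weights, which ",
         "are not bundled and cannot be downloaded here; ",
         "use \"deterministic-test\"")
  widths <- c(12L, 16L)
  cins <- c(3L, 12L)
  layers <- .with_seed(seed, lapply(seq_along(widths), function(i) {
    sd <- sqrt(2 / (9 * cins[i]))
    list(W = array(stats::rnorm(9 * cins[i] * widths[i], sd = sd),
                   c(3L, 3L, cins[i], widths[i])),
         b = numeric(widths[i]))
  }))
  structure(list(name = name, layers = layers, slope = 0.01,
                 input_size = 64L, dim = 16L, spatial = TRUE),
            class = "feature_backend")
}

.as_rgb_array <- function(img) {
  if (inherits(img, "four_channel_sample")) img <- split_four_channel(img)$img
  d <- dim(img)
  if (length(d) != 3L || d[3] != 3L)
    stop("expected an H x W x 3 RGB array")
  img
}

# spatial features: H' x W' x dim array (per-location feature vectors)
.backend_spatial <- function(backend, img) {
  x <- resize_bilinear(.as_rgb_array(img), backend$input_size,
                       backend$input_size)
  for (l in backend$layers) {
    z <- .conv_forward(.nn_pad(x, 1L), l$W, l$b)
    x <- .avgpool2(z * .lrelu_mask(z, backend$slope))
  }
  x
}

.backend_pooled <- function(backend, img) {
  f <- .backend_spatial(backend, img)
  colMeans(matrix(f, ncol = dim(f)[3]))
}

#' Gaussian sufficient statistics
#'
#' @param mu mean vector.
#' @param cov covariance matrix (symmetric, same dimension as `mu`).
#' @param n sample count the statistics were estimated from.
#' @return an object of class `gaussian_stats`.
#' @export
gaussian_stats <- function(mu, cov, n = NA_integer_) {
  cov <- as.matrix(cov)
  if (length(mu) != nrow(cov) || nrow(cov) != ncol(cov))
    stop("mu/cov dimensions inconsistent")
  if (max(abs(cov - t(cov))) > 1e-8 * max(1, max(abs(cov))))
    stop("covariance is not symmetric")
  structure(list(mu = as.numeric(mu), cov = (cov + t(cov)) / 2,
                 n = n), class = "gaussian_stats")
}

#' Gaussian statistics of a feature matrix
#'
#' @param x n x d matrix of feature vectors (rows = observations).
#' @return a [gaussian_stats()] (unbiased covariance estimator).
#' @export
feature_stats <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 observations")
  gaussian_stats(colMeans(x), stats::cov(x), nrow(x))
}

#' Pooled-feature Gaussian statistics of an image set
#'
#' @param images list of RGB images (H x W x 3 model-domain arrays or
#'   [four_channel_sample()] objects); images are resized per the backend
#'   contract before feature extraction, so mixed sizes are fine.
#' @param backend a [feature_backend()].
#' @return a [gaussian_stats()].
#' @export
dataset_feature_stats <- function(images, backend = feature_backend()) {
  if (length(images) < 2L)
    stop("need at least 2 images for a nondegenerate covariance")
  feats <- t(vapply(images, function(im) .backend_pooled(backend, im),
                    numeric(backend$dim)))
  feature_stats(feats)
}

# symmetric PSD square root via eigendecomposition; negative eigenvalues are
# clipped at 0 but rejected beyond tolerance
.sqrtm_psd <- function(M, tol = 1e-8) {
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  scale <- max(1, abs(e$values[1]))
  if (min(e$values) < -tol * scale)
    stop("matrix is not positive semidefinite within tolerance (min ",
         "eigenvalue ", signif(min(e$values), 3), ")")
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Frechet distance between two Gaussians
#'
#' Computes `||mu_a - mu_b||^2 + Tr(C_a + C_b - 2 (C_a C_b)^{1/2})` with the
#' matrix square root evaluated as `S (S C_b S)^{1/2} S^{-...}` -- in the
#' numerically standard symmetric form `sqrtm(S_a C_b S_a)` where
#' `S_a = sqrtm(C_a)` -- using eigendecompositions with negative-eigenvalue
#' clipping at tolerance 1e-8.
#'
#' @param a,b [gaussian_stats()] objects of matching dimension.
#' @return non-negative scalar (values within 1e-8 of zero are possible for
#'   identical inputs).
#' @export
frechet_distance <- function(a, b) {
  stopifnot(inherits(a, "gaussian_stats"), inherits(b, "gaussian_stats"))
  if (length(a$mu) != length(b$mu)) stop("dimension mismatch")
  Sa <- .sqrtm_psd(a$cov)
  cross <- .sqrtm_psd(Sa %*% b$cov %*% Sa)
  d <- sum((a$mu - b$mu)^2) +
    sum(diag(a$cov)) + sum(diag(b$cov)) - 2 * sum(diag(cross))
  if (d < 0 && d > -1e-6) d <- 0
  d
}

#' Dataset FID
#'
#' Frechet distance between the pooled-feature Gaussians of two image sets.
#'
#' @param real,fake nonempty lists of RGB images.
#' @param backend a [feature_backend()].
#' @return scalar FID.
#' @export
compute_fid <- function(real, fake, backend = feature_backend()) {
  frechet_distance(dataset_feature_stats(real, backend),
                   dataset_feature_stats(fake, backend))
}

#' Single-image FID over paired images
#'
#' For each (real, fake) pair, fits a Gaussian to the per-spatial-location
#' feature vectors of each single image and computes the Frechet distance
#' between the two; returns the mean over pairs, with per-pair values as
#' `attr(x, "per_pair")`.
#'
#' @param real,fake paired lists (same length) of RGB images.
#' @param backend a [feature_backend()] with spatial features.
#' @return scalar mean SIFID.
#' @export
compute_sifid <- function(real, fake, backend = feature_backend()) {
  if (length(real) != length(fake) || length(real) == 0L)
    stop("real and fake must be nonempty paired lists of equal length")
  if (!isTRUE(backend$spatial)) stop("SIFID needs a spatial backend")
  per_pair <- vapply(seq_along(real), function(i) {
    fr <- .backend_spatial(backend, real[[i]])
    ff <- .backend_spatial(backend, fake[[i]])
    if (prod(dim(fr)[1:2]) < 4L) stop("feature map spatially too small")
    frechet_distance(feature_stats(matrix(fr, ncol = dim(fr)[3])),
                     feature_stats(matrix(ff, ncol = dim(ff)[3])))
  }, 0)
  structure(mean(per_pair), per_pair = per_pair)
}

#' Aggregate per-set metric values into a report
#'
#' The reporting shape used for repeated generated sets: one value per set
#' plus their mean and (sample) standard deviation.
#'
#' @param per_set_values numeric vector, one metric value per generated set.
#' @return an object of class `frechet_report`.
#' @export
frechet_report <- function(per_set_values) {
  v <- as.numeric(per_set_values)
  structure(list(per_set_values = v, mean = mean(v),
                 sd = if (length(v) > 1L) stats::sd(v) else NA_real_),
            class = "frechet_report")
}

#' @export
print.frechet_report <- function(x, ...) {
  cat(sprintf("<frechet_report> %d sets: %s | mean %.4g sd %.4g\n",
              length(x$per_set_values),
              paste(signif(x$per_set_values, 4), collapse = " "),
              x$mean, x$sd))
  invisible(x)
}

#' FID / SIFID over repeated generated sets
#'
#' @param real list of real RGB images.
#' @param fake_sets list of generated sets (each a list of RGB images; for
#'   `sifid_report` each set is paired with `real`).
#' @param backend a [feature_backend()].
#' @return a [frechet_report()].
#' @export
fid_report <- function(real, fake_sets, backend = feature_backend()) {
  frechet_report(vapply(fake_sets, function(fs)
    compute_fid(real, fs, backend), 0))
}

#' @rdname fid_report
#' @export
sifid_report <- function(real, fake_sets, backend = feature_backend()) {
  frechet_report(vapply(fake_sets, function(fs)
    as.numeric(compute_sifid(real, fs, backend)), 0))
}

#' Foreground percentage of a binary mask
#'
#' @param mask a binary mask: logical matrix, file-domain matrix with values
#'   in `{0, 255}`, or model-domain matrix with values in `{-1, 1}`.
#' @return `100 * foreground pixels / total pixels`.
#' @export
true_pixel_percentage <- function(mask) {
  if (inherits(mask, "four_channel_sample")) mask <- mask$grid[, , 4]
  if (is.logical(mask)) return(100 * mean(mask))
  u <- sort(unique(as.vector(mask)))
  if (all(u %in% c(0, 255))) return(100 * mean(mask == 255))
  if (all(u %in% c(-1, 1))) return(100 * mean(mask == 1))
  stop("mask is not binary: values ", paste(utils::head(u, 5), collapse = ", "))
}

#' Histogram of mask-size percentages
#'
#' Bins `[0, bin_width), [bin_width, 2 bin_width), ..., [100 - bin_width,
#' 100]` -- half-open except the last bin, which includes 100.  Counts
#' always sum to `length(values)`.
#'
#' @param values percentages in `[0, 100]`.
#' @param bin_width bin width; must divide 100.
#' @return named integer vector of `100 / bin_width` counts, with bin lower
#'   edges as `attr(x, "breaks")`.
#' @export
percentage_histogram <- function(values, bin_width = 5) {
  if (100 %% bin_width != 0) stop("bin_width must divide 100")
  if (any(values < 0 | values > 100))
    stop("values outside [0, 100]: ",
         paste(utils::head(values[values < 0 | values > 100], 3),
               collapse = ", "))
  nb <- as.integer(100 / bin_width)
  idx <- pmin(floor(values / bin_width), nb - 1L) + 1L
  counts <- tabulate(idx, nbins = nb)
  lo <- (seq_len(nb) - 1L) * bin_width
  names(counts) <- sprintf("[%g,%g%s", lo, lo + bin_width,
                           c(rep(")", nb - 1L), "]"))
  attr(counts, "breaks") <- lo
  counts
}
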