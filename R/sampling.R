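# Sample generation from trained checkpoints, mask post-processing, and the
# pixel-wise mask diversity statistics.

#' Generate random four-channel samples from a trained bundle
#'
#' Scales below `start_scale` follow the fixed reconstruction path (the
#' stored `z_star` at the coarsest scale, zero noise above); from
#' `start_scale` upward fresh noise is injected at every scale.
#' `start_scale = 0` (the default, and the convention used for maximal
#' diversity) randomizes every scale including the coarsest.
#'
#' @param bundle a trained `checkpoint_bundle`.
#' @param n_samples number of samples (default 10).
#' @param start_scale 0-based index of the first randomized scale; must lie
#'   in `[0, n_scales - 1]`.
#' @param seed integer seed; generation is deterministic given the seed.
#' @return list of `n_samples` [four_channel_sample()] objects at the finest
#'   resolution, mask channel continuous (see [binarize_generated_mask()]).
#' @export
generate_samples <- function(bundle, n_samples = 10L, start_scale = 0L,
                             seed = 1L) {
  stopifnot(inherits(bundle, "checkpoint_bundle"), n_samples >= 1L)
  if (start_scale < 0L || start_scale >= bundle$n_scales)
    stop("start_scale must be in [0, ", bundle$n_scales - 1L, "], got ",
         start_scale)
  .with_seed(seed, {
    lapply(seq_len(n_samples), function(k) {
      y <- .gen_path(bundle$gens, bundle$sigmas, bundle$z_star, bundle$sizes,
                     start_scale = start_scale)
      four_channel_sample(y, sprintf("%s/gen%03d", bundle$provenance, k))
    })
  })
}

#' Reconstruct the training sample from a bundle
#'
#' Runs the deterministic reconstruction path: the stored fixed noise
#' `z_star` at the coarsest scale and zero noise at every finer scale.  For
#' a trained bundle the result approximates the training image.
#'
#' @param bundle a `checkpoint_bundle`.
#' @return a [four_channel_sample()].
#' @export
reconstruct <- function(bundle) {
  stopifnot(inherits(bundle, "checkpoint_bundle"))
  if (is.null(bundle$z_star)) stop("bundle has no reconstruction noise z_star")
  y <- .gen_path(bundle$gens, bundle$sigmas, bundle$z_star, bundle$sizes,
                 start_scale = bundle$n_scales)
  four_channel_sample(y, sprintf("%s/recon", bundle$provenance))
}

#' Binarize the mask channel of a generated sample
#'
#' Thresholds the continuous mask channel at the model-domain midpoint 0:
#' values `>= 0` become foreground (+1), the rest background (-1).  RGB
#' channels are untouched.
#'
#' @param sample a [four_channel_sample()].
#' @return the sample with a binary mask channel.
#' @export
binarize_generated_mask <- function(sample) {
  stopifnot(inherits(sample, "four_channel_sample"))
  sample$grid <- .rebinarize_mask(sample$grid)
  sample
}

#' Pixel-wise mean and standard deviation of a mask stack
#'
#' Stacks the masks and computes per-pixel mean and population standard
#' deviation in the file domain (0/255), the diversity maps used to
#' visualize how much generated masks vary across samples.
#'
#' @param masks list of at least two masks of equal shape; each mask may be a
#'   file-domain matrix (values 0/255), a logical matrix, a model-domain
#'   matrix, or a [four_channel_sample()] (its mask channel is used).
#' @return an object of class `diversity_maps`: list with `mean_map`,
#'   `sd_map` (both H x W, file-domain units) and `n`.
#' @export
mask_diversity <- function(masks) {
  if (length(masks) < 2L) stop("need at least 2 masks")
  as_file_mask <- function(m) {
    if (inherits(m, "four_channel_sample")) m <- m$grid[, , 4]
    if (is.logical(m)) return(ifelse(m, 255, 0))
    if (all(m %in% c(0, 255))) return(m + 0)          # file domain already
    if (all(m >= -1 & m <= 1)) return(ifelse(m >= 0, 255, 0))  # model domain
    ifelse(m >= 128, 255, 0)
  }
  ms <- lapply(masks, as_file_mask)
  d <- dim(ms[[1]])
  if (!all(vapply(ms, function(m) identical(dim(m), d), TRUE)))
    stop("masks have differing shapes")
  n <- length(ms)
  s1 <- Reduce(`+`, ms)
  s2 <- Reduce(`+`, lapply(ms, function(m) m * m))
  mean_map <- s1 / n
  var_map <- pmax(s2 / n - mean_map^2, 0)
  structure(list(mean_map = mean_map, sd_map = sqrt(var_map), n = n),
            class = "diversity_maps")
}

#' @export
print.diversity_maps <- function(x, ...) {
  cat(sprintf("<diversity_maps> %d masks, %dx%d, mean sd %.2f\n",
              x$n, nrow(x$sd_map), ncol(x$sd_map), mean(x$sd_map)))
  invisible(x)
}
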