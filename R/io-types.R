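# Four-channel sample representation and multi-resolution pyramid.
#
# Two value domains are used throughout:
#   file domain  -- 8-bit intensities in [0, 255]; masks are strictly {0, 255}
#                   (255 = foreground).
#   model domain -- real values in [-1, 1], the range of the tanh-bounded
#                   generators; file value v maps to v/127.5 - 1.
# A four_channel_sample always stores the model domain.

#' Domain conversions
#'
#' Linear maps between the 8-bit file domain `[0, 255]` and the model domain
#' `[-1, 1]`.  `model_to_file` quantizes to integers, clipping to the valid
#' range first.
#'
#' @param x numeric array.
#' @return converted array.
#' @export
file_to_model <- function(x) x / 127.5 - 1

#' @rdname file_to_model
#' @export
model_to_file <- function(x) {
  v <- round((.clamp(x) + 1) * 127.5)
  storage.mode(v) <- "integer"
  v
}

#' Construct a four-channel sample
#'
#' @param grid H x W x 4 numeric array in the model domain; channels 1-3 are
#'   RGB, channel 4 is the mask channel.
#' @param provenance free-text identifier carried along with the sample.
#' @return an object of class `four_channel_sample`.
#' @export
four_channel_sample <- function(grid, provenance = "") {
  d <- dim(grid)
  if (length(d) != 3L || d[3] != 4L)
    stop("a four-channel sample needs an H x W x 4 grid, got ",
         paste(d, collapse = "x"))
  if (any(!is.finite(grid))) stop("non-finite values in sample grid")
  structure(list(grid = grid, provenance = as.character(provenance)),
            class = "four_channel_sample")
}

#' @export
print.four_channel_sample <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<four_channel_sample> %dx%d, provenance '%s'\n",
              d[1], d[2], x$provenance))
  invisible(x)
}

#' Stack an RGB image and a mask into a four-channel sample
#'
#' @param img H x W x 3 model-domain RGB array.
#' @param mask H x W model-domain mask (matrix).
#' @param provenance identifier for the resulting sample.
#' @return a [four_channel_sample()].
#' @export
stack_four_channel <- function(img, mask, provenance = "") {
  di <- dim(img)
  if (length(di) != 3L || di[3] != 3L) stop("img must be H x W x 3")
  if (!identical(dim(mask)[1:2], di[1:2]))
    stop("image is ", di[1], "x", di[2], " but mask is ",
         paste(dim(mask)[1:2], collapse = "x"))
  grid <- array(0, c(di[1], di[2], 4L))
  grid[, , 1:3] <- img
  grid[, , 4] <- mask
  four_channel_sample(grid, provenance)
}

#' Split a four-channel sample into its RGB image and mask channel
#'
#' The lossless inverse of [stack_four_channel()].  The mask channel is
#' returned as-is (continuous in the model domain); thresholding is a
#' separate operation ([binarize_generated_mask()]).
#'
#' @param sample a [four_channel_sample()].
#' @return list with `img` (H x W x 3) and `mask` (H x W matrix).
#' @export
split_four_channel <- function(sample) {
  if (!inherits(sample, "four_channel_sample"))
    sample <- four_channel_sample(sample)
  list(img = sample$grid[, , 1:3, drop = FALSE],
       mask = sample$grid[, , 4])
}

# read one image file into a file-domain array (H x W x C, values 0..255)
.read_image_file <- function(path) {
  if (!file.exists(path)) stop("cannot read ", path, ": no such file")
  ext <- tolower(tools::file_ext(path))
  px <- if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("jpeg", quietly = TRUE))
      stop("reading JPEG requires the 'jpeg' package")
    jpeg::readJPEG(path)
  } else {
    png::readPNG(path)
  }
  if (is.matrix(px)) dim(px) <- c(dim(px), 1L)
  round(px * 255)
}

#' Load an image/mask pair as a four-channel sample
#'
#' The mask file is strictly binarized at the 8-bit midpoint (value >= 128 is
#' foreground) before normalization, so gray pixels from antialiased or
#' lossy-compressed masks are resolved deterministically.
#'
#' @param image_path PNG or JPEG RGB image.
#' @param mask_path single-channel PNG mask, white (255) foreground.
#' @return a model-domain [four_channel_sample()]; provenance is the image
#'   file name without extension.
#' @export
load_sample <- function(image_path, mask_path) {
  img <- .read_image_file(image_path)
  msk <- .read_image_file(mask_path)
  if (dim(img)[3] == 1L) img <- array(rep(img, 3L), c(dim(img)[1:2], 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]  # drop alpha
  if (dim(msk)[3] > 1L) msk <- msk[, , 1, drop = FALSE]
  if (!identical(dim(img)[1:2], dim(msk)[1:2]))
    stop("image is ", dim(img)[1], "x", dim(img)[2], " but mask is ",
         dim(msk)[1], "x", dim(msk)[2])
  mask_bin <- ifelse(msk[, , 1] >= 128, 255, 0)
  stack_four_channel(file_to_model(img), file_to_model(mask_bin),
                     provenance = tools::file_path_sans_ext(basename(image_path)))
}

#' Save a four-channel sample as an image file and a mask file
#'
#' The RGB channels are written as an 8-bit PNG (or JPEG by extension); the
#' mask channel is binarized at the model-domain midpoint 0 and written as a
#' single-channel 8-bit PNG containing only 0 and 255.
#'
#' @param sample a [four_channel_sample()].
#' @param image_path,mask_path output paths.
#' @return invisibly, `c(image_path, mask_path)`.
#' @export
save_sample <- function(sample, image_path, mask_path) {
  parts <- split_four_channel(sample)
  img8 <- model_to_file(parts$img)
  ext <- tolower(tools::file_ext(image_path))
  if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("jpeg", quietly = TRUE))
      stop("writing JPEG requires the 'jpeg' package")
    jpeg::writeJPEG(img8 / 255, image_path, quality = 0.95)
  } else {
    png::writePNG(img8 / 255, image_path)
  }
  mask8 <- ifelse(parts$mask >= 0, 255L, 0L)
  png::writePNG(mask8 / 255, mask_path)
  invisible(c(image_path, mask_path))
}

#' Pyramid construction parameters
#'
#' @param scale_factor nominal per-level downscale ratio in (0, 1).  The
#'   effective ratio is adjusted geometrically so the coarsest level lands
#'   exactly on `min_size` (the convention of the reference single-image GAN
#'   implementation).
#' @param min_size lower bound on the coarsest level's maximum dimension.
#' @param max_size cap applied to the input's maximum dimension before
#'   pyramid construction.
#' @return an object of class `pyramid_config`.
#' @export
pyramid_config <- function(scale_factor = 0.75, min_size = 25L,
                           max_size = 250L) {
  stopifnot(scale_factor > 0, scale_factor < 1,
            min_size > 0, min_size <= max_size)
  structure(list(scale_factor = scale_factor, min_size = as.integer(min_size),
                 max_size = as.integer(max_size)),
            class = "pyramid_config")
}

# re-binarize the mask channel of a model-domain grid at the midpoint
.rebinarize_mask <- function(grid) {
  grid[, , 4] <- ifelse(grid[, , 4] >= 0, 1, -1)
  grid
}

#' Build the multi-resolution pyramid of a four-channel sample
#'
#' The input is first capped so its maximum dimension does not exceed
#' `max_size`.  The number of levels is
#' `N = 1 + ceil(log(min_size / capped_max) / log(scale_factor))` and level
#' sizes follow the geometric schedule
#' `round(capped_dims * (min_size / capped_max)^((N - 1 - i) / (N - 1)))`,
#' so the finest level is the capped input exactly and the coarsest level's
#' maximum dimension is `min_size`.  All four channels are resized with
#' bilinear interpolation; the mask channel is re-binarized at the midpoint
#' after every resize.
#'
#' @param sample a [four_channel_sample()].
#' @param config a [pyramid_config()].
#' @return an object of class `image_pyramid`: list of levels (index 1 =
#'   coarsest) plus the config.
#' @export
build_pyramid <- function(sample, config = pyramid_config()) {
  stopifnot(inherits(sample, "four_channel_sample"),
            inherits(config, "pyramid_config"))
  d <- dim(sample$grid)[1:2]
  maxdim <- max(d)
  grid <- sample$grid
  if (maxdim > config$max_size) {
    r <- config$max_size / maxdim
    grid <- .rebinarize_mask(resize_bilinear(grid, max(1L, round(d[1] * r)),
                                             max(1L, round(d[2] * r))))
    d <- dim(grid)[1:2]
    maxdim <- max(d)
  }
  if (maxdim < config$min_size)
    stop("input max dimension ", maxdim, " is below min_size ",
         config$min_size)
  N <- if (maxdim == config$min_size) 1L else
    1L + as.integer(ceiling(log(config$min_size / maxdim) /
                            log(config$scale_factor)))
  levels <- vector("list", N)
  for (i in seq_len(N) - 1L) {
    r <- if (N == 1L) 1 else
      (config$min_size / maxdim)^((N - 1L - i) / (N - 1L))
    hw <- pmax(1L, round(d * r))
    lv <- if (i == N - 1L) grid else
      .rebinarize_mask(resize_bilinear(grid, hw[1], hw[2]))
    levels[[i + 1L]] <- four_channel_sample(lv, sample$provenance)
  }
  structure(list(levels = levels, config = config),
            class = "image_pyramid")
}

#' @export
print.image_pyramid <- function(x, ...) {
  sz <- vapply(x$levels, function(s) paste(dim(s$grid)[1:2], collapse = "x"),
               "")
  cat(sprintf("<image_pyramid> %d levels (coarse to fine): %s\n",
              length(sz), paste(sz, collapse = ", ")))
  invisible(x)
}
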