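# Procedural lesion-like fixtures: a textured background with an elliptical
# lesion region of distinct texture, plus the exact binary mask of that
# region.  These stand in for endoscopy image/mask pairs so that training,
# style transfer and metrics are exercisable without any external data.

#' Specification of a synthetic lesion sample
#'
#' @param size `c(H, W)` canvas size in pixels.
#' @param background one of `"perlin"` (multi-octave smooth noise),
#'   `"gradient"` (smooth ramps plus low-frequency sinusoids) or `"speckle"`
#'   (blurred white noise).
#' @param bg_scale texture scale parameter: approximate feature wavelength in
#'   pixels for the background texture.
#' @param center ellipse center `c(row, col)` in pixels; defaults to the
#'   canvas center.
#' @param axes ellipse semi-axes `c(a, b)` in pixels (must keep the ellipse
#'   fully inside the canvas).
#' @param rotation ellipse rotation in radians.
#' @param contrast lesion texture contrast in `[0, 1]`-ish units; 0 means the
#'   lesion is invisible in the RGB channels although the mask still marks
#'   it.
#' @param seed integer seed; the sample is deterministic per spec.
#' @return an object of class `toy_lesion_spec`.
#' @export
toy_lesion_spec <- function(size = c(64L, 64L), background = "perlin",
                            bg_scale = 16, center = NULL, axes = NULL,
                            rotation = 0, contrast = 0.6, seed = 1L) {
  size <- as.integer(size)
  if (length(size) == 1L) size <- c(size, size)
  if (is.null(center)) center <- (size + 1) / 2
  if (is.null(axes)) axes <- round(size / 5)
  stopifnot(all(size >= 8L), all(axes > 0), contrast >= 0,
            background %in% c("perlin", "gradient", "speckle"))
  # conservative bound: rotated ellipse fits in a disc of radius max(axes)
  if (center[1] - max(axes) < 1 || center[1] + max(axes) > size[1] ||
      center[2] - max(axes) < 1 || center[2] + max(axes) > size[2])
    stop("ellipse (center ", paste(round(center, 1), collapse = ","),
         ", axes ", paste(round(axes, 1), collapse = ","),
         ") does not fit inside a ", size[1], "x", size[2], " canvas")
  structure(list(size = size, background = background, bg_scale = bg_scale,
                 center = center, axes = axes, rotation = rotation,
                 contrast = contrast, seed = as.integer(seed)),
            class = "toy_lesion_spec")
}

# smooth random field: coarse iid noise upsampled bilinearly, one octave per
# halving of the wavelength
.texture_field <- function(h, w, wavelength, octaves = 3L) {
  out <- matrix(0, h, w)
  amp <- 1
  total <- 0
  for (o in seq_len(octaves)) {
    ch <- max(2L, ceiling(h / wavelength))
    cw <- max(2L, ceiling(w / wavelength))
    coarse <- matrix(stats::rnorm(ch * cw), ch, cw)
    out <- out + amp * resize_bilinear(coarse, h, w)
    total <- total + amp
    amp <- amp / 2
    wavelength <- max(2, wavelength / 2)
  }
  out / total
}

.background_texture <- function(kind, h, w, bg_scale) {
  switch(kind,
    perlin = .texture_field(h, w, bg_scale),
    gradient = {
      rr <- matrix(seq(-1, 1, length.out = h), h, w)
      cc <- matrix(seq(-1, 1, length.out = w), h, w, byrow = TRUE)
      a <- stats::runif(3, -1, 1)
      ph <- stats::runif(2, 0, 2 * pi)
      0.6 * (a[1] * rr + a[2] * cc) +
        0.4 * (sin(2 * pi * rr * h / (2 * bg_scale) + ph[1]) +
               sin(2 * pi * cc * w / (2 * bg_scale) + ph[2])) / 2 +
        0.2 * a[3]
    },
    speckle = {
      z <- matrix(stats::rnorm(h * w), h, w)
      k <- max(3L, round(bg_scale / 4))
      resize_bilinear(resize_bilinear(z, max(2L, h %/% k), max(2L, w %/% k)),
                      h, w)
    })
}

.ellipse_mask <- function(h, w, center, axes, rotation) {
  rr <- matrix(seq_len(h), h, w) - center[1]
  cc <- matrix(seq_len(w), h, w, byrow = TRUE) - center[2]
  u <- rr * cos(rotation) + cc * sin(rotation)
  v <- -rr * sin(rotation) + cc * cos(rotation)
  (u / axes[1])^2 + (v / axes[2])^2 <= 1
}

#' Generate one lesion-like four-channel sample
#'
#' The RGB channels hold a textured background with the elliptical lesion
#' region re-textured at the requested contrast (distinct hue and finer
#' texture); the mask channel is the exact ellipse indicator.
#'
#' @param spec a [toy_lesion_spec()].
#' @return a model-domain [four_channel_sample()].
#' @export
make_toy_sample <- function(spec) {
  stopifnot(inherits(spec, "toy_lesion_spec"))
  .with_seed(spec$seed, {
    h <- spec$size[1]; w <- spec$size[2]
    bg <- .background_texture(spec$background, h, w, spec$bg_scale)
    inside <- .ellipse_mask(h, w, spec$center, spec$axes, spec$rotation)
    lesion_tex <- .texture_field(h, w, max(3, spec$bg_scale / 3))
    # base tissue hue (pinkish) with per-channel modulation of the texture
    base <- c(0.35, 0.05, -0.05)
    chan_gain <- c(0.45, 0.35, 0.30)
    lesion_shift <- spec$contrast * c(0.25, -0.3, -0.15)
    img <- array(0, c(h, w, 3L))
    for (ch in 1:3) {
      plane <- base[ch] + chan_gain[ch] * bg
      plane[inside] <- plane[inside] + lesion_shift[ch] +
        spec$contrast * 0.5 * lesion_tex[inside]
      img[, , ch] <- .clamp(plane, -0.95, 0.95)
    }
    mask <- ifelse(inside, 1, -1)
    stack_four_channel(img, mask,
                       provenance = sprintf("toy-seed%d", spec$seed))
  })
}

#' Generate a dataset of lesion-like samples
#'
#' Lesion areas (as a percentage of the canvas) are drawn from a log-normal
#' distribution clipped to `[0.5, 60]` percent, giving the right-skewed
#' size distribution typical of clinical lesion datasets (many small lesions,
#' few large ones: median below mean).
#'
#' @param n number of samples.
#' @param size canvas size, `c(H, W)` or a single integer.
#' @param seed integer seed; the dataset is reproducible from `(n, size,
#'   seed)`.
#' @return list of `n` [four_channel_sample()] objects.
#' @export
make_toy_dataset <- function(n, size = c(64L, 64L), seed = 1L) {
  stopifnot(n >= 1L)
  size <- as.integer(size)
  if (length(size) == 1L) size <- c(size, size)
  .with_seed(seed, {
    specs <- lapply(seq_len(n), function(i) {
      pct <- min(60, max(0.5, exp(stats::rnorm(1, mean = log(8), sd = 0.8))))
      area <- pct / 100 * prod(size)
      ecc <- stats::runif(1, 0.5, 1)        # b/a ratio
      a <- sqrt(area / (pi * ecc))
      b <- a * ecc
      # keep the bounding disc inside the canvas
      amax <- (min(size) - 4) / 2
      if (a > amax) { a <- amax; b <- min(b, a) }
      margin <- a + 1.5
      ctr <- c(stats::runif(1, margin, size[1] - margin + 1),
               stats::runif(1, margin, size[2] - margin + 1))
      toy_lesion_spec(size = size,
                      background = sample(c("perlin", "gradient", "speckle"),
                                          1),
                      bg_scale = stats::runif(1, 8, 24),
                      center = ctr, axes = c(a, b),
                      rotation = stats::runif(1, 0, pi),
                      contrast = stats::runif(1, 0.4, 0.9),
                      seed = sample.int(2^30, 1))
    })
    lapply(specs, make_toy_sample)
  })
}
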