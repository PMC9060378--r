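# Neural style transfer refinement (pipeline step 2): optimize a third image
# to minimize a content distance D_C (feature-map MSE to the generated
# image) plus a style distance D_S (Gram-matrix MSE to the real image),
# weighted content_weight : style_weight.  Operates on RGB only; masks pass
# through untouched.

#' Construct a feature extractor for style transfer
#'
#' The `"test"` backend is a small convolutional network with fixed seeded
#' random weights and taps `conv1` ... `conv4`; it is fully deterministic,
#' needs no downloads, and is the default everywhere in this package.  A
#' classical ImageNet-pretrained VGG extractor (the configuration the
#' neural-style method is usually run with) cannot be bundled or downloaded
#' in an offline installation, so `backend = "pretrained"` signals an error
#' explaining that.
#'
#' @param backend `"test"` or `"pretrained"`.
#' @param seed seed fixing the test backend's weights.
#' @return an object of class `feature_extractor` with named taps.
#' @export
feature_extractor <- function(backend = c("test", "pretrained"), seed = 77L) {
  backend <- match.arg(backend)
  if (backend == "pretrained")
    stop("the pretrained VGG backend requires external ImageNet weights, ",
         "which are not bundled and cannot be downloaded here; ",
         "use backend = \"test\"")
  widths <- c(8L, 16L, 32L, 32L)
  cins <- c(3L, widths[-length(widths)])
  layers <- .with_seed(seed, lapply(seq_along(widths), function(i) {
    sd <- sqrt(2 / (9 * cins[i]))
    list(W = array(stats::rnorm(9 * cins[i] * widths[i], sd = sd),
                   c(3L, 3L, cins[i], widths[i])),
         b = numeric(widths[i]))
  }))
  structure(list(backend = backend, layers = layers, slope = 0.01,
                 taps = paste0("conv", seq_along(widths)),
                 pool_after = c(TRUE, TRUE, TRUE, FALSE)),
            class = "feature_extractor")
}

# forward with caches; returns tap activations (H x W x C each, post-lrelu)
.fx_forward <- function(fx, img) {
  n <- length(fx$layers)
  feats <- vector("list", n)
  cache <- vector("list", n)
  h <- img
  for (i in seq_len(n)) {
    xp <- .nn_pad(h, 1L)
    z <- .conv_forward(xp, fx$layers[[i]]$W, fx$layers[[i]]$b)
    m <- .lrelu_mask(z, fx$slope)
    a <- z * m
    feats[[i]] <- a
    cache[[i]] <- list(xp = xp, mask = m, in_dim = dim(h),
                       pooled = fx$pool_after[i])
    h <- if (fx$pool_after[i]) .avgpool2(a) else a
  }
  names(feats) <- fx$taps
  list(feats = feats, cache = cache)
}

# backward: tap_grads is a named list of gradients w.r.t. tap activations
.fx_backward <- function(fx, cache, tap_grads) {
  n <- length(fx$layers)
  d <- NULL
  for (i in rev(seq_len(n))) {
    if (is.null(d)) {
      d <- array(0, dim(cache[[i]]$mask))
    } else if (cache[[i]]$pooled) {
      d <- .avgpool2_grad(d, dim(cache[[i]]$mask))
    }
    tg <- tap_grads[[fx$taps[i]]]
    if (!is.null(tg)) d <- d + tg
    d <- d * cache[[i]]$mask
    d <- .conv_grad_x(fx$layers[[i]]$W, d)
    d <- .nn_unpad(d, 1L)
  }
  d
}

#' Extract named feature maps
#'
#' @param fx a [feature_extractor()].
#' @param img H x W x 3 model-domain RGB array (or a
#'   [four_channel_sample()], whose RGB channels are used).
#' @return named list of H' x W' x C feature arrays, one per tap.
#' @export
extract_features <- function(fx, img) {
  stopifnot(inherits(fx, "feature_extractor"))
  if (inherits(img, "four_channel_sample")) img <- split_four_channel(img)$img
  .fx_forward(fx, img)$feats
}

#' Gram matrix of a feature map
#'
#' For a feature map with C channels over H x W locations, returns
#' `G = F %*% t(F) / (C * H * W)` where `F` is the C x (H W) flattening:
#' the normalized channel co-activation matrix used as the style
#' representation.  Always symmetric positive semidefinite.
#'
#' @param features H x W x C feature array.
#' @return C x C matrix.
#' @export
gram_matrix <- function(features) {
  d <- dim(features)
  stopifnot(length(d) == 3L)
  F <- t(matrix(features, d[1] * d[2], d[3]))
  (F %*% t(F)) / prod(d)
}

#' Content and style distances
#'
#' `content_loss` is the MSE between feature maps summed over the content
#' layers; `style_loss` is the MSE between Gram matrices summed over the
#' style layers.
#'
#' @param x_features,ref_features named feature lists from
#'   [extract_features()] with matching taps.
#' @param layers character vector of tap names.
#' @return scalar loss.
#' @export
content_loss <- function(x_features, ref_features, layers) {
  if (!all(layers %in% names(x_features)) ||
      !all(layers %in% names(ref_features)))
    stop("unknown content layer(s): ",
         paste(setdiff(layers, names(x_features)), collapse = ", "))
  sum(vapply(layers, function(l)
    mean((x_features[[l]] - ref_features[[l]])^2), 0))
}

#' @rdname content_loss
#' @export
style_loss <- function(x_features, ref_features, layers) {
  if (!all(layers %in% names(x_features)) ||
      !all(layers %in% names(ref_features)))
    stop("unknown style layer(s): ",
         paste(setdiff(layers, names(x_features)), collapse = ", "))
  sum(vapply(layers, function(l)
    mean((gram_matrix(x_features[[l]]) - gram_matrix(ref_features[[l]]))^2),
    0))
}

#' Style transfer configuration
#'
#' The ratio semantics follow the usual reading of "content:style = 1:1000":
#' `content_weight = 1`, `style_weight = 1000`.
#'
#' @param content_weight,style_weight loss weights (non-negative, not both
#'   zero).
#' @param steps optimization steps (default 1000).
#' @param content_layers,style_layers extractor tap names.
#' @param init_mode start from the content image (default, preserves the
#'   structure the mask describes) or from noise.
#' @param backend feature extractor backend, see [feature_extractor()].
#' @param seed seed for the extractor weights and noise init.
#' @return an object of class `style_transfer_config`.
#' @export
style_transfer_config <- function(content_weight = 1, style_weight = 1000,
                                  steps = 1000L,
                                  content_layers = "conv3",
                                  style_layers = c("conv1", "conv2",
                                                   "conv3", "conv4"),
                                  init_mode = c("content", "noise"),
                                  backend = "test", seed = 77L) {
  init_mode <- match.arg(init_mode)
  stopifnot(content_weight >= 0, style_weight >= 0,
            content_weight + style_weight > 0, steps >= 1L)
  structure(list(content_weight = content_weight,
                 style_weight = style_weight, steps = as.integer(steps),
                 content_layers = content_layers, style_layers = style_layers,
                 init_mode = init_mode, backend = backend,
                 seed = as.integer(seed)),
            class = "style_transfer_config")
}

# total loss and gradient w.r.t. the image
.st_objective <- function(fx, x, cfeats, sgrams, cfg) {
  fw <- .fx_forward(fx, x)
  loss <- 0
  tap_grads <- list()
  for (l in cfg$content_layers) {
    diff <- fw$feats[[l]] - cfeats[[l]]
    loss <- loss + cfg$content_weight * mean(diff^2)
    g <- cfg$content_weight * 2 * diff / length(diff)
    tap_grads[[l]] <- if (is.null(tap_grads[[l]])) g else tap_grads[[l]] + g
  }
  for (l in cfg$style_layers) {
    feat <- fw$feats[[l]]
    d <- dim(feat)
    G <- gram_matrix(feat)
    dG <- cfg$style_weight * 2 * (G - sgrams[[l]]) / length(G)
    loss <- loss + cfg$style_weight * mean((G - sgrams[[l]])^2)
    F <- t(matrix(feat, d[1] * d[2], d[3]))
    dF <- (2 * dG %*% F) / prod(d)           # dG symmetric
    g <- array(t(dF), d)
    tap_grads[[l]] <- if (is.null(tap_grads[[l]])) g else tap_grads[[l]] + g
  }
  list(loss = loss, dx = .fx_backward(fx, fw$cache, tap_grads))
}

#' Run neural style transfer
#'
#' Minimizes `content_weight * D_C + style_weight * D_S` over the image with
#' a box-constrained quasi-Newton line-search optimizer (L-BFGS-B), one
#' outer iteration per recorded step, pixels clamped to `[-1, 1]`.  The
#' per-step total loss is attached as `attr(result, "loss_history")`.
#'
#' @param content H x W x 3 model-domain RGB array (content image).
#' @param style RGB array (style image); resized to the content size if it
#'   differs.
#' @param cfg a [style_transfer_config()].
#' @return optimized H x W x 3 RGB array.
#' @export
run_style_transfer <- function(content, style, cfg = style_transfer_config()) {
  stopifnot(inherits(cfg, "style_transfer_config"))
  if (inherits(content, "four_channel_sample"))
    content <- split_four_channel(content)$img
  if (inherits(style, "four_channel_sample"))
    style <- split_four_channel(style)$img
  d <- dim(content)
  stopifnot(length(d) == 3L, d[3] == 3L)
  if (!identical(dim(style), d))
    style <- resize_bilinear(style, d[1], d[2])
  fx <- feature_extractor(cfg$backend, seed = cfg$seed)
  cfeats <- .fx_forward(fx, content)$feats
  sgrams <- lapply(.fx_forward(fx, style)$feats[cfg$style_layers],
                   gram_matrix)
  x <- if (cfg$init_mode == "content") content else
    .with_seed(cfg$seed, array(stats::runif(length(content), -1, 1), d))

  fn <- function(par) {
    .st_objective(fx, array(par, d), cfeats, sgrams, cfg)$loss
  }
  gr <- function(par) {
    as.vector(.st_objective(fx, array(par, d), cfeats, sgrams, cfg)$dx)
  }
  par <- as.vector(x)
  history <- numeric(cfg$steps + 1L)
  history[1] <- fn(par)
  for (s in seq_len(cfg$steps)) {
    res <- stats::optim(par, fn, gr, method = "L-BFGS-B",
                        lower = -1, upper = 1,
                        control = list(maxit = 1L))
    if (!is.finite(res$value))
      stop("non-finite style transfer loss at step ", s)
    if (res$value > history[s]) {            # line search failed to improve
      history[(s + 1L):(cfg$steps + 1L)] <- history[s]
      break
    }
    par <- res$par
    history[s + 1L] <- res$value
    if (res$convergence == 0 && s < cfg$steps) {
      history[(s + 2L):(cfg$steps + 1L)] <- res$value
      break
    }
  }
  out <- array(par, d)
  attr(out, "loss_history") <- history
  out
}

#' Refine a generated sample by style transfer from its real source
#'
#' Replaces the RGB channels of `generated` with
#' `run_style_transfer(generated RGB, real RGB)`; the mask channel is passed
#' through bit-identically.
#'
#' @param generated,real paired [four_channel_sample()] objects.
#' @param cfg a [style_transfer_config()].
#' @return refined [four_channel_sample()].
#' @export
transfer_sample <- function(generated, real, cfg = style_transfer_config()) {
  stopifnot(inherits(generated, "four_channel_sample"),
            inherits(real, "four_channel_sample"))
  rgb <- run_style_transfer(split_four_channel(generated)$img,
                            split_four_channel(real)$img, cfg)
  out <- generated
  out$grid[, , 1:3] <- rgb
  out$provenance <- paste0(generated$provenance, "/st")
  attr(out, "loss_history") <- attr(rgb, "loss_history")
  out
}
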