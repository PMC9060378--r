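# The four-channel single-image GAN: per-scale generator/critic pairs trained
# coarse to fine on an image pyramid.  Each generator receives the upsampled
# output of the previous scale plus spatial noise and learns a residual; each
# critic is a Markovian (patch) critic trained with the Wasserstein objective
# and a gradient penalty.  The mask channel is treated exactly like a color
# channel in every loss.

#' Per-scale network architecture configuration
#'
#' @param n_blocks number of conv blocks per network (conv + leaky ReLU, the
#'   last block being the head).  Must be at least 3.
#' @param base_channels feature width at the coarsest scale; doubles every
#'   `channel_growth_every` scales, capped at 128.
#' @param kernel_size odd conv kernel size.
#' @param channel_growth_every number of scales between channel doublings.
#' @return an object of class `scale_model_config`.
#' @export
scale_model_config <- function(n_blocks = 5L, base_channels = 32L,
                               kernel_size = 3L, channel_growth_every = 4L) {
  stopifnot(n_blocks >= 3L, base_channels >= 8L,
            kernel_size %% 2L == 1L, channel_growth_every >= 1L)
  structure(list(n_blocks = as.integer(n_blocks),
                 base_channels = as.integer(base_channels),
                 kernel_size = as.integer(kernel_size),
                 channel_growth_every = as.integer(channel_growth_every)),
            class = "scale_model_config")
}

#' Training hyper-parameters
#'
#' Defaults follow the conventional single-image GAN recipe: 2000 epochs per
#' scale, three critic and three generator updates per epoch, Adam with
#' lr 5e-4 and betas (0.5, 0.999), and a reconstruction (alpha) weight of 10.
#' The gradient penalty weight defaults to 10, the canonical WGAN-GP value:
#' because the critic here carries no normalization layers, the weaker
#' penalty sometimes paired with batch-normalized critics under-constrains
#' it (see the methods vignette).  The learning rate is decayed by
#' `lr_decay_factor` once `lr_decay_frac` of the epochs have run.
#'
#' @param epochs_per_scale epochs per pyramid scale; one epoch is `d_steps`
#'   critic updates followed by `g_steps` generator updates on the single
#'   training image.
#' @param d_steps,g_steps updates per epoch.
#' @param lr_g,lr_d Adam learning rates.
#' @param beta1,beta2 Adam momenta.
#' @param gp_weight gradient penalty coefficient.
#' @param recon_weight reconstruction MSE coefficient (alpha).
#' @param noise_amp_base base noise amplitude used to scale the per-scale
#'   RMSE into the injected noise standard deviation.
#' @param lr_decay_frac,lr_decay_factor learning-rate schedule.
#' @param max_grad_norm clip threshold for the global L2 norm of each
#'   parameter-gradient update (both networks).  Adversarial gradients
#'   through the generator occasionally burst to 10-100x their typical norm
#'   (normalization layers amplify by 1/sd on near-constant channels, and a
#'   freshly updated critic can be locally steep); clipping the rare bursts
#'   leaves ordinary updates untouched.  `Inf` disables.
#' @param seed integer seed controlling all training randomness.
#' @return an object of class `train_config`.
#' @export
train_config <- function(epochs_per_scale = 2000L, d_steps = 3L, g_steps = 3L,
                         lr_g = 5e-4, lr_d = 5e-4, beta1 = 0.5, beta2 = 0.999,
                         gp_weight = 10, recon_weight = 10,
                         noise_amp_base = 0.1, lr_decay_frac = 0.8,
                         lr_decay_factor = 0.1, max_grad_norm = 50,
                         seed = 42L) {
  stopifnot(epochs_per_scale >= 1L, d_steps >= 1L, g_steps >= 1L,
            lr_g > 0, lr_d > 0, gp_weight >= 0, recon_weight >= 0,
            noise_amp_base > 0)
  structure(list(epochs_per_scale = as.integer(epochs_per_scale),
                 d_steps = as.integer(d_steps), g_steps = as.integer(g_steps),
                 lr_g = lr_g, lr_d = lr_d, beta1 = beta1, beta2 = beta2,
                 gp_weight = gp_weight, recon_weight = recon_weight,
                 noise_amp_base = noise_amp_base,
                 lr_decay_frac = lr_decay_frac,
                 lr_decay_factor = lr_decay_factor,
                 max_grad_norm = max_grad_norm,
                 seed = as.integer(seed)),
            class = "train_config")
}

.width_at_scale <- function(cfg, scale_index) {
  min(cfg$base_channels * 2L^(scale_index %/% cfg$channel_growth_every), 128L)
}

#' Initialize the generator/critic pair for one pyramid scale
#'
#' Both networks take 4-channel spatial input.  The generator ends in a
#' conv + tanh head (zero-initialized, so at initialization the generator is
#' the identity on its prior); the critic ends in a linear conv head whose
#' spatial mean is the critic value.  When the feature width at this scale
#' equals the width at the previous scale, weights are warm-started from the
#' previous scale's trained states; when the width grows they are
#' re-initialized randomly.
#'
#' @param scale_index 0-based scale index (0 = coarsest).
#' @param cfg a [scale_model_config()].
#' @param prev optional list(gen, disc) of the previous scale's trained nets.
#' @return list with elements `gen` and `disc`.
#' @export
init_scale_models <- function(scale_index, cfg = scale_model_config(),
                              prev = NULL) {
  width <- .width_at_scale(cfg, scale_index)
  warm <- !is.null(prev) && scale_index > 0L &&
    .width_at_scale(cfg, scale_index - 1L) == width
  if (warm) {
    prev_w <- dim(prev$gen$layers[[1]]$W)[4]
    if (prev_w != width) stop("warm start width mismatch: previous scale has ",
                              prev_w, " channels, expected ", width)
    return(list(gen = prev$gen, disc = prev$disc))
  }
  widths <- c(rep(width, cfg$n_blocks - 1L), 4L)
  gen <- .make_net(widths, cin = 4L, k = cfg$kernel_size, final = "tanh",
                   zero_head = TRUE, norm = TRUE)
  dwidths <- c(rep(width, cfg$n_blocks - 1L), 1L)
  disc <- .make_net(dwidths, cin = 4L, k = cfg$kernel_size, final = "linear",
                    norm = FALSE)
  list(gen = gen, disc = disc)
}

# generator application with caches for backprop.  The output clamp uses a
# straight-through gradient: a hard-zero gradient outside [-1, 1] would
# permanently freeze any pixel whose pre-clamp value overshoots the range
# (the loss could never pull it back), so the clamp is treated as the
# identity in the backward pass.
.gen_apply <- function(gen, noise, prior, sigma) {
  inp <- sigma * noise + prior
  fw <- .net_forward(gen, .nn_pad(inp, gen$pad))
  y <- .clamp(prior + fw$out)
  list(y = y, fw = fw)
}

.gen_backward <- function(gen, cache, dy) {
  .net_backward(gen, cache$fw, dy, need_dx = FALSE)$grads
}

#' Apply a per-scale generator
#'
#' Computes `clamp(prior + tanh(net(sigma * noise + prior)), -1, 1)`: the
#' network learns a residual on the upsampled previous-scale output, and the
#' result is squashed into the model domain.  With a zero-initialized head
#' the output equals the prior exactly.
#'
#' @param gen a generator network (from [init_scale_models()] or a trained
#'   checkpoint).
#' @param noise an H x W x 4 noise array.
#' @param prior an H x W x 4 prior (upsampled previous-scale output), or
#'   `NULL` for zeros (coarsest scale).
#' @param sigma scalar noise amplitude.
#' @return an H x W x 4 array with values in `[-1, 1]`.
#' @export
generator_forward <- function(gen, noise, prior = NULL, sigma = 1) {
  if (is.null(prior)) prior <- array(0, dim(noise))
  if (!identical(dim(noise), dim(prior)))
    stop("noise and prior shapes differ: ", paste(dim(noise), collapse = "x"),
         " vs ", paste(dim(prior), collapse = "x"))
  .gen_apply(gen, noise, prior, sigma)$y
}

# critic evaluation: spatial mean of the final linear conv map
.critic_apply <- function(disc, x) {
  fw <- .net_forward(disc, .nn_pad(x, disc$pad))
  list(value = mean(fw$out), fw = fw, n_out = length(fw$out))
}

# gradient penalty with parameter gradients; internal worker
.gp_full <- function(disc, real, fake, gp_weight, u = NULL, want_grads = TRUE) {
  if (!identical(dim(real), dim(fake))) stop("real/fake shape mismatch")
  if (is.null(u)) u <- stats::runif(1)
  xhat <- u * real + (1 - u) * fake
  ca <- .critic_apply(disc, xhat)
  bw <- .net_backward(disc, ca$fw, array(1 / ca$n_out, dim(ca$fw$out)),
                      need_dx = TRUE)
  g <- .nn_unpad(bw$dxp, disc$pad)
  gnorm <- sqrt(sum(g * g))
  value <- gp_weight * (gnorm - 1)^2
  grads <- NULL
  if (want_grads) {
    cc <- 2 * gp_weight * (gnorm - 1) / max(gnorm, 1e-12)
    grads <- .net_gp_param_grads(disc, ca$fw, bw$dzs, .nn_pad(cc * g, disc$pad))
  }
  list(value = value, grads = grads)
}

#' WGAN gradient penalty
#'
#' Evaluates `gp_weight * (||grad_x D(xhat)|| - 1)^2` at a random
#' interpolate `xhat = u * real + (1 - u) * fake`, `u ~ U(0, 1)`.
#'
#' @param disc a critic network.
#' @param real,fake 4-channel arrays of identical shape.
#' @param gp_weight penalty coefficient.
#' @param u optional fixed interpolation coefficient (tests); drawn uniformly
#'   when `NULL`.
#' @return scalar penalty value.
#' @export
gradient_penalty <- function(disc, real, fake, gp_weight = 10, u = NULL) {
  .gp_full(disc, real, fake, gp_weight, u = u, want_grads = FALSE)$value
}

#' Wasserstein critic and generator adversarial losses
#'
#' @inheritParams gradient_penalty
#' @return list with `d_loss = mean D(fake) - mean D(real) + penalty` and
#'   `g_adv_loss = -mean D(fake)`.
#' @export
critic_losses <- function(disc, real, fake, gp_weight = 10, u = NULL) {
  if (!identical(dim(real), dim(fake))) stop("real/fake shape mismatch")
  dr <- .critic_apply(disc, real)$value
  df <- .critic_apply(disc, fake)$value
  gp <- gradient_penalty(disc, real, fake, gp_weight, u = u)
  list(d_loss = df - dr + gp, g_adv_loss = -df)
}

#' Weighted reconstruction loss
#'
#' @param x,target 4-channel arrays of identical shape.
#' @param recon_weight loss coefficient (alpha).
#' @return `recon_weight * mean((x - target)^2)` over all four channels.
#' @export
reconstruction_loss <- function(x, target, recon_weight = 10) {
  if (!identical(dim(x), dim(target))) stop("shape mismatch")
  recon_weight * mean((x - target)^2)
}

#' Per-scale noise amplitude
#'
#' The amplitude of the noise injected at a scale is proportional to the RMSE
#' between the upsampled reconstruction from the scales below and the real
#' sample at this scale, so noise is added in proportion to the detail the
#' finer scale must invent.  The coarsest scale uses amplitude 1 by
#' convention.
#'
#' @param scale_index 0-based scale index.
#' @param recon_up upsampled reconstruction from the previous scales.
#' @param level the real 4-channel sample at this scale.
#' @param noise_amp_base base amplitude multiplier.
#' @return scalar amplitude.
#' @export
compute_noise_amplitude <- function(scale_index, recon_up, level,
                                    noise_amp_base = 0.1) {
  if (scale_index == 0L) return(1)
  if (!identical(dim(recon_up), dim(level))) stop("shape mismatch")
  noise_amp_base * sqrt(mean((recon_up - level)^2))
}

# noise draws: independent per channel at the coarsest scale, a single
# spatial channel broadcast across all four channels above it
.draw_noise <- function(h, w, coarsest) {
  if (coarsest) {
    array(stats::rnorm(h * w * 4L), c(h, w, 4L))
  } else {
    z <- matrix(stats::rnorm(h * w), h, w)
    array(rep(z, 4L), c(h, w, 4L))
  }
}

.zero_noise <- function(h, w) array(0, c(h, w, 4L))

# run the generator cascade over scales 0..upto (0-based).  Scales below
# start_scale follow the fixed reconstruction path (z_star at the coarsest,
# zero noise above); scales >= start_scale draw fresh noise.  RNG state is
# the caller's responsibility.
.gen_path <- function(gens, sigmas, z_star, sizes, start_scale = 0L,
                      upto = length(gens) - 1L) {
  y <- NULL
  for (i in 0L:upto) {
    h <- sizes[[i + 1L]][1]
    w <- sizes[[i + 1L]][2]
    noise <- if (i < start_scale) {
      if (i == 0L) z_star else .zero_noise(h, w)
    } else {
      .draw_noise(h, w, coarsest = (i == 0L))
    }
    prior <- if (i == 0L) .zero_noise(h, w) else resize_bilinear(y, h, w)
    y <- .gen_apply(gens[[i + 1L]], noise, prior, sigmas[i + 1L])$y
  }
  y
}

#' Train the full multi-scale GAN on one four-channel sample
#'
#' Trains scales coarse to fine.  At each scale, every epoch runs `d_steps`
#' critic updates (Wasserstein loss with gradient penalty, each on a freshly
#' generated fake) followed by `g_steps` generator updates (adversarial loss
#' plus weighted reconstruction loss on the fixed-noise path).  Finished
#' scales are frozen.  Per-scale noise amplitudes and the fixed coarsest
#' reconstruction noise `z_star` are recorded in the returned bundle.
#'
#' @param pyramid an [build_pyramid()] result.
#' @param scale_cfg a [scale_model_config()].
#' @param train_cfg a [train_config()].
#' @param keep_discs keep critic states in the bundle (needed only to resume
#'   or inspect training).
#' @param verbose print per-scale progress.
#' @return an object of class `checkpoint_bundle` with the trained
#'   generators, noise amplitudes, reconstruction noise, level sizes, the
#'   loss history (`$history`, one row per epoch) and the training sample.
#' @export
train_pyramid <- function(pyramid, scale_cfg = scale_model_config(),
                          train_cfg = train_config(), keep_discs = FALSE,
                          verbose = FALSE) {
  stopifnot(inherits(pyramid, "image_pyramid"))
  set.seed(train_cfg$seed)
  N <- length(pyramid$levels)
  sizes <- lapply(pyramid$levels, function(s) dim(s$grid)[1:2])
  gens <- vector("list", N)
  discs <- vector("list", N)
  sigmas <- numeric(N)
  z_star <- .draw_noise(sizes[[1]][1], sizes[[1]][2], coarsest = TRUE)
  recon_prev <- NULL
  hist_rows <- vector("list", N)

  for (i in seq_len(N) - 1L) {
    level <- pyramid$levels[[i + 1L]]$grid
    h <- sizes[[i + 1L]][1]; w <- sizes[[i + 1L]][2]
    prev <- if (i > 0L) list(gen = gens[[i]], disc = discs[[i]]) else NULL
    ms <- init_scale_models(i, scale_cfg, prev = prev)
    gen <- ms$gen; disc <- ms$disc
    prior_rec <- if (i == 0L) .zero_noise(h, w) else
      resize_bilinear(recon_prev, h, w)
    rec_noise <- if (i == 0L) z_star else .zero_noise(h, w)
    sigmas[i + 1L] <- compute_noise_amplitude(i, prior_rec, level,
                                              train_cfg$noise_amp_base)
    ad_g <- .adam_init(gen); ad_d <- .adam_init(disc)
    E <- train_cfg$epochs_per_scale
    decay_at <- ceiling(train_cfg$lr_decay_frac * E)
    ep_hist <- matrix(NA_real_, E, 3L)

    draw_inputs <- function() {
      prior <- if (i == 0L) .zero_noise(h, w) else
        resize_bilinear(.gen_path(gens, sigmas, z_star, sizes,
                                  start_scale = 0L, upto = i - 1L), h, w)
      noise <- .draw_noise(h, w, coarsest = (i == 0L))
      list(noise = noise, prior = prior)
    }

    for (epoch in seq_len(E)) {
      fac <- if (epoch > decay_at) train_cfg$lr_decay_factor else 1
      lr_d <- train_cfg$lr_d * fac
      lr_g <- train_cfg$lr_g * fac

      d_loss <- NA_real_
      for (s in seq_len(train_cfg$d_steps)) {
        inp <- draw_inputs()
        fake <- .gen_apply(gen, inp$noise, inp$prior, sigmas[i + 1L])$y
        cf <- .critic_apply(disc, fake)
        cr <- .critic_apply(disc, level)
        gp <- .gp_full(disc, level, fake, train_cfg$gp_weight)
        gr <- .net_backward(disc, cf$fw, array(1 / cf$n_out, dim(cf$fw$out)),
                            need_dx = FALSE)$grads
        gr <- .grads_axpy(gr, .net_backward(
          disc, cr$fw, array(-1 / cr$n_out, dim(cr$fw$out)),
          need_dx = FALSE)$grads)
        gr <- .grads_axpy(gr, gp$grads)
        gr <- .grads_clip(gr, train_cfg$max_grad_norm)
        up <- .adam_step(disc, gr, ad_d, lr_d, train_cfg$beta1,
                         train_cfg$beta2)
        disc <- up$net; ad_d <- up$state
        d_loss <- cf$value - cr$value + gp$value
      }

      # generator steps reuse the last critic step's noise and prior (the
      # reference convention), regenerating the fake as the weights move
      g_adv <- NA_real_; rec_mse <- NA_real_
      for (s in seq_len(train_cfg$g_steps)) {
        fk <- list(cache = .gen_apply(gen, inp$noise, inp$prior,
                                      sigmas[i + 1L]))
        cf <- .critic_apply(disc, fk$cache$y)
        dfake <- .nn_unpad(.net_backward(
          disc, cf$fw, array(-1 / cf$n_out, dim(cf$fw$out)),
          need_dx = TRUE)$dxp, disc$pad)
        gr <- .gen_backward(gen, fk$cache, dfake)
        rec <- .gen_apply(gen, rec_noise, prior_rec, sigmas[i + 1L])
        rec_mse <- mean((rec$y - level)^2)
        drec <- train_cfg$recon_weight * 2 * (rec$y - level) / length(level)
        gr <- .grads_axpy(gr, .gen_backward(gen, rec, drec))
        gr <- .grads_clip(gr, train_cfg$max_grad_norm)
        up <- .adam_step(gen, gr, ad_g, lr_g, train_cfg$beta1, train_cfg$beta2)
        gen <- up$net; ad_g <- up$state
        g_adv <- -cf$value
      }

      if (!is.finite(d_loss) || !is.finite(g_adv) || !is.finite(rec_mse))
        stop("non-finite loss at scale ", i, ", epoch ", epoch,
             " (d_loss=", d_loss, ", g_adv=", g_adv, ", recon=", rec_mse, ")")
      ep_hist[epoch, ] <- c(d_loss, g_adv, rec_mse)
    }

    gens[[i + 1L]] <- gen
    discs[[i + 1L]] <- disc
    recon_prev <- .gen_apply(gen, rec_noise, prior_rec, sigmas[i + 1L])$y
    hist_rows[[i + 1L]] <- data.frame(scale = i, epoch = seq_len(E),
                                      d_loss = ep_hist[, 1],
                                      g_adv_loss = ep_hist[, 2],
                                      recon_mse = ep_hist[, 3])
    if (verbose)
      message(sprintf("scale %d (%dx%d): d_loss=%.4f recon_mse=%.5f sigma=%.4f",
                      i, h, w, ep_hist[E, 1], ep_hist[E, 3], sigmas[i + 1L]))
  }

  structure(list(version = "segsynth-ckpt-1",
                 n_scales = N,
                 gens = gens,
                 discs = if (keep_discs) discs else NULL,
                 sigmas = sigmas,
                 z_star = z_star,
                 sizes = sizes,
                 pyramid_config = pyramid$config,
                 scale_cfg = scale_cfg,
                 train_cfg = train_cfg,
                 provenance = pyramid$levels[[N]]$provenance,
                 train_sample = pyramid$levels[[N]]$grid,
                 history = do.call(rbind, hist_rows)),
            class = "checkpoint_bundle")
}

#' @export
print.checkpoint_bundle <- function(x, ...) {
  finest <- x$sizes[[x$n_scales]]
  cat(sprintf("<checkpoint_bundle> %d scales, finest %dx%d, provenance '%s'\n",
              x$n_scales, finest[1], finest[2], x$provenance))
  invisible(x)
}

#' Save / load a checkpoint bundle
#'
#' A bundle is stored as a directory holding `meta.json` (scale sizes, noise
#' amplitudes, configs, format version), one `scale_<i>.rds` per scale with
#' the generator (and critic, if kept) states, `z_star.rds` with the fixed
#' reconstruction noise, and `history.csv` with the loss curves.  A reloaded
#' bundle regenerates bit-identical samples for identical seeds.
#'
#' @param bundle a `checkpoint_bundle`.
#' @param path directory to create/read.
#' @return `load_checkpoint` returns the bundle; `save_checkpoint` returns
#'   `path` invisibly.
#' @export
save_checkpoint <- function(bundle, path) {
  stopifnot(inherits(bundle, "checkpoint_bundle"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  meta <- list(version = bundle$version,
               n_scales = bundle$n_scales,
               sizes = lapply(bundle$sizes, as.integer),
               sigmas = bundle$sigmas,
               pyramid_config = unclass(bundle$pyramid_config),
               scale_cfg = unclass(bundle$scale_cfg),
               train_cfg = unclass(bundle$train_cfg),
               provenance = bundle$provenance,
               has_discs = !is.null(bundle$discs))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (i in seq_len(bundle$n_scales)) {
    saveRDS(list(gen = bundle$gens[[i]], disc = bundle$discs[[i]]),
            file.path(path, sprintf("scale_%03d.rds", i - 1L)))
  }
  # binary-exact numeric state (meta.json keeps a readable copy of sigmas)
  saveRDS(list(z_star = bundle$z_star, sigmas = bundle$sigmas,
               train_sample = bundle$train_sample),
          file.path(path, "aux.rds"))
  if (!is.null(bundle$history))
    utils::write.csv(bundle$history, file.path(path, "history.csv"),
                     row.names = FALSE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) stop("no checkpoint at ", path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(meta$version, "segsynth-ckpt-1"))
    stop("unsupported checkpoint version: ", meta$version)
  N <- meta$n_scales
  gens <- vector("list", N)
  discs <- vector("list", N)
  for (i in seq_len(N)) {
    f <- file.path(path, sprintf("scale_%03d.rds", i - 1L))
    if (!file.exists(f)) stop("checkpoint missing scale ", i - 1L, ": ", f)
    st <- readRDS(f)
    gens[[i]] <- st$gen
    discs[[i]] <- st$disc
  }
  aux_path <- file.path(path, "aux.rds")
  if (!file.exists(aux_path)) stop("checkpoint missing aux.rds: ", path)
  aux <- readRDS(aux_path)
  hist_path <- file.path(path, "history.csv")
  sizes <- if (is.matrix(meta$sizes)) {
    lapply(seq_len(nrow(meta$sizes)), function(i) as.integer(meta$sizes[i, ]))
  } else {
    lapply(meta$sizes, as.integer)
  }
  structure(list(version = meta$version,
                 n_scales = N,
                 gens = gens,
                 discs = if (isTRUE(meta$has_discs)) discs else NULL,
                 sigmas = aux$sigmas,
                 z_star = aux$z_star,
                 sizes = sizes,
                 pyramid_config = do.call(pyramid_config,
                                          as.list(meta$pyramid_config)),
                 scale_cfg = do.call(scale_model_config,
                                     as.list(meta$scale_cfg)),
                 train_cfg = do.call(train_config, as.list(meta$train_cfg)),
                 provenance = meta$provenance,
                 train_sample = aux$train_sample,
                 history = if (file.exists(hist_path))
                   utils::read.csv(hist_path) else NULL),
            class = "checkpoint_bundle")
}
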