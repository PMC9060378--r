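# Low-level numeric kernels for the conv nets used throughout the package.
#
# Tensors are plain R arrays with dim c(H, W, C) (row-major image convention:
# origin top-left, sizes reported as (height, width)).  Convolution weights
# are arrays dim c(k, k, Cin, Cout); valid convolutions are computed as an
# im2col gather followed by one BLAS matrix multiply.  The gather index
# matrices depend only on (H, W, C, k) and are cached per process.

.idx_cache <- new.env(parent = emptyenv())

.im2col_idx <- function(H, W, C, k) {
  key <- paste(H, W, C, k, sep = "x")
  idx <- .idx_cache[[key]]
  if (!is.null(idx)) return(idx)
  oh <- H - k + 1L
  ow <- W - k + 1L
  stopifnot(oh >= 1L, ow >= 1L)
  # linear index of the top-left corner of each patch (channel 1)
  pos0 <- as.vector(outer(seq_len(oh), (seq_len(ow) - 1L) * H, `+`))
  # offsets within a patch, ordered (dh, dw, c) with dh fastest -- the same
  # order in which a c(k, k, Cin, Cout) weight array flattens
  off <- as.vector(outer(
    as.vector(outer(seq_len(k) - 1L, (seq_len(k) - 1L) * H, `+`)),
    (seq_len(C) - 1L) * (H * W), `+`))
  idx <- outer(pos0, off, `+`)
  .idx_cache[[key]] <- idx
  idx
}

.nn_pad <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2L * p, d[2] + 2L * p, d[3]))
  out[(p + 1L):(p + d[1]), (p + 1L):(p + d[2]), ] <- x
  out
}

.nn_unpad <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  x[(p + 1L):(d[1] - p), (p + 1L):(d[2] - p), , drop = FALSE]
}

# valid cross-correlation: x (H,W,Cin), W (k,k,Cin,Cout) -> (H-k+1, W-k+1, Cout)
.conv_forward <- function(x, W, b = NULL) {
  d <- dim(x)
  k <- dim(W)[1]
  Cout <- dim(W)[4]
  idx <- .im2col_idx(d[1], d[2], d[3], k)
  P <- x[idx]
  dim(P) <- dim(idx)
  out <- P %*% matrix(W, ncol = Cout)
  if (!is.null(b)) out <- out + rep(b, each = nrow(out))
  dim(out) <- c(d[1] - k + 1L, d[2] - k + 1L, Cout)
  out
}

# gradient of sum(out * dout) w.r.t. the weights
.conv_grad_w <- function(x, dout, k) {
  d <- dim(x)
  Cout <- dim(dout)[3]
  idx <- .im2col_idx(d[1], d[2], d[3], k)
  P <- x[idx]
  dim(P) <- dim(idx)
  dW <- crossprod(P, matrix(dout, ncol = Cout))
  dim(dW) <- c(k, k, d[3], Cout)
  dW
}

# gradient w.r.t. the input: full conv of dout with the flipped, transposed
# kernel, expressed as another valid conv on a (k-1)-padded dout
.conv_grad_x <- function(W, dout) {
  k <- dim(W)[1]
  Wf <- W[k:1, k:1, , , drop = FALSE]
  Wf <- aperm(Wf, c(1L, 2L, 4L, 3L))
  .conv_forward(.nn_pad(dout, k - 1L), Wf)
}

.lrelu <- function(x, slope) {
  ifelse(x >= 0, x, slope * x)
}

.lrelu_mask <- function(x, slope) {
  m <- array(slope, dim(x))
  m[x >= 0] <- 1
  m
}

.clamp <- function(x, lo = -1, hi = 1) {
  pmin(pmax(x, lo), hi)
}

# -- bilinear resize ---------------------------------------------------------

.interp_cache <- new.env(parent = emptyenv())

# 1-D bilinear interpolation matrix (n_out x n_in), half-pixel-center mapping
.interp_matrix <- function(n_out, n_in) {
  key <- paste(n_out, n_in, sep = "to")
  M <- .interp_cache[[key]]
  if (!is.null(M)) return(M)
  M <- matrix(0, n_out, n_in)
  src <- (seq_len(n_out) - 0.5) * (n_in / n_out) - 0.5
  src <- pmin(pmax(src, 0), n_in - 1)
  i0 <- pmin(floor(src), n_in - 1)
  w <- src - i0
  i1 <- pmin(i0 + 1, n_in - 1)
  for (i in seq_len(n_out)) {
    M[i, i0[i] + 1] <- M[i, i0[i] + 1] + (1 - w[i])
    M[i, i1[i] + 1] <- M[i, i1[i] + 1] + w[i]
  }
  .interp_cache[[key]] <- M
  M
}

#' Bilinear resize
#'
#' Resizes a matrix or H x W x C array with bilinear interpolation using the
#' half-pixel-center convention (the same kernel used for pyramid
#' construction and inter-scale upsampling, so results are consistent
#' everywhere in the package).
#'
#' @param x matrix or 3-d array.
#' @param out_h,out_w output size.
#' @return resized matrix/array.
#' @export
resize_bilinear <- function(x, out_h, out_w) {
  two_d <- length(dim(x)) < 3L || is.null(dim(x))
  if (is.null(dim(x))) stop("resize_bilinear() expects a matrix or 3-d array")
  if (two_d) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  if (d[1] == out_h && d[2] == out_w) {
    if (two_d) dim(x) <- d[1:2]
    return(x)
  }
  Mr <- .interp_matrix(out_h, d[1])
  Mc <- .interp_matrix(out_w, d[2])
  out <- array(0, c(out_h, out_w, d[3]))
  for (c in seq_len(d[3])) out[, , c] <- Mr %*% x[, , c] %*% t(Mc)
  if (two_d) dim(out) <- c(out_h, out_w)
  out
}

# -- 2x2 average pooling (feature extractors) --------------------------------

.avgpool2 <- function(x) {
  d <- dim(x)
  oh <- d[1] %/% 2L
  ow <- d[2] %/% 2L
  x <- x[seq_len(2L * oh), seq_len(2L * ow), , drop = FALSE]
  0.25 * (x[seq(1L, 2L * oh, 2L), seq(1L, 2L * ow, 2L), , drop = FALSE] +
          x[seq(2L, 2L * oh, 2L), seq(1L, 2L * ow, 2L), , drop = FALSE] +
          x[seq(1L, 2L * oh, 2L), seq(2L, 2L * ow, 2L), , drop = FALSE] +
          x[seq(2L, 2L * oh, 2L), seq(2L, 2L * ow, 2L), , drop = FALSE])
}

.avgpool2_grad <- function(dout, in_dim) {
  d <- dim(dout)
  dx <- array(0, in_dim)
  g <- 0.25 * dout
  dx[seq(1L, 2L * d[1], 2L), seq(1L, 2L * d[2], 2L), ] <- g
  dx[seq(2L, 2L * d[1], 2L), seq(1L, 2L * d[2], 2L), ] <- g
  dx[seq(1L, 2L * d[1], 2L), seq(2L, 2L * d[2], 2L), ] <- g
  dx[seq(2L, 2L * d[1], 2L), seq(2L, 2L * d[2], 2L), ] <- g
  dx
}

# -- networks ----------------------------------------------------------------

# A net is list(layers = list(list(W, b), ...), kernel, pad, slope, final)
# where final is "tanh" (generator head) or "linear" (critic head).  The
# input is zero-padded once by pad = n_layers*(k-1)/2 and every conv is
# valid, so the output spatial size equals the input size.

.make_net <- function(widths, cin, k, slope = 0.2, final = c("linear", "tanh"),
                      init_sd = 0.02, zero_head = FALSE, norm = FALSE) {
  final <- match.arg(final)
  n <- length(widths)
  layers <- vector("list", n)
  cprev <- cin
  for (i in seq_len(n)) {
    W <- array(stats::rnorm(k * k * cprev * widths[i], sd = init_sd),
               c(k, k, cprev, widths[i]))
    b <- numeric(widths[i])
    if (zero_head && i == n) W[] <- 0
    layers[[i]] <- list(W = W, b = b)
    if (norm && i < n) {
      layers[[i]]$g <- rep(1, widths[i])
      layers[[i]]$bt <- numeric(widths[i])
    }
    cprev <- widths[i]
  }
  list(layers = layers, kernel = as.integer(k),
       pad = as.integer(n * (k - 1L) / 2L), slope = slope, final = final,
       norm = norm)
}

# per-channel normalization over the spatial dims (batch-of-one batch norm,
# i.e. instance norm); statistics are always the current input's, so the
# operation is deterministic
.norm_forward <- function(z, g, bt, eps = 1e-5) {
  d <- dim(z)
  zm <- matrix(z, ncol = d[3])
  mu <- colMeans(zm)
  v <- colMeans(zm * zm) - mu * mu
  s <- sqrt(v + eps)
  zn <- (zm - rep(mu, each = nrow(zm))) / rep(s, each = nrow(zm))
  out <- zn * rep(g, each = nrow(zm)) + rep(bt, each = nrow(zm))
  dim(out) <- d
  list(out = out, zn = zn, s = s)
}

.norm_backward <- function(dout, cache, g) {
  d <- dim(dout)
  dm <- matrix(dout, ncol = d[3])
  zn <- cache$zn
  dg <- colSums(dm * zn)
  dbt <- colSums(dm)
  dzn <- dm * rep(g, each = nrow(dm))
  m <- nrow(dm)
  dz <- (dzn - rep(colMeans(dzn), each = m) -
         zn * rep(colMeans(dzn * zn), each = m)) / rep(cache$s, each = m)
  dim(dz) <- d
  list(dz = dz, dg = dg, dbt = dbt)
}

# forward pass over a pre-padded input; returns output plus per-layer caches
.net_forward <- function(net, xp) {
  n <- length(net$layers)
  ain <- vector("list", n)   # input to each conv
  mask <- vector("list", n)  # lrelu derivative masks (NULL for head)
  ncache <- vector("list", n)
  h <- xp
  for (i in seq_len(n)) {
    ain[[i]] <- h
    z <- .conv_forward(h, net$layers[[i]]$W, net$layers[[i]]$b)
    if (i < n) {
      if (!is.null(net$layers[[i]]$g)) {
        nf <- .norm_forward(z, net$layers[[i]]$g, net$layers[[i]]$bt)
        ncache[[i]] <- nf
        z <- nf$out
      }
      mask[[i]] <- .lrelu_mask(z, net$slope)
      h <- z * mask[[i]]
    } else {
      h <- if (net$final == "tanh") tanh(z) else z
    }
  }
  list(out = h, ain = ain, mask = mask, ncache = ncache)
}

# backward pass: dout has the shape of out; returns parameter gradients, the
# gradient w.r.t. the (unpadded) input, and the per-layer upstream signals
# dz (needed by the gradient-penalty double-backward).
.net_backward <- function(net, cache, dout, need_dx = TRUE) {
  n <- length(net$layers)
  k <- net$kernel
  grads <- vector("list", n)
  dzs <- vector("list", n)
  d <- dout
  if (net$final == "tanh") d <- d * (1 - cache$out^2)
  for (i in rev(seq_len(n))) {
    if (i < n) d <- d * cache$mask[[i]]
    g <- NULL
    if (i < n && !is.null(net$layers[[i]]$g)) {
      nb <- .norm_backward(d, cache$ncache[[i]], net$layers[[i]]$g)
      d <- nb$dz
      g <- list(g = nb$dg, bt = nb$dbt)
    }
    dzs[[i]] <- d
    grads[[i]] <- c(list(
      W = .conv_grad_w(cache$ain[[i]], d, k),
      b = colSums(matrix(d, ncol = dim(d)[3]))), g)
    if (i > 1L || need_dx) d <- .conv_grad_x(net$layers[[i]]$W, d)
  }
  dxp <- if (need_dx) d else NULL
  list(grads = grads, dxp = dxp, dzs = dzs)
}

# Gradient-penalty double-backward.  The critic is piecewise linear in its
# input (convs + leaky ReLU, linear head), so with the activation pattern
# held fixed the map x -> grad_x D(x) is linear and the exact parameter
# gradient of s = <grad_x D, v> is obtained from one tangent forward pass of
# v through the mask-linearized network paired with the primal upstream
# signals dzs: dW_i = conv_grad_w(h_{i-1}, dz_i), db_i = 0.
.net_gp_param_grads <- function(net, cache, dzs, vp) {
  if (isTRUE(net$norm))
    stop("gradient-penalty double-backward requires a norm-free critic")
  n <- length(net$layers)
  k <- net$kernel
  grads <- vector("list", n)
  h <- vp
  for (i in seq_len(n)) {
    grads[[i]] <- list(
      W = .conv_grad_w(h, dzs[[i]], k),
      b = numeric(length(net$layers[[i]]$b)))
    if (i < n) {
      h <- .conv_forward(h, net$layers[[i]]$W)
      h <- h * cache$mask[[i]]
    }
  }
  grads
}

# -- parameter-list arithmetic and Adam --------------------------------------

.param_names <- function(layer) intersect(c("W", "b", "g", "bt"), names(layer))

.grads_zero <- function(net) {
  lapply(net$layers, function(l) {
    out <- list(W = array(0, dim(l$W)), b = numeric(length(l$b)))
    if (!is.null(l$g)) { out$g <- numeric(length(l$g)); out$bt <- out$g }
    out
  })
}

.grads_axpy <- function(acc, g, a = 1) {
  for (i in seq_along(acc)) {
    for (p in names(acc[[i]])) {
      gp <- g[[i]][[p]]
      if (!is.null(gp)) acc[[i]][[p]] <- acc[[i]][[p]] + a * gp
    }
  }
  acc
}

# rescale a gradient set so its global L2 norm is at most max_norm
.grads_clip <- function(grads, max_norm) {
  if (!is.finite(max_norm)) return(grads)
  total <- sum(vapply(grads, function(l)
    sum(vapply(l, function(p) sum(p * p), 0)), 0))
  n <- sqrt(total)
  if (n <= max_norm) return(grads)
  sc <- max_norm / n
  lapply(grads, function(l) lapply(l, function(p) p * sc))
}

.adam_init <- function(net) {
  list(t = 0L,
       m = .grads_zero(net),
       v = .grads_zero(net))
}

.adam_step <- function(net, grads, st, lr, beta1, beta2, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (i in seq_along(net$layers)) {
    for (p in .param_names(net$layers[[i]])) {
      g <- grads[[i]][[p]]
      st$m[[i]][[p]] <- beta1 * st$m[[i]][[p]] + (1 - beta1) * g
      st$v[[i]][[p]] <- beta2 * st$v[[i]][[p]] + (1 - beta2) * g * g
      net$layers[[i]][[p]] <- net$layers[[i]][[p]] -
        lr * (st$m[[i]][[p]] / bc1) / (sqrt(st$v[[i]][[p]] / bc2) + eps)
    }
  }
  list(net = net, state = st)
}

# run code under a temporary RNG state without clobbering the caller's
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}
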