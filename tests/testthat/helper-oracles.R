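# Independent oracles, deliberately coded along different routes than the
# package implementation.

# direct quadruple-loop valid cross-correlation (vs the im2col path)
naive_conv <- function(x, W, b) {
  d <- dim(x); k <- dim(W)[1]; Cout <- dim(W)[4]
  oh <- d[1] - k + 1L; ow <- d[2] - k + 1L
  out <- array(0, c(oh, ow, Cout))
  for (co in seq_len(Cout)) {
    for (i in seq_len(oh)) for (j in seq_len(ow)) {
      acc <- b[co]
      for (ci in seq_len(d[3]))
        acc <- acc + sum(x[i:(i + k - 1L), j:(j + k - 1L), ci] *
                         W[, , ci, co])
      out[i, j, co] <- acc
    }
  }
  out
}

# critic value by the naive route: zero-pad once, valid convs, leaky relu,
# spatial mean of the linear head
naive_critic_value <- function(disc, x) {
  p <- disc$pad
  d <- dim(x)
  xp <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3]))
  xp[(p + 1):(p + d[1]), (p + 1):(p + d[2]), ] <- x
  n <- length(disc$layers)
  h <- xp
  for (i in seq_len(n)) {
    z <- naive_conv(h, disc$layers[[i]]$W, disc$layers[[i]]$b)
    h <- if (i < n) ifelse(z >= 0, z, disc$slope * z) else z
  }
  mean(h)
}

# gradient norm of the critic at x by central finite differences of the fast
# forward pass (independent of the analytic backward pass under test)
fd_critic_grad_norm <- function(disc, x, h = 1e-5) {
  g <- array(0, dim(x))
  for (j in seq_along(x)) {
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    g[j] <- (segsynth:::.critic_apply(disc, xp)$value -
             segsynth:::.critic_apply(disc, xm)$value) / (2 * h)
  }
  sqrt(sum(g * g))
}

# WGAN-GP losses assembled entirely from the naive critic + FD gradient
oracle_critic_losses <- function(disc, real, fake, gp_weight, u) {
  xhat <- u * real + (1 - u) * fake
  gn <- fd_critic_grad_norm(disc, xhat)
  df <- naive_critic_value(disc, fake)
  dr <- naive_critic_value(disc, real)
  list(d_loss = df - dr + gp_weight * (gn - 1)^2, g_adv_loss = -df)
}

# matrix square root by Denman-Beavers iteration (works on the possibly
# non-symmetric product Ca %*% Cb directly, unlike the eigen route)
db_sqrtm <- function(A, iters = 60) {
  Y <- A; Z <- diag(nrow(A))
  for (i in seq_len(iters)) {
    Yn <- 0.5 * (Y + solve(Z))
    Zn <- 0.5 * (Z + solve(Y))
    Y <- Yn; Z <- Zn
  }
  Y
}

oracle_frechet <- function(a, b) {
  sum((a$mu - b$mu)^2) + sum(diag(a$cov)) + sum(diag(b$cov)) -
    2 * sum(diag(db_sqrtm(a$cov %*% b$cov)))
}

random_psd <- function(d, jitter = 0.1) {
  M <- matrix(rnorm(d * d), d, d)
  M %*% t(M) / d + jitter * diag(d)
}

# a one-conv critic computing w0 * mean-over-map of the channel sum, whose
# input gradient norm is exactly w0 * sqrt(C / (H * W))
linear_critic <- function(w0) {
  W <- array(w0, c(1L, 1L, 4L, 1L))
  list(layers = list(list(W = W, b = 0)), kernel = 1L, pad = 0L,
       slope = 0.2, final = "linear", norm = FALSE)
}
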