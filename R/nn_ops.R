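# Neural-network primitives on (H, W, C, N) arrays.  Convolution lives in
# src/dms_ops.cpp; everything else is cheap enough in vectorized R.

conv2d_forward <- function(x, w, b) .conv2d_fwd_cpp(x, w, b)

# Forward that also returns the gathered patch matrix (external pointer) so
# the backward pass can skip re-gathering.
conv2d_forward_keep <- function(x, w, b) .conv2d_fwd_keep_cpp(x, w, b)

conv2d_backward <- function(cache, w, dy, need_dx = TRUE)
  .conv2d_bwd_cpp(cache, w, dy, need_dx)

# Broadcast a per-channel vector over an (H, W, C, N) array.
bc_channel <- function(v, d) rep(rep(v, each = d[1] * d[2]), times = d[4])

# Per-channel sum of an (H, W, C, N) array -> length-C vector.
channel_sum <- function(a, d) .chan_sums_cpp(a, NULL)[, 1]

# Instance normalization: each (channel, sample) plane is standardized over
# its spatial extent, then scaled/shifted by per-channel gamma/beta.  Unlike
# batch normalization there is no batch coupling and no running state, so
# training and inference are the same deterministic function - the right
# trade-off for CPU-scale batch sizes, where batch statistics degenerate.
# Internally the (H, W, C, N) array is viewed as (H, W, C*N, 1) so the
# per-channel C++ kernels do per-plane work.
instnorm_forward <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x)
  hw <- d[1] * d[2]
  cn <- d[3] * d[4]
  xv <- x
  dim(xv) <- c(d[1], d[2], cn, 1L)
  s <- .chan_sums_cpp(xv, xv)
  mu <- s[, 1] / hw
  invstd <- 1 / sqrt(pmax(s[, 2] / hw - mu^2, 0) + eps)
  xhat <- .chan_affine_cpp(xv, invstd, -mu * invstd)
  y <- .chan_affine_cpp(xhat, rep(gamma, d[4]), rep(beta, d[4]))
  dim(y) <- d
  list(y = y, cache = list(xhat = xhat, invstd = invstd, gamma = gamma,
                           d = d))
}

instnorm_backward <- function(dy, cache) {
  d <- cache$d
  hw <- d[1] * d[2]
  cn <- d[3] * d[4]
  xhat <- cache$xhat                       # (H, W, C*N, 1) view
  dyv <- dy
  dim(dyv) <- c(d[1], d[2], cn, 1L)
  s <- .chan_sums_cpp(dyv, xhat)
  dbeta_cn <- s[, 1]
  dgamma_cn <- s[, 2]
  gi <- rep(cache$gamma, d[4]) * cache$invstd
  dx <- .chan_affine_cpp(dyv, gi, -gi * dbeta_cn / hw) +
    .chan_affine_cpp(xhat, -gi * dgamma_cn / hw, numeric(cn))
  dim(dx) <- d
  list(dx = dx,
       dgamma = .rowSums(matrix(dgamma_cn, d[3], d[4]), d[3], d[4]),
       dbeta = .rowSums(matrix(dbeta_cn, d[3], d[4]), d[3], d[4]))
}

# Gradient with respect to the *input* of instance norm, holding gamma/beta
# fixed (used by gradient-weighted CAM).
instnorm_input_grad <- function(dy, cache) instnorm_backward(dy, cache)$dx

relu_forward <- function(x) {
  mask <- x > 0
  y <- x * mask
  list(y = y, mask = mask)
}

relu_backward <- function(dy, mask) dy * mask

# 2x2 average pooling, stride 2; spatial dims must be even.
avgpool2_forward <- function(x) {
  d <- dim(x)
  oi <- seq.int(1L, d[1], 2L); oj <- seq.int(1L, d[2], 2L)
  y <- (x[oi, oj, , , drop = FALSE] + x[oi + 1L, oj, , , drop = FALSE] +
          x[oi, oj + 1L, , , drop = FALSE] + x[oi + 1L, oj + 1L, , , drop = FALSE]) / 4
  y
}

avgpool2_backward <- function(dy, in_dim) {
  dx <- array(0, in_dim)
  oi <- seq.int(1L, in_dim[1], 2L); oj <- seq.int(1L, in_dim[2], 2L)
  g <- dy / 4
  dx[oi, oj, , ] <- g
  dx[oi + 1L, oj, , ] <- g
  dx[oi, oj + 1L, , ] <- g
  dx[oi + 1L, oj + 1L, , ] <- g
  dx
}

# Global average pooling: (H, W, C, N) -> (C, N).
gap_forward <- function(x) {
  d <- dim(x)
  matrix(.colMeans(x, d[1] * d[2], d[3] * d[4]), d[3], d[4])
}

gap_backward <- function(dy, in_dim) {
  # dy: (C, N) -> spread evenly over H*W
  hw <- in_dim[1] * in_dim[2]
  dx <- array(rep(as.vector(dy), each = hw) / hw, in_dim)
  dx
}

# Linear head: feat (C, N), W (K, C), b (K) -> logits (N, K).
linear_forward <- function(feat, w, b) t(w %*% feat + b)

linear_backward <- function(dlogits, feat, w) {
  # dlogits: (N, K)
  dl <- t(dlogits)                      # (K, N)
  list(dfeat = t(w) %*% dl,             # (C, N)
       dw = dl %*% t(feat),             # (K, C)
       db = .rowSums(dl, nrow(dl), ncol(dl)))
}

softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  e / .rowSums(e, nrow(e), ncol(e))
}

# Mean cross-entropy over the batch; labels are 0-based grades.
# Returns loss and d(loss)/d(logits).
softmax_xent <- function(logits, labels) {
  n <- nrow(logits)
  p <- softmax_rows(logits)
  ix <- cbind(seq_len(n), labels + 1L)
  loss <- -mean(log(pmax(p[ix], 1e-12)))
  dlogits <- p
  dlogits[ix] <- dlogits[ix] - 1
  list(loss = loss, dlogits = dlogits / n, probs = p)
}

# Concatenate (H, W, C, N) arrays along the channel axis.
concat_channels <- function(lst) {
  if (length(lst) == 1L) return(lst[[1L]])
  d1 <- dim(lst[[1L]])
  cs <- vapply(lst, function(a) dim(a)[3], integer(1))
  out <- array(0, c(d1[1], d1[2], sum(cs), d1[4]))
  at <- 0L
  for (a in lst) {
    ca <- dim(a)[3]
    out[, , at + seq_len(ca), ] <- a
    at <- at + ca
  }
  out
}

# Split a channel gradient back into per-source slices of widths `widths`.
split_channels <- function(a, widths) {
  out <- vector("list", length(widths))
  at <- 0L
  for (i in seq_along(widths)) {
    out[[i]] <- a[, , at + seq_len(widths[i]), , drop = FALSE]
    at <- at + widths[i]
  }
  out
}

# ---- Adam ----------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0), v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}

# SGD with momentum, the config-overridable alternative optimizer.
sgd_init <- function(params) {
  list(m = lapply(params, function(p) p * 0))
}

sgd_step <- function(params, grads, opt, lr, momentum = 0.9) {
  for (nm in names(params)) {
    opt$m[[nm]] <- momentum * opt$m[[nm]] + grads[[nm]]
    params[[nm]] <- params[[nm]] - lr * opt$m[[nm]]
  }
  list(params = params, opt = opt)
}

# Global-norm gradient clipping.
clip_gradients <- function(grads, max_norm) {
  if (is.null(max_norm) || !is.finite(max_norm)) return(grads)
  total <- sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
  if (total > max_norm && total > 0) {
    s <- max_norm / total
    grads <- lapply(grads, function(g) g * s)
  }
  grads
}
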