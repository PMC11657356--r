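#' DMS architecture configuration
#'
#' All hyperparameters of the Dense Multi-Scale network.  Every layer runs
#' one convolution branch per kernel scale (default 1x1, 3x3, 5x5), each
#' emitting `growth_rate` channels, on the concatenation of the block input
#' and all previous layer outputs (dense connectivity).  Blocks are joined by
#' transitions (1x1 compression + 2x spatial downsampling); the dense block
#' output concatenates its input, which carries reuse across blocks.
#'
#' @param scales odd positive kernel sizes (default `c(1, 3, 5)`).
#' @param growth_rate channels per scale branch per layer (default 12).
#' @param layers_per_block layers L in each dense block (default 4).
#' @param num_blocks number of dense blocks B (default 3).
#' @param stem_channels channels of the 3x3 stem convolution (default 24).
#' @param compression transition channel-compression factor in `(0, 1]`
#'   (default 0.5).
#' @param num_classes output classes (default 5, the KL grades).
#' @param input_size square input side in pixels (default 224); must be
#'   divisible by `2^(num_blocks - 1)`.
#' @return an object of class `dms_config`.
#' @export
dms_config <- function(scales = c(1L, 3L, 5L), growth_rate = 12L,
                       layers_per_block = 4L, num_blocks = 3L,
                       stem_channels = 24L, compression = 0.5,
                       num_classes = 5L, input_size = 224L) {
  stop_if(length(scales) < 1L || any(scales < 1) || any(scales %% 2 != 1),
          "scales must be odd positive integers")
  check_number(growth_rate, "growth_rate", lower = 1, integer = TRUE)
  check_number(layers_per_block, "layers_per_block", lower = 1, integer = TRUE)
  check_number(num_blocks, "num_blocks", lower = 1, integer = TRUE)
  check_number(stem_channels, "stem_channels", lower = 1, integer = TRUE)
  check_number(compression, "compression", lower = 0, upper = 1,
               strict_lower = TRUE)
  check_number(num_classes, "num_classes", lower = 2, integer = TRUE)
  check_number(input_size, "input_size", lower = 1, integer = TRUE)
  down <- 2^(num_blocks - 1)
  stop_if(input_size %% down != 0 || input_size / down < 1,
          sprintf("input_size must be divisible by %d (one 2x downsampling per transition)", down))
  structure(list(scales = as.integer(scales), growth_rate = as.integer(growth_rate),
                 layers_per_block = as.integer(layers_per_block),
                 num_blocks = as.integer(num_blocks),
                 stem_channels = as.integer(stem_channels),
                 compression = as.numeric(compression),
                 num_classes = as.integer(num_classes),
                 input_size = as.integer(input_size)),
            class = "dms_config")
}

# Channel width entering each block (after the preceding transition, if any).
block_in_channels <- function(cfg) {
  gS <- cfg$growth_rate * length(cfg$scales)
  cin <- integer(cfg$num_blocks)
  c_now <- cfg$stem_channels
  for (b in seq_len(cfg$num_blocks)) {
    cin[b] <- c_now
    c_out <- c_now + cfg$layers_per_block * gS
    c_now <- if (b < cfg$num_blocks) max(1L, floor(cfg$compression * c_out)) else c_out
  }
  cin
}

#' Input channel width of a dense layer (closed form)
#'
#' `c_block_in + layer * growth_rate * |scales|` for 0-based `block` and
#' `layer` indices; a pure function used as the bookkeeping oracle for the
#' built network.
#'
#' @param cfg a [dms_config()].
#' @param block 0-based block index (`0 <= block < num_blocks`).
#' @param layer 0-based layer index within the block
#'   (`0 <= layer < layers_per_block`).
#' @return integer channel count.
#' @export
dms_layer_in_channels <- function(cfg, block, layer) {
  stop_if(!inherits(cfg, "dms_config"), "cfg must be a dms_config")
  check_number(block, "block", lower = 0, integer = TRUE)
  check_number(layer, "layer", lower = 0, integer = TRUE)
  stop_if(block >= cfg$num_blocks, "block index out of range")
  stop_if(layer >= cfg$layers_per_block, "layer index out of range")
  cin <- block_in_channels(cfg)
  as.integer(cin[block + 1L] + layer * cfg$growth_rate * length(cfg$scales))
}

#' Specification of one dense block
#'
#' Pure channel bookkeeping for a block with a given input width; no weights
#' are created.  Layer `l` consumes `in_channels + l * growth_rate * |scales|`
#' channels and emits `growth_rate * |scales|`; the block output concatenates
#' the block input with every layer output.
#'
#' @param cfg a [dms_config()].
#' @param in_channels channel width entering the block.
#' @return list with per-layer in/out widths and the block's `out_channels`.
#' @export
build_dms_block <- function(cfg, in_channels) {
  stop_if(!inherits(cfg, "dms_config"), "cfg must be a dms_config")
  check_number(in_channels, "in_channels", lower = 1, integer = TRUE)
  gS <- cfg$growth_rate * length(cfg$scales)
  layers <- lapply(seq_len(cfg$layers_per_block) - 1L, function(l) {
    list(layer_index = l,
         in_channels = as.integer(in_channels + l * gS),
         out_channels_per_scale = cfg$growth_rate,
         concat_out_channels = as.integer(gS))
  })
  list(in_channels = as.integer(in_channels), layers = layers,
       out_channels = as.integer(in_channels + cfg$layers_per_block * gS))
}

# Closed-form trainable-parameter accounting.  Per dense layer: one instance
# norm on the concatenated input (2 * in_ch affine parameters) plus, per
# scale k, a k x k convolution (in_ch * g * k^2 weights + g biases).
# Transitions and the head carry their own norm.
dms_model_summary <- function(cfg) {
  gS <- cfg$growth_rate * length(cfg$scales)
  cin <- block_in_channels(cfg)
  specs <- list()
  total <- 3 * 3 * 1 * cfg$stem_channels + cfg$stem_channels   # stem conv
  for (b in seq_len(cfg$num_blocks)) {
    for (l in seq_len(cfg$layers_per_block)) {
      in_ch <- cin[b] + (l - 1L) * gS
      p <- 2L * in_ch +
        sum(vapply(cfg$scales, function(k) k * k * in_ch * cfg$growth_rate +
                     cfg$growth_rate, numeric(1)))
      specs[[length(specs) + 1L]] <- list(
        block_index = b - 1L, layer_index = l - 1L,
        in_channels = as.integer(in_ch),
        out_channels_per_scale = cfg$growth_rate,
        concat_out_channels = as.integer(gS), n_params = as.integer(p))
      total <- total + p
    }
    c_out <- cin[b] + cfg$layers_per_block * gS
    if (b < cfg$num_blocks) {
      c_next <- max(1L, floor(cfg$compression * c_out))
      total <- total + 2 * c_out + c_out * c_next + c_next
    } else {
      total <- total + 2 * c_out +                      # head instance norm
        c_out * cfg$num_classes + cfg$num_classes       # linear head
    }
  }
  structure(list(layer_specs = specs, block_in_channels = cin,
                 final_channels = as.integer(cin[cfg$num_blocks] +
                                               cfg$layers_per_block * gS),
                 head = sprintf("global average pool -> linear(%d) -> softmax",
                                cfg$num_classes),
                 n_params = as.integer(total)),
            class = "dms_model_summary")
}

#' @export
print.dms_model_summary <- function(x, ...) {
  cat("<dms_model_summary>\n")
  df <- do.call(rbind, lapply(x$layer_specs, as.data.frame))
  print(df, row.names = FALSE)
  cat(sprintf("head: %s\ntrainable parameters: %d\n", x$head, x$n_params))
  invisible(x)
}

he_init <- function(k, cin, cout) {
  array(rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
        dim = c(k, k, cin, cout))
}

#' Build a DMS model with freshly initialized weights
#'
#' Layers are pre-activation style (instance norm, ReLU, then the parallel
#' scale convolutions); the head is global average pooling into a linear
#' softmax layer.  Weight initialization is seeded He-normal.  Instance
#' normalization keeps training and inference identical (no running batch
#' statistics), which matters at the small batch sizes this CPU
#' implementation targets.
#'
#' @param cfg a [dms_config()].
#' @param seed integer seed for weight initialization.
#' @return an object of class `dms_model` holding `cfg`, the flat parameter
#'   list, and the closed-form `summary`.
#' @export
build_dms_model <- function(cfg = dms_config(), seed = 1L) {
  stop_if(!inherits(cfg, "dms_config"), "cfg must be a dms_config")
  gS <- cfg$growth_rate * length(cfg$scales)
  cin <- block_in_channels(cfg)
  params <- list()
  with_seed(seed, {
    params[["stem.w"]] <- he_init(3L, 1L, cfg$stem_channels)
    params[["stem.b"]] <- numeric(cfg$stem_channels)
    for (b in seq_len(cfg$num_blocks)) {
      for (l in seq_len(cfg$layers_per_block)) {
        in_ch <- cin[b] + (l - 1L) * gS
        id <- sprintf("b%d.l%d", b, l)
        params[[paste0(id, ".bn.gamma")]] <- rep(1, in_ch)
        params[[paste0(id, ".bn.beta")]] <- numeric(in_ch)
        for (k in cfg$scales) {
          params[[sprintf("%s.s%d.w", id, k)]] <- he_init(k, in_ch, cfg$growth_rate)
          params[[sprintf("%s.s%d.b", id, k)]] <- numeric(cfg$growth_rate)
        }
      }
      c_out <- cin[b] + cfg$layers_per_block * gS
      if (b < cfg$num_blocks) {
        c_next <- max(1L, floor(cfg$compression * c_out))
        id <- sprintf("t%d", b)
        params[[paste0(id, ".bn.gamma")]] <- rep(1, c_out)
        params[[paste0(id, ".bn.beta")]] <- numeric(c_out)
        params[[paste0(id, ".w")]] <- he_init(1L, c_out, c_next)
        params[[paste0(id, ".b")]] <- numeric(c_next)
      } else {
        params[["head.bn.gamma"]] <- rep(1, c_out)
        params[["head.bn.beta"]] <- numeric(c_out)
        params[["head.w"]] <- matrix(rnorm(cfg$num_classes * c_out, 0,
                                           sqrt(2 / c_out)),
                                     cfg$num_classes, c_out)
        params[["head.b"]] <- numeric(cfg$num_classes)
      }
    }
  })
  structure(list(cfg = cfg, params = params,
                 summary = dms_model_summary(cfg)),
            class = "dms_model")
}

#' @export
print.dms_model <- function(x, ...) {
  cat(sprintf("<dms_model> scales {%s}, g=%d, L=%d, B=%d, %d params\n",
              paste(x$cfg$scales, collapse = ","), x$cfg$growth_rate,
              x$cfg$layers_per_block, x$cfg$num_blocks, x$summary$n_params))
  invisible(x)
}

# Number of trainable parameters actually held by a built model.
model_param_count <- function(model) {
  sum(vapply(model$params, length, numeric(1)))
}

# ---- forward / backward ---------------------------------------------------

# The parallel scale branches of a layer are computed as ONE convolution at
# the largest scale: each smaller kernel is embedded, centred, in a
# zero-padded k_max x k_max kernel, which is mathematically identical to the
# separate same-padded convolutions but costs a single im2col + GEMM.
# Gradients of the structurally-zero pad entries are simply discarded when
# the per-scale weight gradients are cropped back out.
merge_scale_weights <- function(p, id, scales, g) {
  kmax <- max(scales)
  w1 <- p[[sprintf("%s.s%d.w", id, scales[1])]]
  in_ch <- dim(w1)[3]
  S <- length(scales)
  wm <- array(0, c(kmax, kmax, in_ch, g * S))
  bm <- numeric(g * S)
  for (si in seq_len(S)) {
    k <- scales[si]
    off <- (kmax - k) / 2
    wm[off + seq_len(k), off + seq_len(k), , (si - 1L) * g + seq_len(g)] <-
      p[[sprintf("%s.s%d.w", id, k)]]
    bm[(si - 1L) * g + seq_len(g)] <- p[[sprintf("%s.s%d.b", id, k)]]
  }
  list(w = wm, b = bm)
}

split_scale_grads <- function(dwm, dbm, scales, g) {
  kmax <- max(scales)
  out <- list()
  for (si in seq_along(scales)) {
    k <- scales[si]
    off <- (kmax - k) / 2
    idx <- (si - 1L) * g + seq_len(g)
    out[[sprintf("s%d.w", k)]] <-
      dwm[off + seq_len(k), off + seq_len(k), , idx, drop = FALSE]
    out[[sprintf("s%d.b", k)]] <- dbm[idx]
  }
  out
}

# Full forward pass.  keep_cache retains every intermediate needed by the
# backward pass.  `ablate = list(block=b0, layer=l0)` (1-based) zeroes that
# layer's concatenated scale output.  `trace = TRUE` additionally records
# every dense layer's pre-normalization input and the final convolutional
# feature maps.  Instance normalization makes the pass identical in training
# and inference.
dms_forward_full <- function(model, x, training = FALSE, keep_cache = FALSE,
                             ablate = NULL, trace = FALSE) {
  cfg <- model$cfg
  p <- model$params
  d <- dim(x)
  stop_if(d[1] != d[2], "input images must be square")
  stop_if(d[3] != 1L, "input must be single-channel")
  cache <- if (keep_cache) list() else NULL
  tr <- if (trace) list(layer_inputs = list()) else NULL

  if (keep_cache) {
    sc <- conv2d_forward_keep(x, p[["stem.w"]], p[["stem.b"]])
    cur <- sc$y
    cache$stem_conv <- sc$cache
  } else {
    cur <- conv2d_forward(x, p[["stem.w"]], p[["stem.b"]])
  }
  for (b in seq_len(cfg$num_blocks)) {
    feats <- list(cur)
    for (l in seq_len(cfg$layers_per_block)) {
      id <- sprintf("b%d.l%d", b, l)
      xin <- concat_channels(feats)
      if (trace) tr$layer_inputs[[id]] <- xin
      nr <- instnorm_forward(xin, p[[paste0(id, ".bn.gamma")]],
                             p[[paste0(id, ".bn.beta")]])
      rl <- relu_forward(nr$y)
      mw <- merge_scale_weights(p, id, cfg$scales, cfg$growth_rate)
      if (keep_cache) {
        cv <- conv2d_forward_keep(rl$y, mw$w, mw$b)
        lo <- cv$y
        cache[[id]] <- list(norm = nr$cache, mask = rl$mask, conv = cv$cache)
      } else {
        lo <- conv2d_forward(rl$y, mw$w, mw$b)
      }
      if (!is.null(ablate) && ablate$block == b && ablate$layer == l) lo[] <- 0
      feats[[l + 1L]] <- lo
    }
    cur <- concat_channels(feats)
    if (b < cfg$num_blocks) {
      id <- sprintf("t%d", b)
      nr <- instnorm_forward(cur, p[[paste0(id, ".bn.gamma")]],
                             p[[paste0(id, ".bn.beta")]])
      rl <- relu_forward(nr$y)
      if (keep_cache) {
        cv <- conv2d_forward_keep(rl$y, p[[paste0(id, ".w")]],
                                  p[[paste0(id, ".b")]])
        tout <- cv$y
        cache[[id]] <- list(norm = nr$cache, mask = rl$mask, conv = cv$cache,
                            pre_pool_dim = dim(tout))
      } else {
        tout <- conv2d_forward(rl$y, p[[paste0(id, ".w")]], p[[paste0(id, ".b")]])
      }
      cur <- avgpool2_forward(tout)
    }
  }
  nrh <- instnorm_forward(cur, p[["head.bn.gamma"]], p[["head.bn.beta"]])
  rlh <- relu_forward(nrh$y)
  # the feature stage the classifier head actually reads; CAM maps are
  # defined on these activations
  if (trace) tr$final_features <- rlh$y
  feat <- gap_forward(rlh$y)
  logits <- linear_forward(feat, p[["head.w"]], p[["head.b"]])
  if (keep_cache) {
    cache$head <- list(norm = nrh$cache, mask = rlh$mask, feat = feat,
                       feat_dim = dim(rlh$y))
  }
  list(logits = logits, probs = softmax_rows(logits), cache = cache,
       trace = tr)
}

#' Forward pass: class probabilities
#'
#' Runs the network and returns softmax class probabilities.  Instance
#' normalization makes inference identical to the training-time function.
#'
#' @param model a [build_dms_model()] object.
#' @param x batch array `(H, W, 1, N)`, an `(H, W)` matrix, a
#'   [graded_image()], or an `image_dataset`.
#' @return `(N, num_classes)` probability matrix; rows sum to 1.
#' @export
dms_forward <- function(model, x) {
  stop_if(!inherits(model, "dms_model"), "model must be a dms_model")
  x <- as_batch_array(x)
  stop_if(dim(x)[1] != model$cfg$input_size,
          sprintf("input is %dpx but the model expects %dpx", dim(x)[1],
                  model$cfg$input_size))
  dms_forward_full(model, x, training = FALSE)$probs
}

#' @rdname dms_forward
#' @export
predict.dms_model <- function(object, x, ...) dms_forward(object, x)

# Coerce supported inputs to an (H, W, 1, N) batch array.
as_batch_array <- function(x) {
  if (inherits(x, "image_dataset")) {
    mats <- lapply(x$items, `[[`, "pixels")
    h <- nrow(mats[[1L]]); w <- ncol(mats[[1L]])
    return(array(unlist(mats, use.names = FALSE), c(h, w, 1L, length(mats))))
  }
  if (inherits(x, "graded_image")) x <- x$pixels
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L, 1L))
  stop_if(length(dim(x)) != 4L, "x must be an (H, W, 1, N) array")
  x
}

# Loss + gradients for one batch.  Returns grads as a flat list parallel to
# model$params, the loss value, and the batch probabilities.
dms_loss_grad <- function(model, x, labels) {
  cfg <- model$cfg
  p <- model$params
  fw <- dms_forward_full(model, x, training = TRUE, keep_cache = TRUE)
  ce <- softmax_xent(fw$logits, labels)
  cache <- fw$cache
  gS <- cfg$growth_rate * length(cfg$scales)
  grads <- list()

  lb <- linear_backward(ce$dlogits, cache$head$feat, p[["head.w"]])
  grads[["head.w"]] <- lb$dw
  grads[["head.b"]] <- lb$db
  dact <- gap_backward(lb$dfeat, cache$head$feat_dim)
  dnorm <- relu_backward(dact, cache$head$mask)
  hb <- instnorm_backward(dnorm, cache$head$norm)
  grads[["head.bn.gamma"]] <- hb$dgamma
  grads[["head.bn.beta"]] <- hb$dbeta
  dcur <- hb$dx                      # grad wrt last block output

  for (b in rev(seq_len(cfg$num_blocks))) {
    if (b < cfg$num_blocks) {
      id <- sprintf("t%d", b)
      tc <- cache[[id]]
      dtout <- avgpool2_backward(dcur, tc$pre_pool_dim)
      cb <- conv2d_backward(tc$conv, p[[paste0(id, ".w")]], dtout)
      grads[[paste0(id, ".w")]] <- cb$dw
      grads[[paste0(id, ".b")]] <- cb$db
      dnorm <- relu_backward(cb$dx, tc$mask)
      bb <- instnorm_backward(dnorm, tc$norm)
      grads[[paste0(id, ".bn.gamma")]] <- bb$dgamma
      grads[[paste0(id, ".bn.beta")]] <- bb$dbeta
      dcur <- bb$dx
    }
    # dcur is the gradient of the block-output concatenation
    cin_b <- dms_layer_in_channels(cfg, b - 1L, 0L)
    widths <- c(cin_b, rep(gS, cfg$layers_per_block))
    dfeats <- split_channels(dcur, widths)
    for (l in rev(seq_len(cfg$layers_per_block))) {
      id <- sprintf("b%d.l%d", b, l)
      lc <- cache[[id]]
      dlo <- dfeats[[l + 1L]]
      mw <- merge_scale_weights(p, id, cfg$scales, cfg$growth_rate)
      cb <- conv2d_backward(lc$conv, mw$w, dlo)
      sg <- split_scale_grads(cb$dw, cb$db, cfg$scales, cfg$growth_rate)
      for (nm in names(sg)) {
        g_ <- sg[[nm]]
        if (grepl("\\.w$", nm)) dim(g_) <- dim(p[[paste0(id, ".", nm)]])
        grads[[paste0(id, ".", nm)]] <- g_
      }
      dnorm <- relu_backward(cb$dx, lc$mask)
      bb <- instnorm_backward(dnorm, lc$norm)
      grads[[paste0(id, ".bn.gamma")]] <- bb$dgamma
      grads[[paste0(id, ".bn.beta")]] <- bb$dbeta
      dxin <- bb$dx
      # layer input was concat(block_in, outputs 1..l-1): fold back
      sub <- split_channels(dxin, widths[seq_len(l)])
      for (j in seq_len(l)) dfeats[[j]] <- dfeats[[j]] + sub[[j]]
    }
    dcur <- dfeats[[1L]]            # grad wrt the block input
  }
  sb <- conv2d_backward(cache$stem_conv, p[["stem.w"]], dcur, need_dx = FALSE)
  grads[["stem.w"]] <- sb$dw
  grads[["stem.b"]] <- sb$db
  list(loss = ce$loss, probs = ce$probs, grads = grads)
}
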