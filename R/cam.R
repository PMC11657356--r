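# Class-activation mapping against the final convolutional feature stage:
# the normalized, rectified last-block output that the classifier head
# reads (what GAP pools over).

new_activation_map <- function(heat, target_class, method) {
  structure(list(heat = heat, target_class = target_class, method = method),
            class = "activation_map")
}

#' @export
print.activation_map <- function(x, ...) {
  cat(sprintf("<activation_map> %s, class %s, %dx%d, max %.3f\n", x$method,
              if (is.na(x$target_class)) "-" else x$target_class,
              nrow(x$heat), ncol(x$heat), max(x$heat)))
  invisible(x)
}

# Rectify, bilinearly upsample to (h, w) and max-normalize; an identically
# zero map stays zero (no division).
finish_heat <- function(raw, h, w) {
  raw <- pmax(raw, 0)
  up <- bilinear_resize(raw, h, w)
  up <- pmax(up, 0)
  m <- max(up)
  if (m > 0) up / m else up
}

#' Plain activation map of the final convolutional stage
#'
#' Channel mean of the final feature maps the classifier head reads (the
#' normalized, rectified last-block output), rectified, bilinearly upsampled
#' to the input size and max-normalized (an all-zero map stays zero).
#' Deterministic for fixed weights.
#'
#' @param model a `dms_model`.
#' @param img a [graded_image()] or pixel matrix matching the model input
#'   size.
#' @return an `activation_map` with fields `heat` (matrix in `[0, 1]`, input
#'   shape), `target_class` (`NA`; the plain map is class-agnostic) and
#'   `method`.
#' @export
activation_map <- function(model, img) {
  stop_if(!inherits(model, "dms_model"), "model must be a dms_model")
  x <- as_batch_array(img)
  stop_if(dim(x)[1] != model$cfg$input_size, "image does not match input_size")
  fw <- dms_forward_full(model, x, training = FALSE, trace = TRUE)
  feats <- fw$trace$final_features            # (h, w, C, 1)
  d <- dim(feats)
  raw <- matrix(.rowMeans(matrix(feats, d[1] * d[2], d[3]), d[1] * d[2], d[3]),
                d[1], d[2])
  new_activation_map(finish_heat(raw, dim(x)[1], dim(x)[2]), NA_integer_,
                     "plain")
}

# Analytic gradient of one pre-softmax class score with respect to the final
# convolutional feature maps.  The head is GAP -> linear, so the gradient of
# class k's score at every spatial position of channel c is W[k, c] / (H*W):
# the classic class-activation-map chain.
head_feature_grad <- function(model, cache, target_class) {
  p <- model$params
  hc <- cache$head
  K <- nrow(p[["head.w"]])
  dlogits <- matrix(0, 1, K)
  dlogits[1, target_class + 1L] <- 1
  lb <- linear_backward(dlogits, hc$feat, p[["head.w"]])
  gap_backward(lb$dfeat, hc$feat_dim)
}

#' Gradient-weighted class-activation map (Grad-CAM)
#'
#' Channel weights are the spatial means of the gradient of the target
#' class's pre-softmax score with respect to the final convolutional feature
#' maps; the heat map is the rectified weighted channel sum, upsampled and
#' max-normalized as in [activation_map()].
#'
#' @param model a `dms_model`.
#' @param img a [graded_image()] or pixel matrix matching the model input
#'   size.
#' @param target_class 0-based class index.
#' @return an `activation_map`.
#' @export
grad_cam <- function(model, img, target_class) {
  stop_if(!inherits(model, "dms_model"), "model must be a dms_model")
  stop_if(target_class < 0 || target_class >= model$cfg$num_classes,
          "target_class out of range")
  x <- as_batch_array(img)
  stop_if(dim(x)[1] != model$cfg$input_size, "image does not match input_size")
  fw <- dms_forward_full(model, x, training = FALSE, keep_cache = TRUE,
                         trace = TRUE)
  feats <- fw$trace$final_features
  d <- dim(feats)
  dfeat <- head_feature_grad(model, fw$cache, as.integer(target_class))
  # alpha_c: spatial mean of the class-score gradient per channel
  alpha <- .colMeans(matrix(dfeat, d[1] * d[2], d[3]), d[1] * d[2], d[3])
  fm <- matrix(feats, d[1] * d[2], d[3])
  raw <- matrix(fm %*% alpha, d[1], d[2])
  new_activation_map(finish_heat(raw, dim(x)[1], dim(x)[2]),
                     as.integer(target_class), "grad_weighted")
}

# Five-anchor thermal colormap (dark blue -> red) evaluated at [0, 1].
heat_colormap <- function(v) {
  ramp <- colorRamp(c("#00003f", "#0000ff", "#00ffff", "#ffff00", "#ff0000"))
  ramp(clip01(v)) / 255
}

#' Overlay a heat map on a radiograph
#'
#' Alpha-blends the colormapped heat layer over the grayscale image.
#' `alpha = 0` reproduces the grayscale image rendered to RGB; `alpha = 1`
#' shows the colormapped heat alone.
#'
#' @param img a [graded_image()] or pixel matrix.
#' @param map an `activation_map` (or bare heat matrix) of the same shape.
#' @param alpha blend weight in `[0, 1]` (default 0.4).
#' @return `(H, W, 3)` integer array of 8-bit RGB values (0..255).
#' @export
overlay <- function(img, map, alpha = 0.4) {
  px <- if (inherits(img, "graded_image")) img$pixels else img
  heat <- if (inherits(map, "activation_map")) map$heat else map
  stop_if(!identical(dim(px), dim(heat)), "image and heat map shapes differ")
  check_number(alpha, "alpha", lower = 0, upper = 1)
  rgb_heat <- heat_colormap(as.vector(heat))   # (H*W, 3) in [0, 1]
  out <- array(0L, c(dim(px), 3L))
  for (ch in 1:3) {
    blended <- (1 - alpha) * as.vector(px) + alpha * rgb_heat[, ch]
    out[, , ch] <- as.integer(round(clip01(blended) * 255))
  }
  out
}
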