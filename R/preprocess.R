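#' Preprocessing configuration
#'
#' The radiograph preprocessing chain runs three steps in order: Gaussian
#' denoising, Sobel edge detection blended back onto the image
#' ("accumulation"), and histogram equalization.  Each step can be toggled.
#'
#' @param gaussian_sigma Gaussian sd in pixels (default 1.0; 0 disables
#'   smoothing exactly).
#' @param accumulation_weight weight of the edge map added onto the denoised
#'   image, in `[0, 1]` (default 0.5).
#' @param equalization_bins histogram bins for equalization (default 256).
#' @param do_denoise,do_edges,do_equalize step toggles.
#' @return an object of class `preprocess_config`.
#' @export
preprocess_config <- function(gaussian_sigma = 1.0, accumulation_weight = 0.5,
                              equalization_bins = 256L, do_denoise = TRUE,
                              do_edges = TRUE, do_equalize = TRUE) {
  check_number(gaussian_sigma, "gaussian_sigma", lower = 0)
  check_number(accumulation_weight, "accumulation_weight", lower = 0, upper = 1)
  check_number(equalization_bins, "equalization_bins", lower = 2, integer = TRUE)
  structure(list(gaussian_sigma = gaussian_sigma,
                 accumulation_weight = accumulation_weight,
                 equalization_bins = as.integer(equalization_bins),
                 do_denoise = isTRUE(do_denoise), do_edges = isTRUE(do_edges),
                 do_equalize = isTRUE(do_equalize)),
            class = "preprocess_config")
}

# Normalized 1-D Gaussian kernel truncated at 4*sigma.
gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Separable correlation of a matrix with a 1-D kernel along rows then
# columns, reflect-padded.  Kernels here are symmetric, so correlation and
# convolution coincide.
filter_separable <- function(img, k) {
  r <- (length(k) - 1L) / 2L
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0, h, w)
  for (t in seq_along(k)) {                       # vertical pass
    out <- out + k[t] * img[reflect_index(seq_len(h) + t - r - 1L, h), , drop = FALSE]
  }
  out2 <- matrix(0, h, w)
  for (t in seq_along(k)) {                       # horizontal pass
    out2 <- out2 + k[t] * out[, reflect_index(seq_len(w) + t - r - 1L, w), drop = FALSE]
  }
  out2
}

# Full (non-separable) 3x3 correlation with reflect padding.
filter_3x3 <- function(img, kern) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0, h, w)
  for (dj in -1:1) for (di in -1:1) {
    kv <- kern[di + 2L, dj + 2L]
    if (kv == 0) next
    out <- out + kv * img[reflect_index(seq_len(h) + di, h),
                          reflect_index(seq_len(w) + dj, w), drop = FALSE]
  }
  out
}

#' Gaussian denoising
#'
#' Separable Gaussian filter, kernel truncated at 4 sigma, reflect-padded
#' borders.  `sigma = 0` is an exact identity.
#'
#' @param img pixel matrix in `[0, 1]` (or a [graded_image()]).
#' @param sigma Gaussian sd in pixels, `>= 0`.
#' @return filtered matrix, clipped to `[0, 1]`.
#' @export
gaussian_denoise <- function(img, sigma = 1.0) {
  px <- if (inherits(img, "graded_image")) img$pixels else img
  stop_if(!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma < 0,
          "sigma must be a single number >= 0")
  if (sigma == 0) return(px)
  clip01(filter_separable(px, gaussian_kernel_1d(sigma)))
}

#' Sobel edge-magnitude map
#'
#' Applies the standard 3x3 Sobel pair (reflect-padded), returns
#' `sqrt(Gx^2 + Gy^2)` rescaled to `[0, 1]` by its maximum; an all-zero map
#' stays zero.
#'
#' @param img pixel matrix, at least 3x3.
#' @return edge-magnitude matrix in `[0, 1]`, same shape.
#' @export
sobel_edge_map <- function(img) {
  px <- if (inherits(img, "graded_image")) img$pixels else img
  stop_if(nrow(px) < 3L || ncol(px) < 3L, "image must be at least 3x3")
  # Gx responds to horizontal intensity change (vertical edges), Gy to
  # vertical change; row index is the vertical axis here.
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  ky <- t(kx)
  gx <- filter_3x3(px, kx)
  gy <- filter_3x3(px, ky)
  mag <- sqrt(gx^2 + gy^2)
  m <- max(mag)
  # a map that is zero up to floating-point cancellation stays zero rather
  # than being amplified by the normalization
  if (m > 1e-9) mag / m else mag * 0
}

#' Accumulate an edge map onto an image
#'
#' `clip(img + weight * edge_map, 0, 1)`; `weight = 0` is an identity.
#'
#' @param img pixel matrix.
#' @param edge_map matrix of the same shape.
#' @param weight blend weight in `[0, 1]`.
#' @return blended matrix in `[0, 1]`.
#' @export
edge_accumulate <- function(img, edge_map, weight = 0.5) {
  px <- if (inherits(img, "graded_image")) img$pixels else img
  stop_if(!identical(dim(px), dim(edge_map)), "img and edge_map shapes differ")
  check_number(weight, "weight", lower = 0, upper = 1)
  if (weight == 0) return(px)
  clip01(px + weight * edge_map)
}

#' Histogram equalization
#'
#' Remaps intensities through the normalized cumulative histogram computed on
#' `bins` equal-width bins over `[0, 1]`.  The mapping is non-decreasing, so
#' pixel rank order is preserved; a constant image is unchanged up to bin
#' quantization (it maps to a single level).
#'
#' @param img pixel matrix in `[0, 1]`.
#' @param bins number of histogram bins, `>= 2` (default 256).
#' @return equalized matrix in `[0, 1]`.
#' @export
equalize_hist <- function(img, bins = 256L) {
  px <- if (inherits(img, "graded_image")) img$pixels else img
  check_number(bins, "bins", lower = 2, integer = TRUE)
  bins <- as.integer(bins)
  idx <- pmin(bins, floor(px * bins) + 1L)  # bin of each pixel, 1..bins
  counts <- tabulate(idx, nbins = bins)
  cdf <- cumsum(counts) / length(px)
  matrix(cdf[idx], nrow(px), ncol(px))
}

#' Full preprocessing chain
#'
#' Runs the enabled steps in the stated order: denoise, then Sobel edges of
#' the *denoised* image accumulated back onto it, then histogram
#' equalization.  Grade label and source id pass through unchanged.
#'
#' @param img a [graded_image()] (or bare pixel matrix).
#' @param cfg a [preprocess_config()].
#' @return same type as `img`, preprocessed.
#' @export
preprocess_pipeline <- function(img, cfg = preprocess_config()) {
  stop_if(!inherits(cfg, "preprocess_config"), "cfg must be a preprocess_config")
  is_gi <- inherits(img, "graded_image")
  px <- if (is_gi) img$pixels else img
  if (cfg$do_denoise) px <- gaussian_denoise(px, cfg$gaussian_sigma)
  if (cfg$do_edges) px <- edge_accumulate(px, sobel_edge_map(px),
                                          cfg$accumulation_weight)
  if (cfg$do_equalize) px <- equalize_hist(px, cfg$equalization_bins)
  if (is_gi) {
    img$pixels <- px
    img
  } else px
}

#' Preprocess every image of a dataset
#' @param ds an `image_dataset`.
#' @param cfg a [preprocess_config()].
#' @return the dataset with all pixel matrices preprocessed.
#' @export
preprocess_dataset <- function(ds, cfg = preprocess_config()) {
  stop_if(!inherits(ds, "image_dataset"), "ds must be an image_dataset")
  ds$items <- lapply(ds$items, preprocess_pipeline, cfg = cfg)
  ds
}
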