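#' Run an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so seeded internals never disturb the
#' caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}

# Deterministic per-item seed derived from (master seed, class, index).
# Kept below 2^31 and away from double-precision overflow.
derive_seed <- function(master, class, index) {
  m <- as.double(master) %% 1e6
  as.integer((m * 100003 + as.double(class) * 10007 + as.double(index) * 7919 + 1) %%
               2147483647)
}

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         integer = FALSE, strict_lower = FALSE) {
  stop_if(!is.numeric(x) || length(x) != 1L || !is.finite(x),
          name, " must be a single finite number")
  stop_if(strict_lower && x <= lower, name, " must be > ", lower)
  stop_if(!strict_lower && x < lower, name, " must be >= ", lower)
  stop_if(x > upper, name, " must be <= ", upper)
  stop_if(integer && x != round(x), name, " must be an integer")
  invisible(x)
}

check_grade <- function(grade) {
  stop_if(!is.numeric(grade) || length(grade) != 1L || is.na(grade) ||
            grade != round(grade) || grade < 0 || grade > 4,
          "grade must be an integer in 0..4")
  as.integer(grade)
}

check_pixels <- function(px, name = "pixels") {
  stop_if(!is.matrix(px) || !is.numeric(px), name, " must be a numeric matrix")
  stop_if(any(!is.finite(px)), name, " contains non-finite values")
  stop_if(min(px) < 0 || max(px) > 1, name, " must lie in [0, 1]")
  invisible(px)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# Reflect (mirror, without repeating the edge sample twice at the fold) an
# index vector into 1..n; used for border handling in filtering/augmentation.
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  period <- 2L * (n - 1L)
  j <- (i - 1L) %% period
  j <- ifelse(j < 0, j + period, j)
  as.integer(ifelse(j < n, j + 1L, period - j + 1L))
}

#' Bilinear resize of a grayscale matrix
#' @param img numeric matrix.
#' @param out_h,out_w output dimensions.
#' @return numeric matrix `out_h x out_w`.
#' @keywords internal
bilinear_resize <- function(img, out_h, out_w) {
  h <- nrow(img); w <- ncol(img)
  if (h == out_h && w == out_w) return(img)
  # align-corners-free mapping of output pixel centres onto input coordinates
  ys <- (seq_len(out_h) - 0.5) * h / out_h + 0.5
  xs <- (seq_len(out_w) - 0.5) * w / out_w + 0.5
  ys <- pmin(pmax(ys, 1), h); xs <- pmin(pmax(xs, 1), w)
  y0 <- pmin(floor(ys), h - 1L); x0 <- pmin(floor(xs), w - 1L)
  fy <- ys - y0; fx <- xs - x0
  a <- img[y0, x0, drop = FALSE]; b <- img[y0 + 1, x0, drop = FALSE]
  c_ <- img[y0, x0 + 1, drop = FALSE]; d <- img[y0 + 1, x0 + 1, drop = FALSE]
  wy <- matrix(fy, out_h, out_w); wx <- matrix(fx, out_h, out_w, byrow = TRUE)
  a * (1 - wy) * (1 - wx) + b * wy * (1 - wx) + c_ * (1 - wy) * wx + d * wy * wx
}

# Bilinear sampling of img at fractional (y, x) coordinate matrices, with
# reflect handling outside the support.
bilinear_sample <- function(img, yy, xx) {
  h <- nrow(img); w <- ncol(img)
  y0 <- floor(yy); x0 <- floor(xx)
  fy <- yy - y0; fx <- xx - x0
  iy0 <- reflect_index(as.integer(y0), h)
  iy1 <- reflect_index(as.integer(y0) + 1L, h)
  ix0 <- reflect_index(as.integer(x0), w)
  ix1 <- reflect_index(as.integer(x0) + 1L, w)
  idx <- function(iy, ix) img[cbind(iy, ix)]
  v <- idx(iy0, ix0) * (1 - fy) * (1 - fx) + idx(iy1, ix0) * fy * (1 - fx) +
    idx(iy0, ix1) * (1 - fy) * fx + idx(iy1, ix1) * fy * fx
  matrix(v, nrow = nrow(yy), ncol = ncol(yy))
}
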