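#' Augmentation configuration
#'
#' Label-preserving geometric augmentation used to balance the per-grade
#' class counts: random rotation, random crop-and-resize, and horizontal
#' flipping.  All draws are seeded, so augmentation is reproducible.
#'
#' @param rotation_range maximum absolute rotation in degrees (default 15).
#' @param crop_fraction side fraction of the random crop, in `(0, 1]`
#'   (default 0.9); the crop is resized back to the input size.
#' @param flip_axes character subset of `"horizontal"` (default
#'   `"horizontal"`); each listed axis is flipped with probability 1/2.
#' @param seed integer master seed for [balance_dataset()] draws.
#' @return an object of class `augment_config`.
#' @export
augment_config <- function(rotation_range = 15, crop_fraction = 0.9,
                           flip_axes = "horizontal", seed = 1L) {
  check_number(rotation_range, "rotation_range", lower = 0)
  check_number(crop_fraction, "crop_fraction", lower = 0, upper = 1,
               strict_lower = TRUE)
  stop_if(!all(flip_axes %in% "horizontal"),
          "flip_axes must be a subset of 'horizontal'")
  structure(list(rotation_range = rotation_range,
                 crop_fraction = crop_fraction,
                 flip_axes = as.character(flip_axes),
                 seed = as.integer(seed)),
            class = "augment_config")
}

# Rotate a matrix by `angle` degrees about its centre; bilinear sampling,
# exposed corners filled by edge reflection.  angle == 0 is an exact identity.
rotate_image <- function(img, angle) {
  if (angle == 0) return(img)
  h <- nrow(img); w <- ncol(img)
  th <- angle * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  yy <- matrix(seq_len(h), h, w) - cy
  xx <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  # inverse map: sample source coordinates rotated by -angle
  sy <- cos(th) * yy - sin(th) * xx + cy
  sx <- sin(th) * yy + cos(th) * xx + cx
  bilinear_sample(img, sy, sx)
}

crop_resize <- function(img, frac, off_y, off_x) {
  if (frac >= 1) return(img)
  h <- nrow(img); w <- ncol(img)
  ch <- max(2L, round(frac * h)); cw <- max(2L, round(frac * w))
  y0 <- 1L + floor(off_y * (h - ch)); x0 <- 1L + floor(off_x * (w - cw))
  bilinear_resize(img[y0:(y0 + ch - 1L), x0:(x0 + cw - 1L), drop = FALSE], h, w)
}

flip_horizontal <- function(img) img[, rev(seq_len(ncol(img))), drop = FALSE]

#' Apply one seeded augmentation draw
#'
#' Transform order: rotate, crop-and-resize, flip.  The output keeps the
#' input's shape and grade; its source id is tagged as an augmented child of
#' the input.  The identity configuration (`rotation_range = 0`,
#' `crop_fraction = 1`, no flip axes) returns the input pixels bit-identically.
#'
#' @param img a [graded_image()].
#' @param cfg an [augment_config()].
#' @param draw_seed integer seed for this draw.
#' @param child_id optional source id for the augmented item.
#' @return an augmented [graded_image()].
#' @export
apply_augmentation <- function(img, cfg = augment_config(), draw_seed = 1L,
                               child_id = NULL) {
  stop_if(!inherits(img, "graded_image"), "img must be a graded_image")
  stop_if(!inherits(cfg, "augment_config"), "cfg must be an augment_config")
  px <- with_seed(draw_seed, {
    p <- img$pixels
    if (cfg$rotation_range > 0) {
      p <- rotate_image(p, runif(1, -cfg$rotation_range, cfg$rotation_range))
    }
    if (cfg$crop_fraction < 1) {
      p <- crop_resize(p, cfg$crop_fraction, runif(1), runif(1))
    }
    if ("horizontal" %in% cfg$flip_axes && runif(1) < 0.5) {
      p <- flip_horizontal(p)
    }
    p
  })
  out <- graded_image(clip01(px), img$grade,
                      if (is.null(child_id))
                        sprintf("%s__aug%d", img$source_id, as.integer(draw_seed))
                      else child_id)
  out
}

#' Balance a dataset to an exact per-class count
#'
#' Classes below `target_per_class` gain augmented copies of round-robin
#' sampled originals; classes above it are deterministically subsampled
#' without replacement, retaining originals preferentially over augmented
#' items.  Labels are preserved and every augmented item records its parent.
#'
#' @param ds an `image_dataset`.
#' @param target_per_class target count for every grade; `NULL` (default)
#'   balances up to the current majority count.
#' @param cfg an [augment_config()]; `cfg$seed` drives all draws.
#' @return a balanced `image_dataset` with exactly `target_per_class` items
#'   per grade.
#' @export
balance_dataset <- function(ds, target_per_class = NULL, cfg = augment_config()) {
  stop_if(!inherits(ds, "image_dataset"), "ds must be an image_dataset")
  stop_if(!inherits(cfg, "augment_config"), "cfg must be an augment_config")
  counts <- class_counts(ds)
  if (is.null(target_per_class)) target_per_class <- max(counts)
  check_number(target_per_class, "target_per_class", lower = 1, integer = TRUE)
  stop_if(any(counts == 0 & target_per_class > 0),
          "cannot balance: a grade has no images at all")
  grades <- ds$manifest$grade
  prov <- ds$manifest$provenance
  keep_items <- list(); keep_prov <- character(0); keep_parent <- character(0)
  for (g in 0:4) {
    idx <- which(grades == g)
    orig_idx <- idx[prov[idx] == "original"]
    stop_if(length(orig_idx) == 0L,
            sprintf("grade %d has no original images to augment", g))
    n <- length(idx)
    if (n > target_per_class) {
      # subsample: originals first, then augmented, seeded without replacement
      ranked <- c(orig_idx, setdiff(idx, orig_idx))
      n_orig_kept <- min(length(orig_idx), target_per_class)
      sel <- with_seed(derive_seed(cfg$seed, g, 0L), {
        o <- sample(orig_idx, n_orig_kept)
        extra <- target_per_class - n_orig_kept
        if (extra > 0) c(o, sample(setdiff(idx, orig_idx), extra)) else o
      })
      chosen <- sort(sel)
      keep_items <- c(keep_items, ds$items[chosen])
      keep_prov <- c(keep_prov, prov[chosen])
      keep_parent <- c(keep_parent, ds$manifest$parent_id[chosen])
    } else {
      keep_items <- c(keep_items, ds$items[idx])
      keep_prov <- c(keep_prov, prov[idx])
      keep_parent <- c(keep_parent, ds$manifest$parent_id[idx])
      deficit <- target_per_class - n
      if (deficit > 0) {
        parents <- orig_idx[((seq_len(deficit) - 1L) %% length(orig_idx)) + 1L]
        for (j in seq_len(deficit)) {
          parent <- ds$items[[parents[j]]]
          child <- apply_augmentation(
            parent, cfg, draw_seed = derive_seed(cfg$seed, g, j),
            child_id = sprintf("%s__aug%d", parent$source_id, j))
          keep_items <- c(keep_items, list(child))
          keep_prov <- c(keep_prov, "augmented")
          keep_parent <- c(keep_parent, parent$source_id)
        }
      }
    }
  }
  new_image_dataset(keep_items, provenance = keep_prov, parent_id = keep_parent)
}
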