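#' Phantom radiograph specification
#'
#' Describes the synthetic knee-radiograph generator.  A phantom consists of
#' two bright horizontal "bone" bands (distal femur above, proximal tibia
#' below) separated by a dark joint gap.  Pathology severity is encoded the
#' way radiographic osteoarthritis presents: the joint gap narrows with grade
#' (joint-space narrowing), bright elliptical protrusions appear at the band
#' margins (osteophytes), and the band intensity near the joint rises
#' (subchondral sclerosis).
#'
#' Geometric defaults are expressed as fractions of `image_size` so the same
#' spec scales from thumbnail fixtures to 224 px training images.  None of
#' the default values are clinical measurements; they are chosen so that the
#' five grades are distinguishable by structure yet overlap under jitter.
#'
#' @param image_size side of the square image in pixels (default 224).
#' @param gap_width_by_grade five strictly decreasing gap widths in pixels
#'   (grade 0 widest).  Default: `image_size * c(0.125, 0.10, 0.075, 0.05,
#'   0.025)`.
#' @param osteophyte_count_by_grade five non-decreasing integers; default
#'   `c(0, 1, 2, 4, 6)`.
#' @param osteophyte_radius protrusion radius in pixels; default
#'   `image_size / 45`.
#' @param sclerosis_gain_by_grade five non-decreasing intensity multipliers
#'   in `[1, 2]`; default `c(1, 1.08, 1.18, 1.32, 1.5)`.
#' @param noise_sigma additive Gaussian noise sd in intensity units
#'   (default 0.02).
#' @param background_level soft-tissue background intensity in `[0, 1]`
#'   (default 0.15).
#' @param jitter_fraction multiplicative gap-width jitter bound as a fraction
#'   of the nominal width (default 0.1).
#' @return an object of class `phantom_spec`.
#' @export
#' @examples
#' sp <- phantom_spec(image_size = 64)
#' img <- synth_radiograph(2, sp, seed = 1)
#' dim(img$pixels)
phantom_spec <- function(image_size = 224,
                         gap_width_by_grade = image_size * c(0.125, 0.10, 0.075, 0.05, 0.025),
                         osteophyte_count_by_grade = c(0L, 1L, 2L, 4L, 6L),
                         osteophyte_radius = image_size / 45,
                         sclerosis_gain_by_grade = c(1, 1.08, 1.18, 1.32, 1.5),
                         noise_sigma = 0.02,
                         background_level = 0.15,
                         jitter_fraction = 0.1) {
  check_number(image_size, "image_size", lower = 8, integer = TRUE)
  stop_if(length(gap_width_by_grade) != 5L || any(!is.finite(gap_width_by_grade)),
          "gap_width_by_grade must be 5 finite widths")
  stop_if(any(diff(gap_width_by_grade) >= 0),
          "gap_width_by_grade must be strictly decreasing in grade")
  stop_if(any(gap_width_by_grade <= 0) || any(gap_width_by_grade >= image_size),
          "gap widths must be positive and smaller than image_size")
  stop_if(length(osteophyte_count_by_grade) != 5L ||
            any(osteophyte_count_by_grade != round(osteophyte_count_by_grade)) ||
            any(osteophyte_count_by_grade < 0),
          "osteophyte_count_by_grade must be 5 non-negative integers")
  stop_if(any(diff(osteophyte_count_by_grade) < 0),
          "osteophyte_count_by_grade must be non-decreasing")
  check_number(osteophyte_radius, "osteophyte_radius", lower = 0,
               strict_lower = TRUE)
  stop_if(osteophyte_radius >= image_size, "osteophyte_radius too large")
  stop_if(length(sclerosis_gain_by_grade) != 5L ||
            any(sclerosis_gain_by_grade < 1) || any(sclerosis_gain_by_grade > 2),
          "sclerosis_gain_by_grade must be 5 values in [1, 2]")
  stop_if(any(diff(sclerosis_gain_by_grade) < 0),
          "sclerosis_gain_by_grade must be non-decreasing")
  check_number(noise_sigma, "noise_sigma", lower = 0)
  check_number(background_level, "background_level", lower = 0, upper = 1)
  check_number(jitter_fraction, "jitter_fraction", lower = 0, upper = 0.5)
  structure(list(
    image_size = as.integer(image_size),
    gap_width_by_grade = as.numeric(gap_width_by_grade),
    osteophyte_count_by_grade = as.integer(osteophyte_count_by_grade),
    osteophyte_radius = as.numeric(osteophyte_radius),
    sclerosis_gain_by_grade = as.numeric(sclerosis_gain_by_grade),
    noise_sigma = as.numeric(noise_sigma),
    background_level = as.numeric(background_level),
    jitter_fraction = as.numeric(jitter_fraction)
  ), class = "phantom_spec")
}

#' Construct a graded image
#'
#' @param pixels numeric matrix with values in `[0, 1]`.
#' @param grade integer KL grade in 0..4.
#' @param source_id identifier string.
#' @return an object of class `graded_image`.
#' @export
graded_image <- function(pixels, grade, source_id = "img") {
  check_pixels(pixels)
  structure(list(pixels = pixels, grade = check_grade(grade),
                 source_id = as.character(source_id)),
            class = "graded_image")
}

#' @export
print.graded_image <- function(x, ...) {
  cat(sprintf("<graded_image> %s  %dx%d  KL grade %d\n", x$source_id,
              nrow(x$pixels), ncol(x$pixels), x$grade))
  invisible(x)
}

#' Synthesize one phantom knee radiograph
#'
#' Deterministic in `(grade, spec, seed)`.  The joint centre row and the gap
#' width receive bounded jitter (at most `spec$jitter_fraction` of the
#' nominal width) so that grade information is carried by structure rather
#' than a fixed pixel row.
#'
#' @param grade integer KL grade 0..4.
#' @param spec a [phantom_spec()].
#' @param seed integer seed.
#' @return a [graded_image()].
#' @export
synth_radiograph <- function(grade, spec = phantom_spec(), seed = 1L) {
  grade <- check_grade(grade)
  stop_if(!inherits(spec, "phantom_spec"), "spec must be a phantom_spec")
  n <- spec$image_size
  with_seed(seed, {
    gap_nom <- spec$gap_width_by_grade[grade + 1L]
    gap <- gap_nom * (1 + runif(1, -spec$jitter_fraction, spec$jitter_fraction))
    centre <- n / 2 + runif(1, -0.03, 0.03) * n
    gain <- spec$sclerosis_gain_by_grade[grade + 1L]

    rows <- matrix(seq_len(n), n, n)
    cols <- matrix(seq_len(n), n, n, byrow = TRUE)
    img <- matrix(spec$background_level, n, n)

    # bone shafts: vertical extent with gently curved margins facing the gap
    margin_wiggle <- 0.02 * n * sin(2 * pi * (seq_len(n) / n) + runif(1, 0, 2 * pi))
    top_edge <- centre - gap / 2 + matrix(margin_wiggle, n, n, byrow = TRUE)
    bot_edge <- centre + gap / 2 + matrix(margin_wiggle, n, n, byrow = TRUE)
    band_top <- 0.12 * n
    band_bot <- 0.88 * n
    base <- 0.55
    femur <- rows >= band_top & rows < top_edge
    tibia <- rows > bot_edge & rows <= band_bot

    # sclerosis: intensity gain strongest within ~15% of the image height of
    # the joint margin, fading linearly into the shaft
    d_joint <- pmin(abs(rows - top_edge), abs(rows - bot_edge))
    fade <- pmax(0, 1 - d_joint / (0.15 * n))
    bone_gain <- 1 + (gain - 1) * fade
    img[femur] <- clip01(base * bone_gain[femur])
    img[tibia] <- clip01(base * bone_gain[tibia])

    # lateral cortical shading so bands are not perfectly flat
    shade <- 0.05 * cos(2 * pi * cols / n)
    img[femur | tibia] <- clip01(img[femur | tibia] + shade[femur | tibia])

    # osteophytes: bright ellipses seated on the joint margins, alternating
    # between the medial and lateral band corners
    n_ost <- spec$osteophyte_count_by_grade[grade + 1L]
    if (n_ost > 0) {
      r <- spec$osteophyte_radius
      for (i in seq_len(n_ost)) {
        side <- if (i %% 2 == 0) 0.12 else 0.88       # lateral vs medial
        cx <- n * side + runif(1, -0.04, 0.04) * n
        on_top <- (i %% 4) < 2
        cy <- centre + (if (on_top) -gap / 2 - r * 0.3 else gap / 2 + r * 0.3) +
          runif(1, -0.3, 0.3) * r
        mask <- ((rows - cy) / (1.4 * r))^2 + ((cols - cx) / r)^2 <= 1
        img[mask] <- clip01(pmax(img[mask], clip01(base * gain) + 0.1))
      }
    }

    if (spec$noise_sigma > 0) {
      img <- img + matrix(rnorm(n * n, 0, spec$noise_sigma), n, n)
    }
    graded_image(clip01(img), grade,
                 sprintf("phantom_g%d_s%d", grade, as.integer(seed)))
  })
}

#' Measure the joint gap width of a phantom
#'
#' Independent geometric read-out used by tests and demos: scans the central
#' columns for the longest dark run around the image centre and averages the
#' run length across columns.
#'
#' @param img a [graded_image()] or a pixel matrix.
#' @param dark_threshold intensities below this count as gap (default 0.35).
#' @return estimated gap width in pixels.
#' @export
measure_gap_width <- function(img, dark_threshold = 0.35) {
  px <- if (inherits(img, "graded_image")) img$pixels else img
  n <- nrow(px)
  centre_cols <- seq.int(max(1L, floor(n * 0.3)), ceiling(n * 0.7))
  runs <- vapply(centre_cols, function(j) {
    dark <- px[, j] < dark_threshold
    mid <- round(n / 2)
    if (!dark[mid]) {
      # jittered centre: look for the nearest dark row within the central third
      cand <- which(dark & abs(seq_len(n) - mid) < n / 6)
      if (length(cand) == 0L) return(0)
      mid <- cand[which.min(abs(cand - mid))]
    }
    lo <- mid
    while (lo > 1L && dark[lo - 1L]) lo <- lo - 1L
    hi <- mid
    while (hi < n && dark[hi + 1L]) hi <- hi + 1L
    hi - lo + 1
  }, numeric(1))
  mean(runs)
}

#' Synthesize a phantom dataset
#'
#' Item seeds derive deterministically from `(seed, grade, index)`, so the
#' full dataset is reproducible and items are pairwise independent draws.
#'
#' @param n_per_class integer vector of length 5: images per KL grade.
#' @param spec a [phantom_spec()].
#' @param seed master integer seed.
#' @return an object of class `image_dataset` with fields `items` (list of
#'   [graded_image()]) and `manifest` (data.frame with columns `source_id`,
#'   `grade`, `provenance`, `parent_id`).
#' @export
synth_dataset <- function(n_per_class, spec = phantom_spec(), seed = 1L) {
  stop_if(length(n_per_class) != 5L || any(n_per_class < 0) ||
            any(n_per_class != round(n_per_class)),
          "n_per_class must be 5 non-negative integers")
  items <- vector("list", sum(n_per_class))
  pos <- 0L
  for (g in 0:4) {
    for (i in seq_len(n_per_class[g + 1L])) {
      im <- synth_radiograph(g, spec, derive_seed(seed, g, i))
      im$source_id <- sprintf("g%d_i%04d", g, i)
      pos <- pos + 1L
      items[[pos]] <- im
    }
  }
  new_image_dataset(items)
}

# Internal constructor: builds the manifest from the items.
new_image_dataset <- function(items, provenance = NULL, parent_id = NULL) {
  n <- length(items)
  if (is.null(provenance)) provenance <- rep("original", n)
  if (is.null(parent_id)) parent_id <- rep(NA_character_, n)
  manifest <- data.frame(
    source_id = vapply(items, `[[`, character(1), "source_id"),
    grade = vapply(items, `[[`, integer(1), "grade"),
    provenance = provenance,
    parent_id = parent_id,
    stringsAsFactors = FALSE
  )
  structure(list(items = items, manifest = manifest), class = "image_dataset")
}

#' @export
print.image_dataset <- function(x, ...) {
  cat(sprintf("<image_dataset> %d items\n", length(x$items)))
  print(table(grade = x$manifest$grade, provenance = x$manifest$provenance))
  invisible(x)
}

#' Per-grade item counts of a dataset
#' @param ds an `image_dataset`.
#' @return named integer vector of length 5 (grades 0..4).
#' @export
class_counts <- function(ds) {
  stop_if(!inherits(ds, "image_dataset"), "ds must be an image_dataset")
  cnt <- integer(5)
  tab <- table(factor(ds$manifest$grade, levels = 0:4))
  cnt <- as.integer(tab)
  names(cnt) <- 0:4
  cnt
}
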