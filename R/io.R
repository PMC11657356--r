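# Dataset I/O: 8-bit grayscale PNGs plus the manifest CSV dialect
# (UTF-8, header `source_id,path,grade,provenance`).

#' Write a dataset to disk
#'
#' Writes one 8-bit grayscale PNG per item and a `manifest.csv` with columns
#' `source_id, path, grade, provenance`.  Augmented-item parentage is encoded
#' in the source id (`<parent>__augN`).
#'
#' @param ds an `image_dataset`.
#' @param dir output directory (created if missing).
#' @return path of the written manifest, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stop_if(!inherits(ds, "image_dataset"), "ds must be an image_dataset")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(ds$items))
  for (i in seq_along(ds$items)) {
    it <- ds$items[[i]]
    paths[i] <- paste0(it$source_id, ".png")
    png::writePNG(it$pixels, file.path(dir, paths[i]))
  }
  man <- data.frame(source_id = ds$manifest$source_id, path = paths,
                    grade = ds$manifest$grade,
                    provenance = ds$manifest$provenance)
  out <- file.path(dir, "manifest.csv")
  write.csv(man, out, row.names = FALSE, quote = FALSE)
  invisible(out)
}

#' Read a dataset from a manifest
#'
#' @param manifest path to a `manifest.csv` (columns `source_id, path, grade,
#'   provenance`); image paths are resolved relative to the manifest's
#'   directory.
#' @return an `image_dataset`.
#' @export
read_dataset <- function(manifest) {
  stop_if(!file.exists(manifest), "manifest not found: ", manifest)
  man <- read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("source_id", "path", "grade", "provenance")
  stop_if(!all(need %in% names(man)),
          "manifest must have columns source_id, path, grade, provenance")
  base <- dirname(manifest)
  items <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    g <- man$grade[i]
    if (!is.numeric(g) || is.na(g) || g != round(g) || g < 0 || g > 4) {
      stop(sprintf("invalid grade %s in manifest row %d (source_id %s)",
                   as.character(g), i, man$source_id[i]), call. = FALSE)
    }
    px <- png::readPNG(file.path(base, man$path[i]))
    if (length(dim(px)) == 3L) px <- px[, , 1L]   # collapse grayscale-as-RGB
    items[[i]] <- graded_image(px, g, man$source_id[i])
  }
  prov <- man$provenance
  parent <- ifelse(grepl("__aug\\d+$", man$source_id),
                   sub("__aug\\d+$", "", man$source_id), NA_character_)
  new_image_dataset(items, provenance = prov, parent_id = parent)
}

#' Write a heat map (and its overlay) as PNG
#'
#' @param map an `activation_map`.
#' @param img the underlying [graded_image()] (for the overlay).
#' @param path output PNG path for the raw heat; the overlay is written to
#'   `<path>_overlay.png`.
#' @param alpha overlay blend weight.
#' @return `path`, invisibly.
#' @export
write_heatmap <- function(map, img, path, alpha = 0.4) {
  png::writePNG(map$heat, path)
  ov <- overlay(img, map, alpha)
  png::writePNG(ov / 255, sub("\\.png$", "_overlay.png", path))
  invisible(path)
}
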