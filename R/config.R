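# Run configuration: nested sections mirroring each module's config type.
# YAML on disk (JSON accepted, YAML being a superset for our key set);
# unknown keys are rejected by name, and the resolved config is serialized
# alongside every run so runs are self-describing.

#' Default run configuration
#'
#' @return nested list with sections `phantom`, `preprocess`, `augment`,
#'   `model`, `train`, `eval`, plus global `seed` and `out_dir`.
#' @export
default_run_config <- function() {
  list(
    seed = 7L,
    out_dir = "dms_run",
    phantom = list(enabled = TRUE, n_per_class = c(10L, 10L, 10L, 10L, 10L),
                   image_size = 64L, noise_sigma = 0.02),
    preprocess = list(gaussian_sigma = 1.0, accumulation_weight = 0.5,
                      equalization_bins = 256L, do_denoise = TRUE,
                      do_edges = TRUE, do_equalize = TRUE),
    augment = list(rotation_range = 15, crop_fraction = 0.9,
                   flip_axes = "horizontal", balance = TRUE,
                   target_per_class = NULL),
    model = list(scales = c(1L, 3L, 5L), growth_rate = 12L,
                 layers_per_block = 4L, num_blocks = 3L, stem_channels = 24L,
                 compression = 0.5, num_classes = 5L, input_size = 64L),
    train = list(learning_rate = 1e-4, batch_size = 64L, epochs = 50L,
                 optimizer = "adam", clip_norm = 5, test_fraction = 0.2,
                 val_fraction = 0.1, early_stop = NULL),
    eval = list(cam_method = "grad", cam_samples = 1L, cam_alpha = 0.4)
  )
}

merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (path == "") key else paste0(path, ".", key)
    if (!key %in% names(defaults)) {
      stop(sprintf("unknown config key: %s", full), call. = FALSE)
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      stop_if(!is.list(user[[key]]) && !is.null(user[[key]]),
              sprintf("config key %s must be a section", full))
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Load and validate a run configuration
#'
#' Reads YAML (or JSON), validates keys against [default_run_config()]
#' (unknown keys raise an error naming the key) and fills defaults.  An empty
#' file yields the all-defaults configuration.
#'
#' @param path YAML/JSON file path, or `NULL` for pure defaults.
#' @return validated configuration list of class `run_config`.
#' @export
load_config <- function(path = NULL) {
  user <- list()
  if (!is.null(path)) {
    stop_if(!file.exists(path), "config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    stop_if(!is.list(user), "config must be a mapping")
  }
  cfg <- merge_config(default_run_config(), user)
  structure(cfg, class = "run_config")
}

#' Serialize a run configuration
#'
#' @param cfg a `run_config` (or plain nested list).
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
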