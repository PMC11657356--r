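# End-to-end workflow: synth -> preprocess -> split -> balance(train) ->
# train -> evaluate -> CAM samples.  Balancing happens after splitting and
# only on the training partition, so augmented copies can never leak into
# validation or test.

run_log <- function(con, fmt, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
  writeLines(line, con)
  message(line)
}

#' Run the full DMS pipeline
#'
#' Executes every stage under a run directory and leaves it self-describing:
#' `config.resolved.yaml`, `run.log`, `manifest.csv`, `history.csv`,
#' `best.ckpt` / `final.ckpt`, `metrics.json` and CAM heat maps.  Stage
#' failures propagate with the stage name prefixed.
#'
#' @param cfg a `run_config` from [load_config()] /
#'   [default_run_config()].
#' @param manifest optional manifest CSV of an existing image corpus; when
#'   `NULL` (default) phantoms are synthesized per `cfg$phantom`.
#' @return invisible list: `status` (0 on success), `metrics`
#'   (a [metrics_report()]), `history`, and artifact `paths`.
#' @export
run_pipeline <- function(cfg = load_config(), manifest = NULL) {
  if (!inherits(cfg, "run_config")) cfg <- merge_config(default_run_config(), cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  save_config(cfg, file.path(cfg$out_dir, "config.resolved.yaml"))
  logf <- file(file.path(cfg$out_dir, "run.log"), open = "wt")
  on.exit(close(logf))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  ds <- stage("synth", {
    if (!is.null(manifest)) {
      run_log(logf, "loading dataset from %s", manifest)
      read_dataset(manifest)
    } else {
      stop_if(!isTRUE(cfg$phantom$enabled),
              "no manifest given and phantom synthesis disabled")
      run_log(logf, "synthesizing %d phantoms at %dpx",
              sum(unlist(cfg$phantom$n_per_class)), cfg$phantom$image_size)
      spec <- phantom_spec(image_size = cfg$phantom$image_size,
                           noise_sigma = cfg$phantom$noise_sigma)
      synth_dataset(unlist(cfg$phantom$n_per_class), spec, seed = cfg$seed)
    }
  })
  write_dataset(ds, cfg$out_dir)

  ds <- stage("preprocess", {
    run_log(logf, "preprocessing %d images", length(ds$items))
    pcfg <- preprocess_config(
      gaussian_sigma = cfg$preprocess$gaussian_sigma,
      accumulation_weight = cfg$preprocess$accumulation_weight,
      equalization_bins = cfg$preprocess$equalization_bins,
      do_denoise = cfg$preprocess$do_denoise,
      do_edges = cfg$preprocess$do_edges,
      do_equalize = cfg$preprocess$do_equalize)
    preprocess_dataset(ds, pcfg)
  })

  parts <- stage("split", {
    run_log(logf, "splitting (test %.2f, val %.2f)", cfg$train$test_fraction,
            cfg$train$val_fraction)
    split_dataset(ds, cfg$train$test_fraction, cfg$train$val_fraction,
                  seed = cfg$seed)
  })

  train_ds <- stage("balance", {
    if (isTRUE(cfg$augment$balance)) {
      acfg <- augment_config(rotation_range = cfg$augment$rotation_range,
                             crop_fraction = cfg$augment$crop_fraction,
                             flip_axes = unlist(cfg$augment$flip_axes),
                             seed = cfg$seed)
      tgt <- cfg$augment$target_per_class
      run_log(logf, "balancing training split to %s per class",
              if (is.null(tgt)) "majority count" else tgt)
      balance_dataset(parts$train, tgt, acfg)
    } else parts$train
  })

  trained <- stage("train", {
    mcfg <- dms_config(scales = unlist(cfg$model$scales),
                       growth_rate = cfg$model$growth_rate,
                       layers_per_block = cfg$model$layers_per_block,
                       num_blocks = cfg$model$num_blocks,
                       stem_channels = cfg$model$stem_channels,
                       compression = cfg$model$compression,
                       num_classes = cfg$model$num_classes,
                       input_size = cfg$model$input_size)
    model <- build_dms_model(mcfg, seed = cfg$seed)
    run_log(logf, "training DMS (%d params) for %d epochs",
            model$summary$n_params, cfg$train$epochs)
    hp <- dms_hyperparams(learning_rate = cfg$train$learning_rate,
                          batch_size = cfg$train$batch_size,
                          epochs = cfg$train$epochs,
                          optimizer = cfg$train$optimizer,
                          clip_norm = cfg$train$clip_norm,
                          seed = cfg$seed,
                          early_stop = cfg$train$early_stop)
    val <- if (length(parts$val$items) > 0) parts$val else NULL
    train_model(model, train_ds, val, hp)
  })
  write.csv(trained$history, file.path(cfg$out_dir, "history.csv"),
            row.names = FALSE)
  save_checkpoint(trained$model, file.path(cfg$out_dir, "final.ckpt"))
  save_checkpoint(trained$best_model, file.path(cfg$out_dir, "best.ckpt"))

  report <- stage("evaluate", {
    run_log(logf, "evaluating on %d test items", length(parts$test$items))
    evaluate_model(trained$best_model, parts$test)
  })
  metrics_path <- file.path(cfg$out_dir, "metrics.json")
  write_metrics_json(report, metrics_path)

  heat_paths <- stage("cam", {
    n_cam <- min(cfg$eval$cam_samples, length(parts$test$items))
    run_log(logf, "writing %d CAM heat maps", n_cam)
    vapply(seq_len(n_cam), function(i) {
      im <- parts$test$items[[i]]
      map <- if (identical(cfg$eval$cam_method, "plain")) {
        activation_map(trained$best_model, im)
      } else {
        grad_cam(trained$best_model, im, im$grade)
      }
      p <- file.path(cfg$out_dir, sprintf("heat_%s.png", im$source_id))
      write_heatmap(map, im, p, alpha = cfg$eval$cam_alpha)
      p
    }, character(1))
  })

  run_log(logf, "done: macro ACC %.4f, overall accuracy %.4f",
          report$macro$ACC, report$overall_accuracy)
  invisible(list(status = 0L, metrics = report, history = trained$history,
                 paths = list(run_dir = cfg$out_dir, metrics = metrics_path,
                              heatmaps = heat_paths)))
}

# Serialize a metrics_report (including confusion matrix and ROC point
# lists) to JSON, deterministically.
write_metrics_json <- function(report, path) {
  payload <- list(
    per_class = report$per_class,
    macro = report$macro,
    overall_accuracy = report$overall_accuracy,
    micro_auc = report$micro_auc,
    confusion = unclass(report$confusion),
    roc = if (is.null(report$roc)) NULL else
      lapply(report$roc, function(r) list(auc = r$auc, points = r$points))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", matrix = "rowmajor")
  invisible(path)
}
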