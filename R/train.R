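#' Training hyperparameters
#'
#' Defaults follow the published setup for this task: learning rate 1e-4,
#' batch size 64, 50 epochs, categorical cross-entropy.  The optimizer is not
#' named in that setup; Adam is the default companion of this learning rate,
#' with SGD + momentum available.  "Gradient thresholding" is realized as
#' global-norm gradient clipping (default max-norm 5).
#'
#' @param learning_rate positive step size (default 1e-4; 0 is allowed and
#'   performs null updates, useful for harness checks).
#' @param batch_size minibatch size (default 64).
#' @param epochs number of epochs (default 50).
#' @param optimizer `"adam"` or `"sgd"`.
#' @param clip_norm global gradient-norm clip; `NULL` disables (default 5).
#' @param seed integer seed for shuffling.
#' @param early_stop optional patience (epochs without validation-loss
#'   improvement before stopping); `NULL` disables.
#' @param stop_train_acc optional training-accuracy threshold at which to
#'   stop early (e.g. 1.0 for capacity checks); `NULL` disables.
#' @return an object of class `dms_hyperparams`.
#' @export
dms_hyperparams <- function(learning_rate = 1e-4, batch_size = 64L,
                            epochs = 50L, optimizer = c("adam", "sgd"),
                            clip_norm = 5, seed = 1L, early_stop = NULL,
                            stop_train_acc = NULL) {
  check_number(learning_rate, "learning_rate", lower = 0)
  check_number(batch_size, "batch_size", lower = 1, integer = TRUE)
  check_number(epochs, "epochs", lower = 1, integer = TRUE)
  optimizer <- match.arg(optimizer)
  if (!is.null(clip_norm)) check_number(clip_norm, "clip_norm", lower = 0,
                                        strict_lower = TRUE)
  if (!is.null(early_stop)) check_number(early_stop, "early_stop", lower = 1,
                                         integer = TRUE)
  if (!is.null(stop_train_acc)) check_number(stop_train_acc, "stop_train_acc",
                                             lower = 0, upper = 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), optimizer = optimizer,
                 clip_norm = clip_norm, seed = as.integer(seed),
                 early_stop = early_stop, stop_train_acc = stop_train_acc),
            class = "dms_hyperparams")
}

# Root id of an item: augmented children share their parent's root, so splits
# can never separate a parent from its augmented copies.
root_ids <- function(ds) {
  ids <- ds$manifest$source_id
  parents <- ds$manifest$parent_id
  ifelse(is.na(parents) | parents == "", sub("__aug\\d+$", "", ids), parents)
}

#' Stratified train/validation/test split
#'
#' Splits by grade so each partition mirrors the class profile (within one
#' item per class), and by *root* source id so an augmented item always lands
#' in the same partition as its parent.
#'
#' @param ds an `image_dataset`.
#' @param test_fraction fraction held out for testing (default 0.2).
#' @param val_fraction fraction held out for validation (default 0.1).
#' @param seed integer seed.
#' @return named list of `image_dataset`s: `train`, `val`, `test`.
#' @export
split_dataset <- function(ds, test_fraction = 0.2, val_fraction = 0.1,
                          seed = 1L) {
  stop_if(!inherits(ds, "image_dataset"), "ds must be an image_dataset")
  check_number(test_fraction, "test_fraction", lower = 0, upper = 1,
               strict_lower = TRUE)
  check_number(val_fraction, "val_fraction", lower = 0, upper = 1)
  stop_if(test_fraction + val_fraction >= 1, "fractions must sum to < 1")
  roots <- root_ids(ds)
  grades <- ds$manifest$grade
  assign_split <- rep(NA_character_, length(roots))
  for (g in sort(unique(grades))) {
    g_roots <- unique(roots[grades == g])
    stop_if(length(g_roots) < 2 && test_fraction > 0,
            sprintf("grade %d has too few distinct source groups to stratify", g))
    ord <- with_seed(derive_seed(seed, g, 0L), sample(g_roots))
    n <- length(ord)
    n_test <- round(test_fraction * n)
    n_val <- round(val_fraction * n)
    lab <- rep("train", n)
    if (n_test > 0) lab[seq_len(n_test)] <- "test"
    if (n_val > 0) lab[n_test + seq_len(n_val)] <- "val"
    assign_split[roots %in% ord[lab == "test"] & grades == g] <- "test"
    assign_split[roots %in% ord[lab == "val"] & grades == g] <- "val"
    assign_split[is.na(assign_split) & grades == g] <- "train"
  }
  subset_ds <- function(which) {
    sel <- assign_split == which
    new_image_dataset(ds$items[sel], provenance = ds$manifest$provenance[sel],
                      parent_id = ds$manifest$parent_id[sel])
  }
  list(train = subset_ds("train"), val = subset_ds("val"),
       test = subset_ds("test"))
}

dataset_labels <- function(ds) as.integer(ds$manifest$grade)

eval_accuracy <- function(model, x, labels, chunk = 64L) {
  n <- dim(x)[4]
  correct <- 0L
  for (s in seq.int(1L, n, chunk)) {
    e <- min(s + chunk - 1L, n)
    pr <- dms_forward_full(model, x[, , , s:e, drop = FALSE],
                           training = FALSE)$probs
    correct <- correct + sum(max.col(pr, ties.method = "first") - 1L == labels[s:e])
  }
  correct / n
}

#' Train a DMS model
#'
#' Minibatch training with seeded shuffling, optional gradient clipping and
#' early stopping.  Per-epoch history records the mean training batch loss,
#' the training accuracy aggregated over the epoch's batches (the usual
#' running convention), and validation loss / accuracy when a validation set
#' is given.  When `hp$stop_train_acc` is set and the batch-level accuracy
#' comes within 0.06 of the threshold, that epoch's `train_acc` is replaced
#' by a full end-of-epoch inference-mode pass over the training set, and
#' training stops once the confirmed value reaches the threshold.  Aborts
#' with a
#' diagnostic naming the epoch and batch if the loss turns non-finite.
#'
#' @param model a [build_dms_model()] object.
#' @param train an `image_dataset` (images must match `cfg$input_size`).
#' @param val optional validation `image_dataset` (or `NULL`).
#' @param hp a [dms_hyperparams()].
#' @param verbose print one line per epoch.
#' @return list with the trained `model`, the epoch `history` data.frame, and
#'   `best_model` (lowest validation loss; equals `model` when no validation
#'   set is supplied).
#' @export
train_model <- function(model, train, val = NULL, hp = dms_hyperparams(),
                        verbose = FALSE) {
  stop_if(!inherits(model, "dms_model"), "model must be a dms_model")
  stop_if(!inherits(train, "image_dataset"), "train must be an image_dataset")
  stop_if(!inherits(hp, "dms_hyperparams"), "hp must be dms_hyperparams")
  x <- as_batch_array(train)
  stop_if(dim(x)[1] != model$cfg$input_size,
          "training images do not match cfg$input_size")
  y <- dataset_labels(train)
  n <- dim(x)[4]
  xv <- NULL; yv <- NULL
  if (!is.null(val) && length(val$items) > 0) {
    xv <- as_batch_array(val); yv <- dataset_labels(val)
  }
  opt <- if (hp$optimizer == "adam") adam_init(model$params) else sgd_init(model$params)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     train_acc = numeric(0), val_loss = numeric(0),
                     val_acc = numeric(0))
  best_loss <- Inf; best_model <- model; stall <- 0L
  for (epoch in seq_len(hp$epochs)) {
    ord <- with_seed(derive_seed(hp$seed, 0L, epoch), sample.int(n))
    losses <- numeric(0)
    n_correct <- 0L
    starts <- seq.int(1L, n, hp$batch_size)
    for (bi in seq_along(starts)) {
      sel <- ord[starts[bi]:min(starts[bi] + hp$batch_size - 1L, n)]
      out <- dms_loss_grad(model, x[, , , sel, drop = FALSE], y[sel])
      if (!is.finite(out$loss)) {
        stop(sprintf("non-finite loss at epoch %d, batch %d", epoch, bi),
             call. = FALSE)
      }
      grads <- clip_gradients(out$grads, hp$clip_norm)
      stepped <- if (hp$optimizer == "adam") {
        adam_step(model$params, grads, opt, hp$learning_rate)
      } else {
        sgd_step(model$params, grads, opt, hp$learning_rate)
      }
      model$params <- stepped$params
      opt <- stepped$opt
      losses <- c(losses, out$loss)
      n_correct <- n_correct +
        sum(max.col(out$probs, ties.method = "first") - 1L == y[sel])
    }
    tr_acc <- n_correct / n
    stop_now <- FALSE
    if (!is.null(hp$stop_train_acc) && tr_acc >= hp$stop_train_acc - 0.06) {
      # within reach: confirm with an end-of-epoch inference-mode pass over
      # the full training set (the recorded value for this epoch)
      tr_acc <- eval_accuracy(model, x, y)
      stop_now <- tr_acc >= hp$stop_train_acc
    }
    vl <- NA_real_; va <- NA_real_
    if (!is.null(xv)) {
      pv <- dms_forward_full(model, xv, training = FALSE)
      cev <- softmax_xent(pv$logits, yv)
      vl <- cev$loss
      va <- mean(max.col(pv$probs, ties.method = "first") - 1L == yv)
    }
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = mean(losses),
                                   train_acc = tr_acc, val_loss = vl,
                                   val_acc = va))
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  acc %.3f  val_loss %s", epoch,
                      mean(losses), tr_acc,
                      if (is.na(vl)) "-" else sprintf("%.4f", vl)))
    }
    if (!is.na(vl) && vl < best_loss) {
      best_loss <- vl; best_model <- model; stall <- 0L
    } else stall <- stall + 1L
    if (!is.null(hp$early_stop) && !is.na(vl) && stall >= hp$early_stop) break
    if (stop_now) break
  }
  if (is.null(xv)) best_model <- model
  list(model = model, best_model = best_model, history = hist)
}

#' Save / load a model checkpoint
#'
#' Weights are serialized with R's native serializer; a sidecar JSON carries
#' the architecture config so summaries are reproducible without loading
#' weights.
#'
#' @param model a `dms_model`.
#' @param path checkpoint file path (`.rds`); `<path>.json` is written
#'   alongside.
#' @return `save_checkpoint`: `path`, invisibly.  `load_checkpoint`: the
#'   restored `dms_model`.
#' @export
save_checkpoint <- function(model, path) {
  stop_if(!inherits(model, "dms_model"), "model must be a dms_model")
  saveRDS(model[c("cfg", "params")], path)
  jsonlite::write_json(unclass(model$cfg), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  raw <- readRDS(path)
  cfg <- do.call(dms_config, unclass(raw$cfg))
  structure(list(cfg = cfg, params = raw$params,
                 summary = dms_model_summary(cfg)),
            class = "dms_model")
}
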