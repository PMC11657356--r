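test_that("split_dataset stratifies, partitions and keeps families together", {
  ds <- tiny_dataset(rep(20L, 5), size = 16L)
  sp <- split_dataset(ds, test_fraction = 0.2, val_fraction = 0.1, seed = 3)
  expect_equal(unname(class_counts(sp$test)), rep(4L, 5))
  expect_equal(unname(class_counts(sp$val)), rep(2L, 5))
  expect_equal(unname(class_counts(sp$train)), rep(14L, 5))

  ids <- lapply(sp, function(d) d$manifest$source_id)
  expect_length(intersect(ids$train, ids$test), 0)
  expect_length(intersect(ids$train, ids$val), 0)
  expect_length(intersect(ids$val, ids$test), 0)
  expect_setequal(unlist(ids), ds$manifest$source_id)

  sp2 <- split_dataset(ds, test_fraction = 0.2, val_fraction = 0.1, seed = 3)
  expect_identical(sp$test$manifest, sp2$test$manifest)

  # augmented children follow their parent's partition
  bal <- balance_dataset(tiny_dataset(c(10L, 4L, 10L, 10L, 10L), size = 16L),
                         10L, augment_config(seed = 5))
  spb <- split_dataset(bal, 0.25, 0, seed = 7)
  fam <- function(d) unique(dmsnet:::root_ids(d))
  expect_length(intersect(fam(spb$train), fam(spb$test)), 0)
})

test_that("training runs, records history and aborts cleanly", {
  ds <- tiny_dataset(c(2L, 2L, 2L, 2L, 2L), size = 16L)
  model <- build_dms_model(tiny_model_cfg(), seed = 2)
  hp <- dms_hyperparams(epochs = 1L, batch_size = 64L, seed = 2)
  res <- train_model(model, ds, NULL, hp)
  expect_equal(nrow(res$history), 1)
  expect_true(all(is.finite(res$history$train_loss)))
})

test_that("learning_rate 0 leaves the weights unchanged", {
  ds <- tiny_dataset(c(2L, 2L, 2L, 2L, 2L), size = 16L)
  model <- build_dms_model(tiny_model_cfg(), seed = 5)
  hp <- dms_hyperparams(learning_rate = 0, epochs = 1L, batch_size = 10L,
                        seed = 5)
  res <- train_model(model, ds, NULL, hp)
  for (nm in names(model$params)) {
    expect_equal(res$model$params[[nm]], model$params[[nm]], tolerance = 1e-14,
                 ignore_attr = TRUE)
  }
})

test_that("training is reproducible under a fixed seed", {
  ds <- tiny_dataset(rep(2L, 5), size = 16L)
  run <- function() {
    model <- build_dms_model(tiny_model_cfg(), seed = 8)
    train_model(model, ds, NULL,
                dms_hyperparams(epochs = 2L, batch_size = 4L, seed = 8))$history
  }
  expect_identical(run(), run())
})

test_that("gradient clipping caps the global norm", {
  g <- list(a = matrix(3, 2, 2), b = rep(4, 3))
  clipped <- dmsnet:::clip_gradients(g, 1)
  norm <- sqrt(sum(unlist(clipped)^2))
  expect_equal(norm, 1, tolerance = 1e-12)
  # direction preserved
  expect_equal(clipped$a / clipped$a[1], g$a / g$a[1])
  expect_identical(dmsnet:::clip_gradients(g, 1e6), g)
})

test_that("checkpoints round-trip weights and config", {
  model <- build_dms_model(tiny_model_cfg(), seed = 12)
  path <- file.path(withr::local_tempdir(), "m.ckpt")
  save_checkpoint(model, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- load_checkpoint(path)
  expect_equal(back$cfg, model$cfg)
  expect_equal(back$params, model$params)
  x <- array(runif(16 * 16), c(16, 16, 1, 1))
  expect_identical(dms_forward(model, x), dms_forward(back, x))
})
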