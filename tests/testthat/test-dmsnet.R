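# Independent parameter-count oracle: iterative accumulation over the
# architecture, sharing no code with dms_model_summary().
oracle_param_count <- function(cfg) {
  gS <- cfg$growth_rate * length(cfg$scales)
  total <- 9 * cfg$stem_channels + cfg$stem_channels
  width <- cfg$stem_channels
  for (b in seq_len(cfg$num_blocks)) {
    for (l in seq_len(cfg$layers_per_block)) {
      total <- total + 2 * width                       # batch norm
      for (k in cfg$scales) total <- total + k^2 * width * cfg$growth_rate +
          cfg$growth_rate
      width <- width + gS                              # dense concat grows
    }
    if (b < cfg$num_blocks) {
      nxt <- max(1, floor(cfg$compression * width))
      total <- total + 2 * width + width * nxt + nxt
      width <- nxt
    }
  }
  total + 2 * width + width * cfg$num_classes + cfg$num_classes  # head
}

test_that("dms_layer_in_channels: closed form matches iterative accumulation", {
  cfg <- dms_config()
  expect_equal(dms_layer_in_channels(cfg, 0, 0), 24)
  expect_equal(dms_layer_in_channels(cfg, 0, 2), 24 + 2 * 36)
  expect_error(dms_layer_in_channels(cfg, 3, 0), "out of range")
  expect_error(dms_layer_in_channels(cfg, 0, 4), "out of range")

  set.seed(31)
  for (i in 1:5) {
    cfg <- dms_config(scales = sort(sample(c(1L, 3L, 5L, 7L), sample(1:3, 1))),
                      growth_rate = sample(1:8, 1),
                      layers_per_block = sample(1:4, 1),
                      num_blocks = sample(1:3, 1),
                      stem_channels = sample(2:16, 1),
                      compression = runif(1, 0.3, 1), input_size = 16L)
    gS <- cfg$growth_rate * length(cfg$scales)
    width <- cfg$stem_channels
    for (b in seq_len(cfg$num_blocks)) {
      for (l in seq_len(cfg$layers_per_block)) {
        expect_equal(dms_layer_in_channels(cfg, b - 1L, l - 1L), width)
        width <- width + gS
      }
      if (b < cfg$num_blocks) width <- max(1L, floor(cfg$compression * width))
    }
    # strictly increasing within every block
    for (b in seq_len(cfg$num_blocks)) {
      w <- vapply(seq_len(cfg$layers_per_block) - 1L, function(l)
        dms_layer_in_channels(cfg, b - 1L, l), integer(1))
      if (length(w) > 1) expect_true(all(diff(w) > 0))
    }
  }
})

test_that("build_dms_block channel bookkeeping", {
  cfg1 <- dms_config(scales = 3L, growth_rate = 4L, layers_per_block = 1L,
                     num_blocks = 1L, stem_channels = 8L, input_size = 16L)
  blk <- build_dms_block(cfg1, 8L)
  expect_equal(blk$out_channels, 12L)

  cfg2 <- dms_config(input_size = 16L, num_blocks = 1L)
  blk2 <- build_dms_block(cfg2, 24L)
  expect_equal(blk2$out_channels, 24L + 4L * 36L)
  expect_equal(vapply(blk2$layers, `[[`, integer(1), "in_channels"),
               c(24L, 60L, 96L, 132L))
})

test_that("parameter count equals the independent oracle for random configs", {
  set.seed(17)
  for (i in 1:6) {
    cfg <- dms_config(scales = sort(sample(c(1L, 3L, 5L), sample(1:3, 1))),
                      growth_rate = sample(1:6, 1),
                      layers_per_block = sample(1:3, 1),
                      num_blocks = sample(1:3, 1),
                      stem_channels = sample(2:12, 1),
                      compression = runif(1, 0.3, 1), input_size = 16L)
    model <- build_dms_model(cfg, seed = i)
    expect_equal(model$summary$n_params, oracle_param_count(cfg))
    expect_equal(dmsnet:::model_param_count(model), oracle_param_count(cfg))
  }
})

test_that("runtime feature-map widths equal dms_layer_in_channels everywhere", {
  cfg <- tiny_model_cfg()
  model <- build_dms_model(cfg, seed = 4)
  x <- array(runif(16 * 16 * 2), c(16, 16, 1, 2))
  fw <- dmsnet:::dms_forward_full(model, x, trace = TRUE)
  for (b in seq_len(cfg$num_blocks)) {
    for (l in seq_len(cfg$layers_per_block)) {
      xin <- fw$trace$layer_inputs[[sprintf("b%d.l%d", b, l)]]
      expect_equal(dim(xin)[3], dms_layer_in_channels(cfg, b - 1L, l - 1L))
    }
  }
  expect_equal(dim(fw$trace$final_features)[3], model$summary$final_channels)
})

test_that("single-scale compression-1 config reduces to the plain dense formula", {
  cfg <- dms_config(scales = 3L, growth_rate = 5L, layers_per_block = 3L,
                    num_blocks = 1L, stem_channels = 7L, compression = 1,
                    input_size = 16L)
  widths <- vapply(0:2, function(l) dms_layer_in_channels(cfg, 0L, l), integer(1))
  expect_equal(widths, 7L + (0:2) * 5L)   # k0 + l*g, the DenseNet recurrence
})

test_that("forward output is a probability matrix with batch equivariance", {
  model <- build_dms_model(tiny_model_cfg(), seed = 9)
  x0 <- matrix(0, 16, 16)
  p <- dms_forward(model, x0)
  expect_identical(dim(p), c(1L, 5L))
  expect_true(all(is.finite(p)))
  expect_equal(sum(p), 1, tolerance = 1e-6)

  set.seed(2)
  imgs <- array(runif(16 * 16 * 3), c(16, 16, 1, 3))
  batch <- array(imgs[, , , c(1, 2, 3, 1)], c(16, 16, 1, 4))
  pb <- dms_forward(model, batch)
  expect_equal(rowSums(pb), rep(1, 4), tolerance = 1e-6)
  expect_equal(pb[1, ], pb[4, ], tolerance = 1e-12)     # identical inputs
  perm <- dms_forward(model, array(imgs[, , , c(3, 1, 2)], c(16, 16, 1, 3)))
  expect_equal(perm, pb[c(3, 1, 2), ], tolerance = 1e-12)
  expect_error(dms_forward(model, matrix(0, 8, 8)), "expects")
})

test_that("zeroing a layer's output slice affects later layers only", {
  cfg <- tiny_model_cfg()
  model <- build_dms_model(cfg, seed = 21)
  x <- array(runif(16 * 16), c(16, 16, 1, 1))
  base <- dmsnet:::dms_forward_full(model, x, trace = TRUE)$trace$layer_inputs
  for (b0 in 1:2) for (l0 in 1:2) {
    abl <- dmsnet:::dms_forward_full(model, x, trace = TRUE,
                                     ablate = list(block = b0, layer = l0))
    ab <- abl$trace$layer_inputs
    for (b in 1:2) for (l in 1:2) {
      id <- sprintf("b%d.l%d", b, l)
      after <- (b > b0) || (b == b0 && l > l0)
      if (after) {
        expect_gt(max(abs(ab[[id]] - base[[id]])), 0)
      } else {
        expect_identical(ab[[id]], base[[id]])
      }
    }
  }
})

test_that("every parameter receives a finite nonzero gradient", {
  model <- build_dms_model(tiny_model_cfg(), seed = 33)
  set.seed(33)
  x <- array(runif(16 * 16 * 4), c(16, 16, 1, 4))
  y <- c(0L, 1L, 3L, 4L)
  out <- dmsnet:::dms_loss_grad(model, x, y)
  expect_true(is.finite(out$loss))
  expect_setequal(names(out$grads), names(model$params))
  for (nm in names(out$grads)) {
    g <- out$grads[[nm]]
    expect_true(all(is.finite(g)), info = nm)
    expect_gt(max(abs(g)), 0, label = sprintf("max |grad| of %s", nm))
  }
})

test_that("input size must accommodate the transition downsamplings", {
  expect_error(dms_config(num_blocks = 3L, input_size = 18L), "divisible")
  expect_s3_class(dms_config(num_blocks = 3L, input_size = 20L), "dms_config")
})
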