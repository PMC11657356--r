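cam_fixture <- function(seed = 14) {
  # one block, no downsampling: feature maps stay at input resolution, so the
  # upsampling step is an exact identity and oracles are directly comparable
  cfg <- dms_config(scales = 3L, growth_rate = 1L, layers_per_block = 1L,
                    num_blocks = 1L, stem_channels = 2L, input_size = 12L)
  model <- build_dms_model(cfg, seed = seed)
  set.seed(seed)
  img <- graded_image(matrix(runif(144), 12, 12), 1, "toy")
  list(model = model, img = img)
}

test_that("activation_map satisfies determinism, bounds and shape", {
  fx <- cam_fixture()
  m1 <- activation_map(fx$model, fx$img)
  m2 <- activation_map(fx$model, fx$img)
  expect_identical(m1$heat, m2$heat)
  expect_identical(dim(m1$heat), dim(fx$img$pixels))
  expect_gte(min(m1$heat), 0)
  expect_lte(max(m1$heat), 1)
  expect_equal(max(m1$heat), 1)   # nonzero map is max-normalized
  expect_equal(m1$method, "plain")
})

test_that("an all-zero final stage yields an all-zero map without NaN", {
  fx <- cam_fixture()
  # zero every path into the final features: stem and the dense layer convs
  for (nm in grep("^(stem|b1\\.l1\\.s)", names(fx$model$params), value = TRUE)) {
    fx$model$params[[nm]][] <- 0
  }
  m <- activation_map(fx$model, fx$img)
  expect_true(all(m$heat == 0))
  g <- grad_cam(fx$model, fx$img, 2)
  expect_true(all(is.finite(g$heat)))
  expect_true(all(g$heat == 0))
})

test_that("grad_cam matches the hand-derived chain-rule oracle", {
  fx <- cam_fixture()
  model <- fx$model
  img <- fx$img
  fw <- dmsnet:::dms_forward_full(model, dmsnet:::as_batch_array(img),
                                  trace = TRUE)
  feats <- fw$trace$final_features            # (12, 12, 3, 1)
  d <- dim(feats)
  hw <- d[1] * d[2]
  for (target in c(0L, 3L)) {
    # head is GAP -> linear, so d(logit_k)/d(feat[h,w,c]) = W[k,c]/HW at
    # every position; the channel weights are exactly W[k,c]/HW.
    wrow <- model$params[["head.w"]][target + 1L, ]
    alpha <- wrow / hw
    raw <- matrix(0, d[1], d[2])
    for (c_ in seq_len(d[3])) raw <- raw + alpha[c_] * feats[, , c_, 1]
    raw <- pmax(raw, 0)
    expected <- if (max(raw) > 0) raw / max(raw) else raw

    got <- grad_cam(model, img, target)
    expect_equal(got$heat, expected, tolerance = 1e-6)
    expect_identical(got$heat, grad_cam(model, img, target)$heat)
  }
  expect_error(grad_cam(model, img, 7), "out of range")
})

test_that("a single positively-weighted channel reproduces its feature map", {
  fx <- cam_fixture(seed = 6)
  model <- fx$model
  model$params[["head.w"]][] <- 0
  model$params[["head.w"]][3, 2] <- 1.5     # class 2 reads only channel 2
  fw <- dmsnet:::dms_forward_full(model, dmsnet:::as_batch_array(fx$img),
                                  trace = TRUE)
  feat <- fw$trace$final_features[, , 2, 1]
  raw <- pmax(feat, 0)
  expected <- if (max(raw) > 0) raw / max(raw) else raw
  got <- grad_cam(model, fx$img, 2)
  expect_equal(got$heat, expected, tolerance = 1e-10)
})

test_that("overlay blends correctly at the alpha extremes", {
  img <- synth_radiograph(1, tiny_spec(16L), seed = 2)
  heat <- matrix(runif(256), 16, 16)
  ov0 <- overlay(img, heat, alpha = 0)
  expect_identical(dim(ov0), c(16L, 16L, 3L))
  expect_true(is.integer(ov0))
  for (ch in 1:3) {
    expect_equal(ov0[, , ch], matrix(as.integer(round(img$pixels * 255)), 16, 16))
  }
  ov1 <- overlay(img, heat, alpha = 1)
  cmap <- dmsnet:::heat_colormap(as.vector(heat))
  expect_equal(ov1[, , 1], matrix(as.integer(round(cmap[, 1] * 255)), 16, 16))
  expect_error(overlay(img, matrix(0, 4, 4), 0.5), "shapes differ")
  expect_true(all(ov1 >= 0 & ov1 <= 255))
})
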