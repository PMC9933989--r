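# Small configurations keep these structural checks fast; the full
# variant x size x temporal grid is exercised in the acceptance suite.

test_that("every 2D variant emits maps at the input resolution", {
  for (variant in c("v2a", "v2b", "v2c", "v2d", "v2e", "v1_regression")) {
    m <- build_model(model_config(variant, base_filters = 2,
                                  input_size = c(48, 32), seed = 1))
    out <- predict_frame(m, array(0.1, c(48, 32, 1)))
    expect_equal(dim(out$seg), c(48, 32, 1))
    if (variant == "v1_regression") {
      expect_length(out$points, 4)
      expect_true(all(is.finite(out$points)))
    } else {
      expect_equal(dim(out$keypoint_maps), c(48, 32, 2))
      expect_true(all(out$keypoint_maps >= 0 & out$keypoint_maps <= 1))
    }
    expect_true(all(out$seg >= 0 & out$seg <= 1))
  }
})

test_that("the v2c variant has three output heads", {
  m <- build_model(model_config("v2c", base_filters = 2,
                                input_size = c(32, 32), seed = 1))
  heads <- grep("_head", names(m$ps$params), value = TRUE)
  expect_setequal(unique(sub("\\..*", "", heads)),
                  c("seg_head", "ap_head", "pp_head"))
})

test_that("both v2e decoders read the same latent representation", {
  # one shared encoder: encoder/latent weights exist once, decoder weights
  # exist per task
  m <- build_model(model_config("v2e", base_filters = 2,
                                input_size = c(32, 32), seed = 1))
  nms <- names(m$ps$params)
  expect_length(grep("^latent\\.c1\\.w$", nms), 1)
  expect_length(grep("^enc1\\.c1\\.w$", nms), 1)
  expect_true(any(startsWith(nms, "dseg4")))
  expect_true(any(startsWith(nms, "dkp4")))
  # and the latent weights receive gradient from both heads
  tape <- midlinenet:::new_tape()
  out <- midlinenet:::model_forward(m, array(0.1, c(32, 32, 1)), tape,
                                    training = TRUE)
  l <- midlinenet:::op_wsum(tape,
    list(midlinenet:::op_dice_loss(tape, out$seg, array(1, c(32, 32, 1))),
         midlinenet:::op_mse_loss(tape, out$kp, array(0, c(32, 32, 2)))),
    c(1, 1))
  g <- midlinenet:::tp_backward(tape, l)
  expect_true("latent.c1.w" %in% names(g))
  expect_gt(max(abs(g[["latent.c1.w"]])), 0)
})

test_that("parameter counts are deterministic and monotone in width", {
  c8 <- count_parameters(build_model(model_config("v2e", base_filters = 4,
                                                  input_size = c(32, 32))))
  c16 <- count_parameters(build_model(model_config("v2e", base_filters = 8,
                                                   input_size = c(32, 32))))
  expect_gt(c16, c8)
  again <- count_parameters(build_model(model_config("v2e", base_filters = 4,
                                                     input_size = c(32, 32))))
  expect_identical(c8, again)
  # the dual decoder costs parameters over the shared-decoder variant
  ca <- count_parameters(build_model(model_config("v2a", base_filters = 4,
                                                  input_size = c(32, 32))))
  expect_gt(c8, ca)
})

test_that("temporal variants emit per-frame (or centre-frame) outputs", {
  mch <- build_temporal_model(model_config("v2e", temporal_mode = "channels",
                                           base_filters = 2, n_frames = 4,
                                           input_size = c(32, 32), seed = 1))
  o <- predict_frame(mch, array(0.1, c(32, 32, 4)))
  expect_equal(dim(o$seg), c(32, 32, 1))
  expect_equal(dim(o$keypoint_maps), c(32, 32, 2))
  for (mode in c("conv3d", "convlstm")) {
    m <- build_temporal_model(model_config("v2e", temporal_mode = mode,
                                           base_filters = 2, n_frames = 3,
                                           input_size = c(32, 32), seed = 1))
    o <- predict_frame(m, array(0.1, c(32, 32, 3, 1)))
    expect_equal(dim(o$seg), c(32, 32, 3, 1))
    expect_equal(dim(o$keypoint_maps), c(32, 32, 3, 2))
    expect_true(all(o$seg >= 0 & o$seg <= 1))
  }
})

test_that("invalid configurations are rejected with clear messages", {
  expect_error(model_config("v9"), "unknown variant")
  expect_error(model_config("v2e", input_size = c(30, 32)), "divisible")
  expect_error(model_config("v2e", temporal_mode = "conv3d"), "n_frames")
  expect_error(model_config("v2a", temporal_mode = "conv3d", n_frames = 3),
               "v2e")
  expect_error(build_temporal_model(model_config("v2e")), "temporal_mode")
})

test_that("models round-trip through save/load", {
  root <- withr::local_tempdir()
  m <- build_model(model_config("v2b", base_filters = 2,
                                input_size = c(32, 32), seed = 3))
  x <- array(rnorm(32 * 32, sd = 0.2), c(32, 32, 1))
  before <- predict_frame(m, x)
  p <- file.path(root, "model.rds")
  save_model(m, p)
  expect_true(file.exists(file.path(root, "model_config.json")))
  m2 <- load_model(p)
  after <- predict_frame(m2, x)
  expect_equal(after$seg, before$seg, tolerance = 1e-12)
  expect_equal(count_parameters(m2), count_parameters(m))
})
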