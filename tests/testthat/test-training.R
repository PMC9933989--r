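test_that("dice loss matches its formula on canonical cases and the oracle", {
  a <- matrix(0, 10, 20); a[2:6, 3:22 - 2] <- 1
  expect_lte(dice_loss(a, a), 1 / (2 * sum(a) + 1))
  p <- matrix(0, 20, 20); p[1:5, 1:20] <- 1        # 100 px
  q <- matrix(0, 20, 20); q[11:15, 1:20] <- 1      # disjoint 100 px
  expect_equal(dice_loss(p, q), 1 - 1 / 201)
  set.seed(13)
  for (k in 1:100) {
    pr <- matrix(runif(48), 6, 8)
    tr <- matrix(rbinom(48, 1, 0.4), 6, 8)
    expect_equal(dice_loss(pr, tr), oracle_dice(pr, tr), tolerance = 1e-6)
  }
  expect_error(dice_loss(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("half-intensity predictions give the analytic dice value", {
  tr <- matrix(0, 8, 8); tr[1:4, 1:8] <- 1         # N = 32 of 2N = 64 px
  pr <- matrix(0.5, 8, 8)
  expect_equal(dice_loss(pr, tr), oracle_dice(pr, tr), tolerance = 1e-12)
})

test_that("keypoint loss is the elementwise MSE", {
  t0 <- array(rbinom(32, 1, 0.3), c(4, 4, 2))
  expect_equal(keypoint_loss(t0, t0), 0)
  expect_equal(keypoint_loss(1 - t0, t0), 1)
  set.seed(17)
  for (k in 1:100) {
    p <- array(runif(32), c(4, 4, 2))
    expect_equal(keypoint_loss(p, t0), oracle_mse(p, t0), tolerance = 1e-6)
  }
})

test_that("the combined loss is the stated weighted sum", {
  out <- list(seg = matrix(runif(16), 4, 4),
              kp = array(runif(32), c(4, 4, 2)))
  tgt <- list(seg = matrix(rbinom(16, 1, 0.5), 4, 4),
              kp = array(rbinom(32, 1, 0.2), c(4, 4, 2)))
  expect_equal(combined_loss(out, tgt, c(1, 0)), dice_loss(out$seg, tgt$seg))
  expect_equal(combined_loss(out, tgt, c(0, 1)), keypoint_loss(out$kp, tgt$kp))
  expect_equal(combined_loss(out, tgt, c(1, 1)),
               dice_loss(out$seg, tgt$seg) + keypoint_loss(out$kp, tgt$kp))
  expect_error(combined_loss(out, tgt, c(-1, 1)), "nonnegative")
})

test_that("learning-rate policies follow their definitions", {
  expect_equal(lr_schedule("constant", 2e-4, 17), 2e-4)
  expect_equal(lr_schedule("exp_decay", 1e-3, 0), 1e-3)
  expect_equal(lr_schedule("exp_decay", 1e-3, 5), 1e-3 * 0.95^5)
  expect_equal(lr_schedule("scheduler1", 1e-3, 10), 5e-4)
  expect_equal(lr_schedule("scheduler1", 1e-3, 9), 1e-3)
  expect_equal(lr_schedule("scheduler2", 9e-4, 0), 3e-4)   # warmup 1/3
  expect_equal(lr_schedule("scheduler2", 9e-4, 2), 9e-4)   # warmup done
  expect_lt(lr_schedule("scheduler2", 9e-4, 10), 9e-4)
  expect_error(lr_schedule("bogus", 1e-3, 1), "policy")
})

test_that("horizontal flips transform image, mask, maps and points together", {
  s <- tiny_prepared(2)
  W <- ncol(s$image)
  f <- augment_sample(s, augment_config(ops = "horizontal_flip", prob = 1),
                      seed = 1)
  expect_equal(f$ap[1], W - 1 - s$ap[1])
  expect_equal(f$image, s$image[, W:1])
  expect_equal(f$mask, s$mask[, W:1])
  kp <- decode_keypoints(f$target_maps)
  expect_lt(max(abs(kp$ap - f$ap)), 0.5)
  # flipping twice is the identity
  ff <- augment_sample(f, augment_config(ops = "horizontal_flip", prob = 1),
                       seed = 1)
  expect_equal(ff$image, s$image)
  expect_equal(ff$ap, s$ap)
})

test_that("rotations keep points and rebuilt maps consistent", {
  set.seed(23)
  s <- tiny_prepared(3)
  for (k in 1:20) {
    r <- augment_sample(s, augment_config(ops = "rotation", prob = 1),
                        seed = 100 + k)
    kp <- decode_keypoints(r$target_maps)
    expect_lt(max(abs(kp$ap - r$ap)), 0.5)
    expect_lt(max(abs(kp$pp - r$pp)), 0.5)
    # rotated mask centroid should track the rotated points' midpoint roughly
    expect_true(all(r$ap >= 0 & r$ap <= c(ncol(r$image) - 1, nrow(r$image) - 1)))
  }
  # zero-degree rotation is the identity on points
  r0 <- midlinenet:::rotate_sample(s, 0)
  expect_equal(r0$ap, s$ap, tolerance = 1e-12)
  expect_equal(r0$image, s$image, tolerance = 1e-9)
})

test_that("photometric augmentations leave geometry untouched", {
  s <- tiny_prepared(4)
  a <- augment_sample(s, augment_config(ops = c("blur", "random_gamma",
                                                "gaussian_noise"), prob = 1),
                      seed = 5)
  expect_identical(a$ap, s$ap)
  expect_identical(a$mask, s$mask)
  expect_identical(a$target_maps, s$target_maps)
  expect_false(identical(a$image, s$image))
  expect_true(all(a$image >= -1 & a$image <= 1))
})

test_that("augment_dataset expands by the configured factor", {
  s <- tiny_prepared(5)
  out <- augment_dataset(list(s, s), augment_config(augment_factor = 3), seed = 1)
  expect_length(out, 6)
  expect_identical(out[[1]], s)
})

test_that("the autodiff training gradients match finite differences", {
  set.seed(33)
  m <- build_model(model_config("v2b", base_filters = 2,
                                input_size = c(16, 16), seed = 2))
  x <- array(rnorm(256, sd = 0.5), c(16, 16, 1))
  seg <- array(rbinom(256, 1, 0.3), c(16, 16, 1))
  kp <- array(rbinom(512, 1, 0.1), c(16, 16, 2))
  loss_at <- function() {
    tape <- midlinenet:::new_tape()
    out <- midlinenet:::model_forward(m, x, tape, training = TRUE)
    l <- midlinenet:::op_wsum(tape,
      list(midlinenet:::op_dice_loss(tape, out$seg, seg),
           midlinenet:::op_mse_loss(tape, out$kp, kp)), c(1, 1))
    list(value = l$value, grads = midlinenet:::tp_backward(tape, l))
  }
  base <- loss_at()
  eps <- 1e-5
  for (nm in c("enc1.c1.w", "latent.c2.w", "seg_head.w", "dec4.n1.g")) {
    g <- base$grads[[nm]]
    idx <- sample(length(g), min(3, length(g)))
    for (i in idx) {
      orig <- m$ps$params[[nm]][i]
      m$ps$params[[nm]][i] <- orig + eps
      up <- loss_at()$value
      m$ps$params[[nm]][i] <- orig - eps
      dn <- loss_at()$value
      m$ps$params[[nm]][i] <- orig
      expect_equal(g[i], (up - dn) / (2 * eps), tolerance = 1e-4)
    }
  }
})

test_that("short training runs are deterministic and track history", {
  vids <- generate_dataset(3, small_gen_ranges(), seed = 41)
  samples <- prepare_all(vids, c(32, 32), 2)
  m1 <- build_model(model_config("v2a", base_filters = 2,
                                 input_size = c(32, 32), seed = 7))
  cfg <- train_config(epochs = 1, lr0 = 1e-3, batch_size = 4,
                      val_fraction = 0.34, seed = 3)
  f1 <- train_model(m1, samples, cfg)
  expect_equal(nrow(f1$history), 1)
  expect_true(all(is.finite(unlist(f1$history))))
  m2 <- build_model(model_config("v2a", base_filters = 2,
                                 input_size = c(32, 32), seed = 7))
  f2 <- train_model(m2, samples, cfg)
  expect_identical(f1$history, f2$history)
  expect_error(train_model(m1, list(), cfg), "empty")
})

test_that("the regression baseline and temporal models also train end to end", {
  vids <- generate_dataset(3, small_gen_ranges(), seed = 47)
  samples <- prepare_all(vids, c(32, 32), 2)
  mv1 <- build_model(model_config("v1_regression", base_filters = 2,
                                  input_size = c(32, 32), seed = 1))
  cfg <- train_config(epochs = 1, lr0 = 1e-3, batch_size = 4,
                      val_fraction = 0.34, seed = 2)
  f <- train_model(mv1, samples, cfg)
  expect_true(all(is.finite(unlist(f$history))))
  m3d <- build_temporal_model(model_config("v2e", temporal_mode = "conv3d",
                                           base_filters = 2, n_frames = 5,
                                           input_size = c(32, 32), seed = 1))
  f3 <- train_model(m3d, samples, cfg)      # 10-frame videos -> 2 clips each
  expect_true(all(is.finite(unlist(f3$history))))
  expect_equal(nrow(f3$history), 1)
})

test_that("the validation split is video-disjoint and close to its target", {
  vids <- generate_dataset(10, small_gen_ranges(), seed = 43)
  samples <- prepare_all(vids, c(32, 32), 2)      # 10 videos x 10 frames
  tset <- midlinenet:::as_training_set(samples,
                                       model_config("v2a", base_filters = 2,
                                                    input_size = c(32, 32)))
  set.seed(1)
  sp <- midlinenet:::split_by_video(tset, 0.10)
  expect_length(sp$val, 10)                        # floor(0.10 * 100)
  val_vids <- unique(vapply(tset[sp$val], `[[`, character(1), "video_id"))
  train_vids <- unique(vapply(tset[sp$train], `[[`, character(1), "video_id"))
  expect_length(intersect(val_vids, train_vids), 0)
})
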