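test_that("decoding recovers disk centers and single pixels", {
  maps <- array(0, c(30, 30, 2))
  maps[, , 1] <- make_target_map(c(10, 10), c(30, 30), 2)
  maps[8, 4, 2] <- 0.7                # single pixel at (x=3, y=7)
  kp <- decode_keypoints(maps)
  expect_equal(kp$ap, c(10, 10))
  expect_equal(kp$pp, c(3, 7))
})

test_that("ambiguous two-pixel maps decode to the weighted centroid", {
  maps <- array(0, c(10, 10, 2))
  maps[1, 1, 1] <- 0.8                # (0, 0)
  maps[1, 5, 1] <- 0.8                # (4, 0)
  maps[3, 3, 2] <- 1
  expect_equal(decode_keypoints(maps)$ap, c(2, 0))
})

test_that("all-zero channels raise an error naming the channel", {
  maps <- array(0, c(10, 10, 2))
  maps[3, 3, 1] <- 1
  expect_error(decode_keypoints(maps), "posterior")
})

test_that("argmax decoding returns the first maximum in row-major order", {
  maps <- array(0, c(10, 10, 2))
  maps[2, 6, 1] <- 1; maps[5, 2, 1] <- 1
  maps[4, 4, 2] <- 1
  kp <- decode_keypoints(maps, method = "argmax")
  expect_equal(kp$ap, c(5, 1))        # row 2 comes before row 5
})

test_that("decode inverts encode within half a pixel for all studied radii", {
  set.seed(21)
  for (r in c(5, 8, 10, 12, 15, 20)) {
    for (k in 1:10) {
      p1 <- c(runif(1, r, 63 - r), runif(1, r, 63 - r))
      p2 <- c(runif(1, r, 63 - r), runif(1, r, 63 - r))
      maps <- array(0, c(64, 64, 2))
      maps[, , 1] <- make_target_map(p1, c(64, 64), r)
      maps[, , 2] <- make_target_map(p2, c(64, 64), r)
      kp <- decode_keypoints(maps)
      expect_lt(max(abs(kp$ap - p1)), 0.5)
      expect_lt(max(abs(kp$pp - p2)), 0.5)
    }
  }
})

test_that("midline direction is the unit vector from pp to ap", {
  m <- midline_from_points(c(0, 0), c(0, 10))
  expect_equal(m$direction, c(0, -1))
  expect_equal(midline_from_points(c(3, 4), c(0, 0))$direction, c(0.6, 0.8))
  expect_equal(midline_from_points(c(0, 0), c(3, 4))$direction, c(-0.6, -0.8))
  expect_error(midline_from_points(c(1, 1), c(1, 1)), "coincide")
})

test_that("moving median matches the pad-sort-select oracle", {
  tr <- data.frame(ap_x = c(0, 10, 0), ap_y = 0, pp_x = 0, pp_y = 0)
  expect_equal(moving_median_filter(tr, 3)$ap_x, c(0, 0, 0))
  set.seed(31)
  for (k in 1:10) {
    T_ <- sample(2:40, 1)
    x <- rnorm(T_)
    for (w in 1:18) {
      got <- suppressWarnings(moving_median_filter(
        data.frame(ap_x = x, ap_y = 0, pp_x = 0, pp_y = 0), w))$ap_x
      expect_identical(got, oracle_moving_median(x, w))
    }
  }
})

test_that("filtering preserves length, identity cases and warns on huge windows", {
  tr <- data.frame(ap_x = rnorm(8), ap_y = rnorm(8), pp_x = rnorm(8),
                   pp_y = rnorm(8))
  expect_identical(moving_median_filter(tr, 1), tr)
  const <- data.frame(ap_x = rep(2, 6), ap_y = rep(3, 6), pp_x = rep(4, 6),
                      pp_y = rep(5, 6))
  for (w in c(2, 5, 12)) expect_equal(moving_median_filter(const, w), const)
  expect_equal(nrow(moving_median_filter(tr, 18)), 8)
  expect_warning(moving_median_filter(tr, 40), "padding")
  expect_error(moving_median_filter(tr, 0), "window")
})

test_that("median filtering shrinks jitter on noisy constant trajectories", {
  set.seed(9)
  truth <- list(ap = c(20, 10), pp = c(22, 48))
  worse <- 0
  for (k in 1:10) {
    tr <- data.frame(ap_x = truth$ap[1] + rnorm(30, sd = 3),
                     ap_y = truth$ap[2] + rnorm(30, sd = 3),
                     pp_x = truth$pp[1] + rnorm(30, sd = 3),
                     pp_y = truth$pp[2] + rnorm(30, sd = 3))
    j0 <- trajectory_jitter(tr, truth)
    j1 <- trajectory_jitter(moving_median_filter(tr, 12), truth)
    if (j1$ap_std >= j0$ap_std || j1$pp_std >= j0$pp_std) worse <- worse + 1
  }
  expect_lte(worse, 1)
})

test_that("predict_video returns one decoded point pair per frame", {
  cfg <- model_config("v2a", base_filters = 2, input_size = c(32, 32), seed = 1)
  model <- build_model(cfg)
  frames <- lapply(1:5, function(i) matrix(rnorm(32 * 32, sd = 0.1), 32, 32))
  out <- predict_video(model, frames, window = 1)
  expect_equal(nrow(out$trajectory), 5)
  expect_equal(dim(out$seg_maps), c(32, 32, 5))
  expect_identical(out$trajectory, out$raw_trajectory)
  out12 <- predict_video(model, frames, window = 3)
  expect_equal(nrow(out12$trajectory), 5)
})
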