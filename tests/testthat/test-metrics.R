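test_that("mape matches the loop oracle and its printed examples", {
  expect_equal(mape(c(110, 110, 110, 110), c(100, 100, 100, 100)), 10)
  expect_equal(mape(c(3, 4), c(3, 4)), 0)
  set.seed(11)
  for (k in 1:100) {
    true <- runif(4, 1, 200)
    pred <- true + rnorm(4, sd = 5)
    expect_equal(mape(pred, true), oracle_mape(pred, true), tolerance = 1e-9)
  }
  expect_error(mape(c(1, 2), c(0, 2)), "1-based")
  expect_error(mape(1:3, 1:4), "length")
})

test_that("mape is invariant under joint coordinate scaling", {
  set.seed(2)
  true <- runif(4, 10, 100)
  pred <- true * runif(4, 0.9, 1.1)
  expect_equal(mape(2 * pred, 2 * true), mape(pred, true), tolerance = 1e-12)
})

test_that("iou matches the counting oracle, is symmetric, handles empties", {
  a <- matrix(0, 8, 8); a[2:3, 2:3] <- 1       # 4 px
  b <- matrix(0, 8, 8); b[2:5, 2:3] <- 1       # 8 px, superset
  expect_equal(iou(a, b), 0.5)
  expect_equal(iou(a, a), 1)
  d <- matrix(0, 8, 8); d[7:8, 7:8] <- 1
  expect_equal(iou(a, d), 0)
  expect_equal(iou(a * 0, a * 0), 1)
  set.seed(4)
  for (k in 1:100) {
    x <- matrix(rbinom(36, 1, 0.4), 6, 6)
    y <- matrix(rbinom(36, 1, 0.4), 6, 6)
    expect_equal(iou(x, y), oracle_iou(x, y), tolerance = 1e-12)
    expect_identical(iou(x, y), iou(y, x))
  }
})

test_that("trajectory jitter equals the population std of distances", {
  traj <- data.frame(ap_x = c(10, 10, 10, 10), ap_y = c(5, 7, 5, 7),
                     pp_x = rep(3, 4), pp_y = rep(9, 4))
  true <- list(ap = c(10, 5), pp = c(3, 9))
  j <- trajectory_jitter(traj, true)
  expect_equal(j$ap_std, 1)           # distances alternate 0, 2
  expect_equal(j$pp_std, 0)
  set.seed(8)
  for (k in 1:20) {
    tr <- data.frame(ap_x = rnorm(9, 20), ap_y = rnorm(9, 30),
                     pp_x = rnorm(9, 22), pp_y = rnorm(9, 50))
    d <- sqrt((tr$ap_x - 20)^2 + (tr$ap_y - 30)^2)
    expect_equal(trajectory_jitter(tr, list(ap = c(20, 30), pp = c(22, 50)))$ap_std,
                 oracle_pop_sd(d), tolerance = 1e-9)
  }
  expect_error(trajectory_jitter(traj[1, ], true), "2 frames")
})

test_that("score summaries use interpolated quantiles and stay ordered", {
  s <- summarize_scores(c(1, 2, 3, 4))
  expect_equal(s$median, 2.5)
  expect_equal(s$q1, 1.75)
  expect_equal(s$q3, 3.25)
  one <- summarize_scores(5)
  expect_true(all(unlist(one) == 5))
  set.seed(6)
  for (k in 1:20) {
    x <- rexp(sample(3:40, 1))
    s <- summarize_scores(x)
    expect_true(s$min <= s$q1 && s$q1 <= s$median &&
                  s$median <= s$q3 && s$q3 <= s$max)
    expect_equal(s$q1, oracle_quantile(x, 0.25), tolerance = 1e-9)
    expect_equal(s$median, oracle_quantile(x, 0.5), tolerance = 1e-9)
  }
  expect_error(summarize_scores(numeric()), "empty")
})

test_that("eval_report aggregates MAPE, IoU and jitter", {
  true_pts <- matrix(runif(20, 10, 50), 5, 4)
  rep <- eval_report(true_pts, true_pts,
                     pred_masks = list(matrix(1, 4, 4)),
                     true_masks = list(matrix(1, 4, 4)))
  expect_equal(rep$mape_summary$median, 0)
  expect_equal(rep$mean_iou, 1)
})
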