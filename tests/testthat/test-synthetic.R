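test_that("identical parameters reproduce a bit-identical video", {
  v1 <- tiny_video(7)
  v2 <- tiny_video(7)
  expect_identical(v1, v2)
  v3 <- tiny_video(8)
  expect_false(identical(v1$frames[[2]]$image, v3$frames[[2]]$image))
})

test_that("the glottis is closed at phase zero and oscillates unimodally", {
  v <- generate_video(tiny_params(1, n_frames = 12, cycle_frames = 12,
                                  noise_sd = 0))
  areas <- vapply(v$frames, function(f) sum(f$mask), numeric(1))
  expect_equal(areas[1], 0)
  half <- areas[1:7]                  # phase 0 .. pi over one half-cycle
  peak <- which.max(half)
  expect_true(all(diff(half[1:peak]) >= 0))
  expect_true(all(diff(half[peak:7]) <= 0))
})

test_that("mask centroid stays on the anterior-posterior axis", {
  for (seed in 1:3) {
    v <- generate_video(tiny_params(seed, midline_angle = c(-20, 10, 25)[seed],
                                    noise_sd = 0))
    for (f in v$frames) {
      if (sum(f$mask) == 0) next
      cx <- mean(col(f$mask)[f$mask == 1] - 1)
      cy <- mean(row(f$mask)[f$mask == 1] - 1)
      # brute-force distance from the centroid to the ap-pp segment
      ab <- f$pp - f$ap
      t_ <- ((c(cx, cy) - f$ap) %*% ab) / sum(ab^2)
      t_ <- min(max(t_, 0), 1)
      proj <- f$ap + as.numeric(t_) * ab
      expect_lt(sqrt(sum((c(cx, cy) - proj)^2)), 2)
    }
  }
})

test_that("annotated points are the lens tips and constant across frames", {
  v <- tiny_video(3)
  expect_true(all(vapply(v$frames, function(f) identical(f$ap, v$ap), logical(1))))
  expect_true(all(vapply(v$frames, function(f) identical(f$pp, v$pp), logical(1))))
  # tips lie at distance glottis_length along the configured axis
  expect_equal(sqrt(sum((v$ap - v$pp)^2)), v$params$glottis_length)
  # mask pixels nearest to each tip are within rasterization distance
  open_frame <- v$frames[[4]]
  px <- cbind(col(open_frame$mask)[open_frame$mask == 1] - 1,
              row(open_frame$mask)[open_frame$mask == 1] - 1)
  d_ap <- min(sqrt(rowSums(sweep(px, 2, v$ap)^2)))
  d_pp <- min(sqrt(rowSums(sweep(px, 2, v$pp)^2)))
  expect_lt(d_ap, 2)
  expect_lt(d_pp, 2)
})

test_that("invalid parameters raise errors naming the offending field", {
  expect_error(synth_params(glottis_length = 200), "glottis_length")
  expect_error(synth_params(max_half_width = 0.5), "max_half_width")
  expect_error(synth_params(cycle_frames = 1), "cycle_frames")
  expect_error(synth_params(n_frames = 0), "n_frames")
  expect_error(generate_video(tiny_params(1, midline_center = c(2, 2))),
               "midline_center")
})

test_that("generate_dataset is reproducible and draws within ranges", {
  d1 <- generate_dataset(3, small_gen_ranges(), seed = 5)
  d2 <- generate_dataset(3, small_gen_ranges(), seed = 5)
  expect_identical(d1, d2)
  expect_length(d1, 3)
  d3 <- generate_dataset(3, small_gen_ranges(), seed = 6)
  expect_false(identical(d1[[1]]$frames[[2]]$image, d3[[1]]$frames[[2]]$image))
  for (v in d1) {
    expect_length(v$frames, 10)
    expect_gte(v$params$glottis_length, 22)
    expect_lte(v$params$glottis_length, 30)
  }
  expect_error(generate_dataset(0), "n_videos")
  expect_error(generate_dataset(2, list(glottis_length = numeric())),
               "glottis_length")
})

test_that("a dataset at study scale has the right shape", {
  # the video-snippet corpus scale: 532 training videos of 30 frames each
  # (tiny 24 x 24 frames keep the sweep cheap; the geometry is unchanged)
  d <- generate_dataset(532, list(height = 24, width = 24, n_frames = 30,
                                  cycle_frames = 15,
                                  glottis_length = c(12, 16),
                                  max_half_width = c(2, 4),
                                  noise_sd = 0.02), seed = 2)
  expect_length(d, 532)
  expect_true(all(vapply(d, function(v) length(v$frames), numeric(1)) == 30))
})
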