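# Small fixtures built in code at test time.

tiny_params <- function(seed = 1, ...) {
  args <- list(height = 64, width = 48, n_frames = 6, cycle_frames = 6,
               glottis_length = 40, max_half_width = 8, noise_sd = 0.02,
               seed = seed)
  args[names(list(...))] <- list(...)
  do.call(synth_params, args)
}

tiny_video <- function(seed = 1, ...) generate_video(tiny_params(seed, ...))

# One prepared frame with an open glottis.
tiny_prepared <- function(seed = 1, out_size = c(64, 48), radius = 3) {
  v <- tiny_video(seed)
  f <- v$frames[[3]]
  prepare_sample(f$image, f$mask, f$ap, f$pp, out_size, radius)
}

# Dataset generation ranges used for small training runs (64 x 32 frames).
small_gen_ranges <- function() {
  list(height = 64, width = 32, n_frames = 10, cycle_frames = 10,
       midline_angle = c(-15, 15), midline_center = c(14, 18, 24, 40),
       glottis_length = c(22, 30), max_half_width = c(3, 6), noise_sd = 0.03)
}

prepare_all <- function(videos, out_size, radius) {
  samples <- list()
  for (v in names(videos))
    samples <- c(samples,
                 prepare_video(videos[[v]], out_size, radius, video_id = v))
  samples
}
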