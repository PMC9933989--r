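#' Synthetic high-speed videoendoscopy parameters
#'
#' Parameter set for the synthetic clip generator. The generator emulates the
#' statistical structure of annotated endoscopy video snippets: a lens-shaped
#' glottal opening (intersection of two circular arcs) whose tips are the
#' anterior and posterior points, oscillating over a glottal cycle with the
#' half-width scaled by `|sin(pi * t / cycle_frames)|` (full closure at phase
#' zero), a fixed anterior-posterior axis per video, a bright background with
#' a dark opening, and additive Gaussian intensity noise clipped to `[0, 1]`.
#'
#' Defaults emulate one 30-frame snippet at 256 x 128 pixels, roughly two
#' oscillation cycles at typical recording and phonation rates.
#'
#' @param height,width frame size in pixels.
#' @param n_frames number of frames (>= 1).
#' @param cycle_frames frames per oscillation cycle (>= 2).
#' @param midline_angle midline angle in degrees from vertical.
#' @param midline_center `(x, y)` center of the anterior-posterior axis,
#'   0-based pixel coordinates.
#' @param glottis_length anterior-posterior distance in pixels.
#' @param max_half_width peak half-opening in pixels (>= 1).
#' @param noise_sd Gaussian intensity noise SD on the `[0, 1]` scale.
#' @param background_level background intensity on `[0, 1]`.
#' @param seed integer seed; identical parameter sets (including the seed)
#'   produce bit-identical videos.
#' @return a `synth_params` list.
#' @export
synth_params <- function(height = 256, width = 128, n_frames = 30,
                         cycle_frames = 15, midline_angle = 0,
                         midline_center = c(width / 2, height / 2),
                         glottis_length = 100, max_half_width = 14,
                         noise_sd = 0.03, background_level = 0.65, seed = 1) {
  p <- list(height = as.integer(height), width = as.integer(width),
            n_frames = as.integer(n_frames),
            cycle_frames = as.integer(cycle_frames),
            midline_angle = midline_angle,
            midline_center = as.numeric(midline_center),
            glottis_length = glottis_length,
            max_half_width = max_half_width, noise_sd = noise_sd,
            background_level = background_level, seed = as.integer(seed))
  validate_synth_params(p)
  structure(p, class = "synth_params")
}

validate_synth_params <- function(p) {
  chk <- function(ok, field, why) {
    if (!ok) ml_param_error(sprintf("invalid synth parameter '%s': %s", field, why))
  }
  chk(p$height >= 8 && p$width >= 8, "height/width", "must be >= 8")
  chk(p$n_frames >= 1, "n_frames", "must be >= 1")
  chk(p$cycle_frames >= 2, "cycle_frames", "must be >= 2")
  chk(p$glottis_length < min(p$height, p$width), "glottis_length",
      sprintf("must be < min(height, width) = %d", min(p$height, p$width)))
  chk(p$glottis_length > 0, "glottis_length", "must be positive")
  chk(p$max_half_width >= 1, "max_half_width", "must be >= 1")
  chk(p$noise_sd >= 0, "noise_sd", "must be >= 0")
  chk(p$background_level >= 0 && p$background_level <= 1, "background_level",
      "must be in [0, 1]")
  chk(length(p$midline_center) == 2, "midline_center", "must be (x, y)")
  invisible(p)
}

# Tips of the lens axis for a parameter set; anterior on top (smaller y) for
# an upright midline.
axis_points <- function(p) {
  th <- p$midline_angle * pi / 180
  v <- c(sin(th), cos(th))
  ap <- p$midline_center - p$glottis_length / 2 * v
  pp <- p$midline_center + p$glottis_length / 2 * v
  list(ap = ap, pp = pp)
}

# Rasterize the lens: a pixel is inside iff it lies in both circles through
# the two tips with half-width h at the axis midpoint.
lens_mask <- function(p, h) {
  H <- p$height; W <- p$width
  if (h <= 1e-9) return(matrix(0, H, W))
  th <- p$midline_angle * pi / 180
  v <- c(sin(th), cos(th))            # along-axis unit vector
  nrm <- c(cos(th), -sin(th))         # perpendicular unit vector
  L <- p$glottis_length
  R <- (L^2 / 4 + h^2) / (2 * h)
  grid <- expand.grid(y = seq_len(H) - 1, x = seq_len(W) - 1)
  dx <- grid$x - p$midline_center[1]
  dy <- grid$y - p$midline_center[2]
  u <- dx * v[1] + dy * v[2]
  w <- dx * nrm[1] + dy * nrm[2]
  inside <- u^2 + (abs(w) + R - h)^2 <= R^2
  matrix(as.numeric(inside), H, W)
}

#' Generate one synthetic endoscopy video
#'
#' @param params a [synth_params()] object (or a plain list of its fields).
#' @return a `video_sample`: list with `frames` (each an `annotated_frame`
#'   with `image`, `mask`, `ap`, `pp`), the video-constant `ap`/`pp` points
#'   and the generating `params`. Images are `H x W` matrices in `[0, 1]`,
#'   masks binary `H x W` matrices.
#' @export
generate_video <- function(params) {
  if (!inherits(params, "synth_params")) params <- do.call(synth_params, params)
  validate_synth_params(params)
  tips <- axis_points(params)
  H <- params$height; W <- params$width
  if (any(c(tips$ap, tips$pp) < 0) || any(tips$ap > c(W - 1, H - 1)) ||
      any(tips$pp > c(W - 1, H - 1)))
    ml_param_error("invalid synth parameter 'midline_center': axis tips fall outside the image")
  old <- preserve_rng()
  on.exit(restore_rng(old))
  set.seed(params$seed)
  frames <- vector("list", params$n_frames)
  for (t in seq_len(params$n_frames) - 1L) {
    h <- params$max_half_width * abs(sin(pi * t / params$cycle_frames))
    mask <- lens_mask(params, h)
    img <- matrix(params$background_level, H, W)
    img[mask == 1] <- 0.1
    if (params$noise_sd > 0)
      img <- img + matrix(stats::rnorm(H * W, sd = params$noise_sd), H, W)
    img <- pmin(pmax(img, 0), 1)
    frames[[t + 1L]] <- structure(list(image = img, mask = mask,
                                       ap = tips$ap, pp = tips$pp),
                                  class = "annotated_frame")
  }
  structure(list(frames = frames, ap = tips$ap, pp = tips$pp, params = params),
            class = "video_sample")
}

preserve_rng <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}

restore_rng <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  invisible(NULL)
}

#' Generate a dataset of synthetic videos
#'
#' Draws one parameter set per video uniformly from the given ranges, with a
#' per-video seed derived from the master seed, so the dataset is fully
#' reproducible and each video is independently re-generable.
#'
#' @param n_videos number of videos (>= 1).
#' @param params_ranges named list of `c(min, max)` ranges (or fixed scalars)
#'   for [synth_params()] fields; unlisted fields use the generator defaults.
#'   `midline_center` may be given as `c(xmin, xmax, ymin, ymax)`.
#' @param seed master integer seed.
#' @return list of `video_sample`s, named `video_001`, ...
#' @export
generate_dataset <- function(n_videos, params_ranges = list(), seed = 1) {
  if (n_videos < 1) ml_param_error("invalid parameter 'n_videos': must be >= 1")
  for (nm in names(params_ranges)) {
    r <- params_ranges[[nm]]
    if (length(r) == 0 || any(is.na(r)))
      ml_param_error(sprintf("invalid parameter range '%s': empty or NA", nm))
    if (length(r) %in% c(2L, 4L) && any(r[c(TRUE, FALSE)] > r[c(FALSE, TRUE)]))
      ml_param_error(sprintf("invalid parameter range '%s': min > max", nm))
  }
  old <- preserve_rng()
  on.exit(restore_rng(old))
  set.seed(seed)
  video_seeds <- sample.int(.Machine$integer.max, n_videos)
  draw <- function(r) if (length(r) == 1) r else stats::runif(1, r[1], r[2])
  int_fields <- c("height", "width", "n_frames", "cycle_frames")
  videos <- vector("list", n_videos)
  for (i in seq_len(n_videos)) {
    args <- list()
    for (nm in setdiff(names(params_ranges), "midline_center")) {
      v <- draw(params_ranges[[nm]])
      if (nm %in% int_fields) v <- as.integer(round(v))
      args[[nm]] <- v
    }
    if (!is.null(params_ranges$midline_center)) {
      r <- params_ranges$midline_center
      if (length(r) == 2) args$midline_center <- r
      else args$midline_center <- c(draw(r[1:2]), draw(r[3:4]))
    }
    args$seed <- video_seeds[i]
    videos[[i]] <- generate_video(do.call(synth_params, args))
  }
  names(videos) <- sprintf("video_%03d", seq_len(n_videos))
  videos
}
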