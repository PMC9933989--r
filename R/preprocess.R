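#' Build a keypoint target localization map
#'
#' Encodes a point as a filled disk of radius `radius` on an `H x W` grid:
#' pixel `(r, c)` (0-based) is 1 iff `(c - x)^2 + (r - y)^2 <= radius^2`.
#' Disks are clipped at the borders. Sub-pixel centers are honoured: the
#' membership test uses the float center. With `shape = "gaussian"` a smooth
#' map `exp(-d^2 / (2 * (radius/2)^2))` is produced instead of a binary disk.
#'
#' @param point `(x, y)` in 0-based pixel coordinates.
#' @param size `c(H, W)` grid size.
#' @param radius disk radius in pixels (> 0, float allowed).
#' @param shape `"disk"` (binary, default) or `"gaussian"`.
#' @return `H x W` numeric matrix. If the disk lies entirely outside the grid
#'   an all-zero map is returned with a warning.
#' @export
make_target_map <- function(point, size, radius, shape = c("disk", "gaussian")) {
  shape <- match.arg(shape)
  if (!is.numeric(radius) || length(radius) != 1 || radius <= 0)
    ml_param_error("invalid parameter 'radius': must be a positive scalar")
  if (length(point) != 2 || any(!is.finite(point)))
    ml_param_error("invalid parameter 'point': must be finite (x, y)")
  H <- size[1]; W <- size[2]
  dy2 <- (seq_len(H) - 1 - point[2])^2
  dx2 <- (seq_len(W) - 1 - point[1])^2
  d2 <- outer(dy2, dx2, "+")
  m <- if (shape == "disk") (d2 <= radius^2) * 1
  else exp(-d2 / (2 * (radius / 2)^2))
  if (shape == "disk" && sum(m) == 0)
    warning(sprintf("target disk at (%.1f, %.1f) lies entirely outside the %dx%d grid",
                    point[1], point[2], H, W))
  m
}

#' Prepare one annotated frame for the network
#'
#' Converts to grayscale (Rec. 601 luminance for RGB input), resizes the image
#' bilinearly and the mask nearest-neighbour to `out_size`, maps intensities
#' linearly from `[0, 1]` to `[-1, 1]`, re-binarizes the mask, scales the
#' anterior/posterior points by the resize factors and rasterizes the two
#' target localization maps.
#'
#' @param image `H x W` matrix in `[0, 1]` (or `H x W x 3` RGB array).
#' @param mask binary `H x W` matrix.
#' @param ap,pp `(x, y)` points, 0-based, inside the image.
#' @param out_size `c(H, W)` output size (divisible by 16 for model input).
#' @param radius target-map disk radius at the output scale, in pixels.
#' @param map_shape passed to [make_target_map()].
#' @return a `prepared_sample`: `image` in `[-1, 1]`, binary `mask`,
#'   `target_maps` (`H x W x 2`, anterior then posterior), scaled `ap`/`pp`,
#'   `radius`.
#' @export
prepare_sample <- function(image, mask, ap, pp, out_size, radius,
                           map_shape = "disk") {
  if (length(dim(image)) == 3) {
    if (dim(image)[3] >= 3)
      image <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
    else image <- image[, , 1]
  }
  H <- nrow(image); W <- ncol(image)
  if (!all(dim(mask) == c(H, W)))
    ml_validation_error("image and mask dimensions differ")
  inb <- function(p) all(p >= 0) && p[1] <= W - 1 && p[2] <= H - 1
  if (!inb(ap) || !inb(pp))
    ml_validation_error("anterior/posterior point outside image bounds")
  oh <- out_size[1]; ow <- out_size[2]
  sx <- ow / W; sy <- oh / H
  img <- resize_image(image, oh, ow, "bilinear") * 2 - 1
  msk <- (resize_image(mask, oh, ow, "nearest") > 0.5) * 1
  ap2 <- c(ap[1] * sx, ap[2] * sy)
  pp2 <- c(pp[1] * sx, pp[2] * sy)
  if (!all(ap2 >= 0 & ap2 <= c(ow - 1, oh - 1)) ||
      !all(pp2 >= 0 & pp2 <= c(ow - 1, oh - 1)))
    ml_validation_error("point outside bounds after resize")
  maps <- array(0, c(oh, ow, 2))
  maps[, , 1] <- make_target_map(ap2, c(oh, ow), radius, map_shape)
  maps[, , 2] <- make_target_map(pp2, c(oh, ow), radius, map_shape)
  structure(list(image = img, mask = msk, target_maps = maps,
                 ap = ap2, pp = pp2, radius = radius, map_shape = map_shape),
            class = "prepared_sample")
}

#' Prepare all frames of a video
#'
#' @param video a `video_sample` (see [generate_video()]) or list of
#'   `annotated_frame`s.
#' @param out_size,radius,map_shape as in [prepare_sample()].
#' @param video_id identifier attached to each prepared frame.
#' @return list of `prepared_sample`s with `$video_id` and `$frame_idx`
#'   (0-based) set.
#' @export
prepare_video <- function(video, out_size, radius, map_shape = "disk",
                          video_id = "video") {
  frames <- if (inherits(video, "video_sample")) video$frames else video
  out <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    s <- prepare_sample(f$image, f$mask, f$ap, f$pp, out_size, radius, map_shape)
    s$video_id <- video_id
    s$frame_idx <- i - 1L
    out[[i]] <- s
  }
  out
}
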