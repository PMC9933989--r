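# Geometric resampling with an explicit coordinate convention shared with the
# point annotations: (x, y) = (column, row), 0-based, origin top-left, pixel
# centers on integer coordinates. Keeping warping and point transforms on one
# convention is what makes the sub-pixel consistency contracts (points vs.
# rebuilt target maps) hold.

# Sample img (H x W matrix) at 0-based float coordinates, bilinear with
# clamped borders; coordinates outside the image return `fill`.
bilinear_gather <- function(img, xs, ys, fill = 0) {
  H <- nrow(img); W <- ncol(img)
  inside <- xs > -0.5 & xs < W - 0.5 & ys > -0.5 & ys < H - 0.5
  xc <- pmin(pmax(xs, 0), W - 1)
  yc <- pmin(pmax(ys, 0), H - 1)
  x0 <- floor(xc); y0 <- floor(yc)
  x1 <- pmin(x0 + 1, W - 1); y1 <- pmin(y0 + 1, H - 1)
  fx <- xc - x0; fy <- yc - y0
  v <- img[cbind(y0 + 1, x0 + 1)] * (1 - fx) * (1 - fy) +
    img[cbind(y0 + 1, x1 + 1)] * fx * (1 - fy) +
    img[cbind(y1 + 1, x0 + 1)] * (1 - fx) * fy +
    img[cbind(y1 + 1, x1 + 1)] * fx * fy
  v[!inside] <- fill
  v
}

nearest_gather <- function(img, xs, ys, fill = 0) {
  H <- nrow(img); W <- ncol(img)
  xi <- round(xs); yi <- round(ys)
  inside <- xi >= 0 & xi <= W - 1 & yi >= 0 & yi <= H - 1
  v <- rep(fill, length(xs))
  v[inside] <- img[cbind(yi[inside] + 1, xi[inside] + 1)]
  v
}

# Resize so that a point at (x, y) maps to (x * W'/W, y * H'/H): output pixel
# (c', r') samples the input at (c'/sx, r'/sy).
resize_image <- function(img, out_h, out_w, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  H <- nrow(img); W <- ncol(img)
  if (out_h == H && out_w == W) return(img)
  sx <- out_w / W; sy <- out_h / H
  grid <- expand.grid(y = seq_len(out_h) - 1, x = seq_len(out_w) - 1)
  xs <- grid$x / sx; ys <- grid$y / sy
  v <- if (method == "bilinear") bilinear_gather(img, xs, ys, fill = 0)
  else nearest_gather(img, xs, ys, fill = 0)
  matrix(v, out_h, out_w)
}

# Rotate points by `theta` degrees about the image center ((W-1)/2, (H-1)/2).
rotate_points <- function(pts, theta, h, w) {
  th <- theta * pi / 180
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  x <- pts[, 1] - cx; y <- pts[, 2] - cy
  cbind(cx + cos(th) * x - sin(th) * y, cy + sin(th) * x + cos(th) * y)
}

# Rotate an image with the matching convention (inverse mapping).
rotate_image <- function(img, theta, method = c("bilinear", "nearest"),
                         fill = 0) {
  method <- match.arg(method)
  H <- nrow(img); W <- ncol(img)
  th <- -theta * pi / 180
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  grid <- expand.grid(y = seq_len(H) - 1, x = seq_len(W) - 1)
  dx <- grid$x - cx; dy <- grid$y - cy
  xs <- cx + cos(th) * dx - sin(th) * dy
  ys <- cy + sin(th) * dx + cos(th) * dy
  v <- if (method == "bilinear") bilinear_gather(img, xs, ys, fill = fill)
  else nearest_gather(img, xs, ys, fill = fill)
  matrix(v, H, W)
}

# Separable Gaussian blur built on the package's convolution kernel.
gaussian_blur <- function(img, sigma = 1) {
  k <- 2L * as.integer(ceiling(2 * sigma)) + 1L
  xs <- seq_len(k) - (k + 1) / 2
  g <- exp(-xs^2 / (2 * sigma^2))
  g <- g / sum(g)
  x <- array(img, c(nrow(img), ncol(img), 1))
  x <- conv2d_fwd_cpp(x, matrix(g, ncol = 1), 0, k, 1L)
  x <- conv2d_fwd_cpp(x, matrix(g, ncol = 1), 0, 1L, k)
  matrix(x, nrow(img), ncol(img))
}
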