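# Independent brute-force oracles, written as plain per-element loops so they
# share no code path with the implementations they check.

# Disk membership decided pixel by pixel.
oracle_disk_map <- function(point, size, radius) {
  H <- size[1]; W <- size[2]
  m <- matrix(0, H, W)
  for (r in seq_len(H)) {
    for (c in seq_len(W)) {
      if ((c - 1 - point[1])^2 + (r - 1 - point[2])^2 <= radius^2)
        m[r, c] <- 1
    }
  }
  m
}

# MAPE as an explicit per-coordinate loop.
oracle_mape <- function(pred, true) {
  s <- 0
  for (i in seq_along(pred)) s <- s + abs(pred[i] - true[i]) / abs(true[i])
  100 * s / length(pred)
}

# IoU by counting pixels one by one.
oracle_iou <- function(a, b) {
  inter <- 0; uni <- 0
  for (i in seq_along(a)) {
    if (a[i] > 0 && b[i] > 0) inter <- inter + 1
    if (a[i] > 0 || b[i] > 0) uni <- uni + 1
  }
  if (uni == 0) 1 else inter / uni
}

# Dice loss by explicit elementwise accumulation.
oracle_dice <- function(p, t, eps = 1) {
  sp <- 0; st <- 0; spt <- 0
  for (i in seq_along(p)) {
    sp <- sp + p[i]; st <- st + t[i]; spt <- spt + p[i] * t[i]
  }
  1 - (2 * spt + eps) / (sp + st + eps)
}

# MSE by double loop over a matrix/array.
oracle_mse <- function(p, t) {
  s <- 0
  for (i in seq_along(p)) s <- s + (p[i] - t[i])^2
  s / length(p)
}

# Moving median: pad, then sort each window explicitly and pick/average the
# central order statistics.
oracle_moving_median <- function(x, w) {
  n <- length(x)
  lead <- ceiling((w - 1) / 2)
  trail <- floor((w - 1) / 2)
  xp <- c(rep(x[1], lead), x, rep(x[n], trail))
  out <- numeric(n)
  for (i in seq_len(n)) {
    win <- sort(xp[i:(i + w - 1)])
    out[i] <- if (w %% 2 == 1) win[(w + 1) / 2]
    else (win[w / 2] + win[w / 2 + 1]) / 2
  }
  out
}

# Population standard deviation via a two-pass loop.
oracle_pop_sd <- function(d) {
  m <- 0
  for (v in d) m <- m + v
  m <- m / length(d)
  s <- 0
  for (v in d) s <- s + (v - m)^2
  sqrt(s / length(d))
}

# Interpolated quantile (type 7) computed from first principles.
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}
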