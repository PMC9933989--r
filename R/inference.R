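#' Decode anterior/posterior points from localization maps
#'
#' Per channel, pixels at or above half the channel maximum are kept and the
#' intensity-weighted centroid of the surviving pixels is returned (exact on
#' ideal symmetric disks, robust to plateaued maxima). `method = "argmax"`
#' returns the first maximal pixel in row-major order instead.
#'
#' @param pred_maps `H x W x 2` array (anterior map first) with finite values.
#' @param method `"centroid"` (default) or `"argmax"`.
#' @return list with `ap` and `pp`, each `(x, y)` in 0-based sub-pixel
#'   coordinates.
#' @export
decode_keypoints <- function(pred_maps, method = c("centroid", "argmax")) {
  method <- match.arg(method)
  if (length(dim(pred_maps)) != 3 || dim(pred_maps)[3] != 2)
    ml_validation_error("pred_maps must be an H x W x 2 array")
  if (any(!is.finite(pred_maps)))
    ml_validation_error("pred_maps contains non-finite values")
  nm <- c("anterior", "posterior")
  pts <- lapply(1:2, function(k) {
    m <- pred_maps[, , k]
    mx <- max(m)
    if (mx <= 0)
      ml_validation_error(sprintf("degenerate all-zero %s (channel %d) map",
                                  nm[k], k))
    if (method == "argmax") {
      hits <- which(m == mx, arr.ind = TRUE)
      hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
      return(as.numeric(c(hits[1, 2] - 1, hits[1, 1] - 1)))
    }
    keep <- m >= 0.5 * mx
    w <- m * keep
    tot <- sum(w)
    rows <- row(m) - 1
    cols <- col(m) - 1
    c(sum(cols * w) / tot, sum(rows * w) / tot)
  })
  list(ap = pts[[1]], pp = pts[[2]])
}

#' Glottal midline through the anterior and posterior points
#'
#' @param ap,pp `(x, y)` points; must differ.
#' @return list with `ap`, `pp` and the unit `direction` from pp to ap.
#' @export
midline_from_points <- function(ap, pp) {
  d <- ap - pp
  len <- sqrt(sum(d^2))
  if (len == 0)
    ml_validation_error("midline undefined: anterior and posterior points coincide")
  structure(list(ap = ap, pp = pp, direction = d / len), class = "midline")
}

#' Moving-median filter for point trajectories
#'
#' Smooths each coordinate series (ap_x, ap_y, pp_x, pp_y) independently. The
#' series is padded with `ceiling((w-1)/2)` replicates of the first value and
#' `floor((w-1)/2)` replicates of the last value, then a length-`w` window
#' slides over it and the median is taken (for even `w`, the mean of the two
#' central order statistics). The trajectory length is preserved.
#'
#' @param traj data frame (or matrix) with columns `ap_x`, `ap_y`, `pp_x`,
#'   `pp_y` (additional columns are passed through untouched).
#' @param window window length in frames (>= 1; 1 is the identity). Values
#'   much larger than the trajectory (over 4x its length) trigger a warning
#'   since the result is dominated by the padding.
#' @return filtered trajectory of the same class and length.
#' @export
moving_median_filter <- function(traj, window) {
  if (!is.numeric(window) || length(window) != 1 || window < 1)
    ml_param_error("invalid parameter 'window': must be >= 1")
  window <- as.integer(window)
  is_df <- is.data.frame(traj)
  cols <- c("ap_x", "ap_y", "pp_x", "pp_y")
  if (is_df && !all(cols %in% names(traj)))
    ml_validation_error("trajectory must have columns ap_x, ap_y, pp_x, pp_y")
  T_ <- if (is_df) nrow(traj) else length(traj)
  if (window > 4 * T_)
    warning("filter window exceeds 4x the trajectory length; output dominated by padding")
  filt1 <- function(x) {
    n <- length(x)
    lead <- ceiling((window - 1) / 2)
    trail <- floor((window - 1) / 2)
    xp <- c(rep(x[1], lead), x, rep(x[n], trail))
    vapply(seq_len(n), function(i) stats::median(xp[i:(i + window - 1L)]),
           numeric(1))
  }
  if (window == 1) return(traj)
  if (is_df) {
    for (cl in cols) traj[[cl]] <- filt1(traj[[cl]])
    traj
  } else filt1(traj)
}

# Assemble a clip input for a temporal model from a list of prepared frames.
stack_frames <- function(imgs, mode) {
  H <- nrow(imgs[[1]]); W <- ncol(imgs[[1]])
  T_ <- length(imgs)
  if (mode == "channels") array(unlist(imgs), c(H, W, T_))
  else {
    x <- array(0, c(H, W, T_, 1))
    for (t in seq_len(T_)) x[, , t, 1] <- imgs[[t]]
    x
  }
}

#' Predict a point trajectory and segmentation maps for a video
#'
#' Runs the model frame-wise (2D), with a centre-aligned sliding window whose
#' edges are padded by frame replication (`channels` mode), or on
#' consecutive clips of `n_frames` frames with tail replication
#' (`conv3d`/`convlstm`), then decodes the anterior/posterior points per frame
#' and optionally applies the moving-median filter.
#'
#' @param model a `midline_model`.
#' @param frames list of prepared images (matrices in `[-1, 1]` at the model
#'   input size), e.g. `lapply(prepare_video(...), [[, "image")`.
#' @param window moving-median window in frames (1 = no filtering).
#' @param decode_method passed to [decode_keypoints()].
#' @return list with `trajectory` (data frame `frame_idx`, `ap_x`, `ap_y`,
#'   `pp_x`, `pp_y`), `raw_trajectory` (before filtering) and `seg_maps`
#'   (`H x W x T` array of glottis probabilities).
#' @export
predict_video <- function(model, frames, window = 1, decode_method = "centroid") {
  if (is.array(frames) && length(dim(frames)) == 3)
    frames <- lapply(seq_len(dim(frames)[3]), function(t) frames[, , t])
  T_ <- length(frames)
  mode <- model$config$temporal_mode
  H <- nrow(frames[[1]]); W <- ncol(frames[[1]])
  seg <- array(0, c(H, W, T_))
  pts <- matrix(0, T_, 4)
  decode1 <- function(out, t) {
    if (!is.null(out$points)) {
      pts[t, ] <<- out$points
    } else {
      kp <- decode_keypoints(out$keypoint_maps, decode_method)
      pts[t, ] <<- c(kp$ap, kp$pp)
    }
    seg[, , t] <<- out$seg[, , 1]
  }
  if (mode == "none") {
    for (t in seq_len(T_)) {
      out <- predict_frame(model, array(frames[[t]], c(H, W, 1)))
      decode1(out, t)
    }
  } else if (mode == "channels") {
    nf <- model$config$n_frames
    ref <- (nf - 1L) %/% 2L             # centre (0-based) frame of the window
    for (t in seq_len(T_)) {
      idx <- (t - 1L) - ref + 0:(nf - 1L)
      idx <- pmin(pmax(idx, 0L), T_ - 1L) + 1L
      out <- predict_frame(model, stack_frames(frames[idx], mode))
      decode1(out, t)
    }
  } else {
    nf <- model$config$n_frames
    starts <- seq.int(1L, T_, by = nf)
    for (s in starts) {
      idx <- pmin(s + 0:(nf - 1L), T_)
      out <- predict_frame(model, stack_frames(frames[idx], mode))
      for (j in seq_len(nf)) {
        t <- s + j - 1L
        if (t > T_) break
        kp <- decode_keypoints(array(out$keypoint_maps[, , j, ], c(H, W, 2)),
                               decode_method)
        pts[t, ] <- c(kp$ap, kp$pp)
        seg[, , t] <- out$seg[, , j, 1]
      }
    }
  }
  raw <- data.frame(frame_idx = seq_len(T_) - 1L, ap_x = pts[, 1],
                    ap_y = pts[, 2], pp_x = pts[, 3], pp_y = pts[, 4])
  traj <- if (window > 1) moving_median_filter(raw, window) else raw
  list(trajectory = traj, raw_trajectory = raw, seg_maps = seg)
}
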