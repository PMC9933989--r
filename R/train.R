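#' Soft Dice loss
#'
#' `1 - (2 * sum(p * t) + eps) / (sum(p) + sum(t) + eps)` with `eps = 1`,
#' which keeps the loss defined on frames with a fully closed glottis (empty
#' target mask).
#'
#' @param pred_mask predicted probabilities in `[0, 1]`.
#' @param true_mask binary target of the same shape.
#' @param eps smoothing constant.
#' @return loss in `[0, 1)`.
#' @export
dice_loss <- function(pred_mask, true_mask, eps = 1) {
  if (!identical(length(pred_mask), length(true_mask)) ||
      !all(dim2(pred_mask) == dim2(true_mask)))
    ml_validation_error("pred and true mask shapes differ")
  1 - (2 * sum(pred_mask * true_mask) + eps) /
    (sum(pred_mask) + sum(true_mask) + eps)
}

dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

#' Keypoint map loss (MSE)
#'
#' Mean squared difference over all pixels of both localization maps.
#'
#' @param pred_maps,target_maps arrays of identical shape.
#' @return scalar loss.
#' @export
keypoint_loss <- function(pred_maps, target_maps) {
  if (!identical(length(pred_maps), length(target_maps)) ||
      !all(dim2(pred_maps) == dim2(target_maps)))
    ml_validation_error("pred and target map shapes differ")
  mean((pred_maps - target_maps)^2)
}

#' Combined multitask loss
#'
#' `w_seg * dice_loss + w_pts * keypoint_loss`; the default equal weighting
#' `(1, 1)` trains both heads jointly.
#'
#' @param outputs list with `seg` and `kp` (predicted arrays).
#' @param targets list with `seg` and `kp` (target arrays).
#' @param weights `c(w_seg, w_pts)`, nonnegative, not both zero.
#' @return scalar loss.
#' @export
combined_loss <- function(outputs, targets, weights = c(1, 1)) {
  check_weights(weights)
  weights[1] * dice_loss(outputs$seg, targets$seg) +
    weights[2] * keypoint_loss(outputs$kp, targets$kp)
}

check_weights <- function(weights) {
  if (length(weights) != 2 || any(weights < 0) || sum(weights) == 0)
    ml_param_error("loss weights must be two nonnegative values, not both zero")
  invisible(weights)
}

#' Learning-rate policies
#'
#' * `constant` - `lr0` at every epoch.
#' * `exp_decay` - `lr0 * gamma^epoch` (default `gamma = 0.95`).
#' * `scheduler1` - step decay `lr0 * 0.5^floor(epoch / 10)`.
#' * `scheduler2` - linear warmup over the first 3 epochs to `lr0`, then
#'   exponential decay with factor 0.9 (the default policy of the final
#'   model). The warmup/decay forms of the two named schedulers are this
#'   package's definitions, exposed as presets.
#'
#' @param policy one of `"constant"`, `"scheduler1"`, `"scheduler2"`,
#'   `"exp_decay"`.
#' @param lr0 base learning rate.
#' @param epoch 0-based epoch number.
#' @param gamma decay factor for `exp_decay`.
#' @return learning rate for the epoch.
#' @export
lr_schedule <- function(policy, lr0, epoch, gamma = 0.95) {
  if (epoch < 0) ml_param_error("epoch must be >= 0")
  switch(policy,
         constant = lr0,
         exp_decay = lr0 * gamma^epoch,
         scheduler1 = lr0 * 0.5^(epoch %/% 10),
         scheduler2 = if (epoch < 3) lr0 * (epoch + 1) / 3
                      else lr0 * 0.9^(epoch - 2),
         ml_param_error(sprintf("unknown learning-rate policy '%s'", policy)))
}

#' Augmentation configuration
#'
#' Geometric operations (rotation, horizontal flip) transform image, mask and
#' points consistently; target maps are rebuilt from the transformed points.
#' Photometric operations (blur, random gamma, Gaussian noise) touch the
#' image only.
#'
#' @param ops subset of `c("rotation", "horizontal_flip", "blur",
#'   "random_gamma", "gaussian_noise")`.
#' @param augment_factor offline expansion factor for [augment_dataset()]
#'   (original + factor-1 augmented copies).
#' @param rotation_range max |rotation| in degrees.
#' @param prob per-operation application probability.
#' @param blur_sigma range of the Gaussian blur sigma (pixels).
#' @param gamma_range range of the random gamma exponent.
#' @param noise_sd SD of the additive Gaussian image noise (on the `[-1, 1]`
#'   intensity scale).
#' @return an `augment_config` list.
#' @export
augment_config <- function(ops = c("rotation", "horizontal_flip", "blur",
                                   "random_gamma", "gaussian_noise"),
                           augment_factor = 10, rotation_range = 30,
                           prob = 0.5, blur_sigma = c(0.5, 1.5),
                           gamma_range = c(0.8, 1.25), noise_sd = 0.03) {
  known <- c("rotation", "horizontal_flip", "blur", "random_gamma",
             "gaussian_noise")
  if (!all(ops %in% known))
    ml_param_error(sprintf("unknown augmentation ops: %s",
                           paste(setdiff(ops, known), collapse = ", ")))
  structure(list(ops = ops, augment_factor = augment_factor,
                 rotation_range = rotation_range, prob = prob,
                 blur_sigma = blur_sigma, gamma_range = gamma_range,
                 noise_sd = noise_sd),
            class = "augment_config")
}

flip_sample <- function(sample) {
  W <- ncol(sample$image)
  sample$image <- sample$image[, W:1]
  sample$mask <- sample$mask[, W:1]
  sample$target_maps <- sample$target_maps[, W:1, , drop = FALSE]
  sample$ap[1] <- W - 1 - sample$ap[1]
  sample$pp[1] <- W - 1 - sample$pp[1]
  sample
}

rotate_sample <- function(sample, theta) {
  H <- nrow(sample$image); W <- ncol(sample$image)
  pts <- rotate_points(rbind(sample$ap, sample$pp), theta, H, W)
  if (any(pts < 0) || any(pts[, 1] > W - 1) || any(pts[, 2] > H - 1))
    return(NULL)                      # rejected: point left the image
  sample$image <- rotate_image(sample$image, theta, "bilinear", fill = -1)
  sample$mask <- rotate_image(sample$mask, theta, "nearest", fill = 0)
  sample$ap <- pts[1, ]
  sample$pp <- pts[2, ]
  sample$target_maps[, , 1] <- make_target_map(sample$ap, c(H, W),
                                               sample$radius, sample$map_shape)
  sample$target_maps[, , 2] <- make_target_map(sample$pp, c(H, W),
                                               sample$radius, sample$map_shape)
  sample
}

#' Augment one prepared sample
#'
#' Each enabled operation is applied with probability `config$prob`. A
#' rotation that would move a point outside the image is rejected and a new
#' angle drawn (up to 10 tries, then the rotation is skipped).
#'
#' @param sample a `prepared_sample`.
#' @param config an [augment_config()].
#' @param seed optional integer seed for reproducible augmentation.
#' @return augmented `prepared_sample`.
#' @export
augment_sample <- function(sample, config = augment_config(), seed = NULL) {
  if (!is.null(seed)) {
    old <- preserve_rng()
    on.exit(restore_rng(old))
    set.seed(seed)
  }
  on_ <- function(op) op %in% config$ops && stats::runif(1) < config$prob
  if (on_("rotation")) {
    for (i in 1:10) {
      theta <- stats::runif(1, -config$rotation_range, config$rotation_range)
      rs <- rotate_sample(sample, theta)
      if (!is.null(rs)) { sample <- rs; break }
    }
  }
  if (on_("horizontal_flip")) sample <- flip_sample(sample)
  if (on_("blur"))
    sample$image <- gaussian_blur(sample$image,
                                  stats::runif(1, config$blur_sigma[1],
                                               config$blur_sigma[2]))
  if (on_("random_gamma")) {
    g <- stats::runif(1, config$gamma_range[1], config$gamma_range[2])
    u <- pmin(pmax((sample$image + 1) / 2, 0), 1)
    sample$image <- u^g * 2 - 1
  }
  if (on_("gaussian_noise")) {
    sample$image <- pmin(pmax(sample$image +
      matrix(stats::rnorm(length(sample$image), sd = config$noise_sd),
             nrow(sample$image)), -1), 1)
  }
  sample
}

#' Expand a dataset by offline augmentation
#'
#' @param samples list of `prepared_sample`s.
#' @param config an [augment_config()]; `augment_factor` copies per sample
#'   (the first copy is the original).
#' @param seed integer seed.
#' @return expanded list.
#' @export
augment_dataset <- function(samples, config = augment_config(), seed = 1) {
  out <- vector("list", length(samples) * config$augment_factor)
  k <- 0L
  for (i in seq_along(samples)) {
    for (j in seq_len(config$augment_factor)) {
      k <- k + 1L
      out[[k]] <- if (j == 1) samples[[i]]
      else augment_sample(samples[[i]], config, seed = seed * 1000L + k)
    }
  }
  out
}

#' Training configuration
#'
#' @param epochs training epochs (2D default 30; temporal variants are
#'   typically trained longer, e.g. 100, to offset the smaller clip count).
#' @param lr_policy see [lr_schedule()]; the final-model default is
#'   `scheduler2`.
#' @param lr0 base learning rate for the Adam optimizer.
#' @param batch_size samples per optimizer step (gradients averaged).
#' @param val_fraction fraction of frames held out for validation, split by
#'   video (frames of one video never straddle the split).
#' @param seed integer seed covering the split, shuffling and augmentation.
#' @param loss_weights `c(w_seg, w_pts)` multitask weighting.
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 30, lr_policy = "scheduler2", lr0 = 1e-3,
                         batch_size = 4, val_fraction = 0.10, seed = 1,
                         loss_weights = c(1, 1)) {
  if (val_fraction <= 0 || val_fraction >= 1)
    ml_param_error("val_fraction must be in (0, 1)")
  check_weights(loss_weights)
  structure(list(epochs = as.integer(epochs), lr_policy = lr_policy,
                 lr0 = lr0, batch_size = as.integer(batch_size),
                 val_fraction = val_fraction, seed = as.integer(seed),
                 loss_weights = loss_weights),
            class = "train_config")
}

# Convert per-frame prepared samples into model-shaped training samples.
# For temporal modes, frames are grouped by video and cut into consecutive
# clips of n_frames (tail clips are dropped if incomplete).
as_training_set <- function(samples, config) {
  mode <- config$temporal_mode
  if (mode == "none") {
    return(lapply(samples, function(s) {
      H <- nrow(s$image); W <- ncol(s$image)
      list(x = array(s$image, c(H, W, 1)),
           seg = array(s$mask, c(H, W, 1)), kp = s$target_maps,
           points = c(s$ap, s$pp), video_id = s$video_id %||% "v")
    }))
  }
  nf <- config$n_frames
  vids <- vapply(samples, function(s) s$video_id %||% "v", character(1))
  out <- list()
  for (v in unique(vids)) {
    fs <- samples[vids == v]
    ord <- order(vapply(fs, function(s) s$frame_idx %||% 0L, numeric(1)))
    fs <- fs[ord]
    n_clips <- length(fs) %/% nf
    for (k in seq_len(n_clips)) {
      clip <- fs[((k - 1) * nf + 1):(k * nf)]
      H <- nrow(clip[[1]]$image); W <- ncol(clip[[1]]$image)
      x <- stack_frames(lapply(clip, `[[`, "image"), mode)
      if (mode == "channels") {
        ref <- (nf - 1L) %/% 2L + 1L
        out[[length(out) + 1L]] <- list(
          x = x, seg = array(clip[[ref]]$mask, c(H, W, 1)),
          kp = clip[[ref]]$target_maps,
          points = c(clip[[ref]]$ap, clip[[ref]]$pp), video_id = v)
      } else {
        seg <- array(0, c(H, W, nf, 1))
        kp <- array(0, c(H, W, nf, 2))
        for (t in seq_len(nf)) {
          seg[, , t, 1] <- clip[[t]]$mask
          kp[, , t, ] <- clip[[t]]$target_maps
        }
        out[[length(out) + 1L]] <- list(x = x, seg = seg, kp = kp,
                                        points = c(clip[[1]]$ap, clip[[1]]$pp),
                                        video_id = v)
      }
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Video-disjoint validation split targeting floor(val_fraction * n) frames.
split_by_video <- function(train_samples, val_fraction) {
  vids <- vapply(train_samples, `[[`, character(1), "video_id")
  uv <- sample(unique(vids))
  target <- floor(val_fraction * length(train_samples))
  val_vids <- character()
  count <- 0
  for (v in uv) {
    if (count >= max(target, 1)) break
    if (length(val_vids) + 1 == length(uv)) break  # keep >= 1 training video
    val_vids <- c(val_vids, v)
    count <- count + sum(vids == v)
  }
  list(train = which(!vids %in% val_vids), val = which(vids %in% val_vids))
}

sample_loss_nodes <- function(tape, out, s, weights) {
  if (!is.null(out$points)) {
    lp <- op_mse_loss(tape, out$points, s$points)
    ls <- op_dice_loss(tape, out$seg, s$seg)
    op_wsum(tape, list(ls, lp), weights)
  } else {
    ls <- op_dice_loss(tape, out$seg, s$seg)
    lk <- op_mse_loss(tape, out$kp, s$kp)
    op_wsum(tape, list(ls, lk), weights)
  }
}

# MAPE/IoU of one validation sample (decoded in 1-based coordinates).
# Per-frame (temporal) outputs are evaluated on their first frame.
val_metrics_sample <- function(out, s) {
  temporal <- length(dim(s$seg)) == 4
  if (temporal) {
    seg <- out$seg$value[, , 1, 1]
    tseg <- s$seg[, , 1, 1]
  } else {
    seg <- out$seg$value[, , 1]
    tseg <- s$seg[, , 1]
  }
  if (!is.null(out$points)) {
    pred <- out$points$value
  } else {
    kp <- out$kp$value
    if (temporal) kp <- array(kp[, , 1, ], dim(kp)[c(1, 2, 4)])
    dk <- tryCatch(decode_keypoints(kp), error = function(e) NULL)
    pred <- if (is.null(dk)) rep(NA_real_, 4) else c(dk$ap, dk$pp)
  }
  m <- if (any(is.na(pred))) NA_real_
  else mape(eval_points(pred), eval_points(s$points))
  list(mape = m, iou = iou(seg > 0.5, tseg))
}

#' Train a model
#'
#' Adam optimization of the multitask objective (Dice segmentation loss +
#' MSE keypoint-map loss), with a video-disjoint validation split evaluated
#' after each epoch and the checkpoint with the best validation MAPE
#' retained. Fully seeded: two runs with the same seeds produce identical
#' histories.
#'
#' @param model a `midline_model` from [build_model()].
#' @param dataset list of `prepared_sample`s (see [prepare_video()]); for
#'   temporal models the frames are cut into clips of `n_frames`.
#' @param config a [train_config()].
#' @param augment an optional [augment_config()] applied on the fly to the
#'   training split (2D samples only).
#' @return a `midline_fit`: `model` (best validation MAPE), `final_model`,
#'   `history` data frame (epoch, lr, train_loss, val_loss, val_iou,
#'   val_mape), `best_epoch`.
#' @export
train_model <- function(model, dataset, config = train_config(),
                        augment = NULL) {
  if (length(dataset) == 0) ml_param_error("empty training dataset")
  cfg <- model$config
  tset <- as_training_set(dataset, cfg)
  if (length(tset) < 2)
    ml_param_error("need at least 2 training samples (check n_frames vs video length)")
  old <- preserve_rng()
  on.exit(restore_rng(old))
  set.seed(config$seed)
  sp <- split_by_video(tset, config$val_fraction)
  if (length(sp$val) == 0 || length(sp$train) == 0)
    ml_param_error("validation split empty; need >= 2 videos")
  adam <- new.env(parent = emptyenv())
  adam$m <- list(); adam$v <- list(); adam$t <- 0
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  hist <- data.frame()
  best <- list(mape = Inf, params = NULL, epoch = NA, running = NULL)
  do_augment <- !is.null(augment) && cfg$temporal_mode == "none"
  for (epoch in seq_len(config$epochs) - 1L) {
    lr <- lr_schedule(config$lr_policy, config$lr0, epoch)
    ord <- sample(sp$train)
    tl <- 0
    nb <- 0
    i <- 1
    while (i <= length(ord)) {
      idx <- ord[i:min(i + config$batch_size - 1L, length(ord))]
      i <- i + config$batch_size
      acc <- list()
      for (j in idx) {
        s <- tset[[j]]
        if (do_augment) {
          a <- augment_sample(dataset[[j]], augment)
          H <- nrow(a$image); W <- ncol(a$image)
          s <- list(x = array(a$image, c(H, W, 1)),
                    seg = array(a$mask, c(H, W, 1)), kp = a$target_maps,
                    points = c(a$ap, a$pp), video_id = s$video_id)
        }
        tape <- new_tape()
        out <- model_forward(model, s$x, tape, training = TRUE)
        loss <- sample_loss_nodes(tape, out, s, config$loss_weights)
        if (!is.finite(loss$value))
          ml_validation_error(sprintf("non-finite loss at epoch %d", epoch))
        grads <- tp_backward(tape, loss)
        tl <- tl + loss$value
        for (nm in names(grads)) {
          if (is.null(acc[[nm]])) acc[[nm]] <- grads[[nm]]
          else acc[[nm]] <- acc[[nm]] + grads[[nm]]
        }
      }
      nb <- nb + length(idx)
      adam$t <- adam$t + 1
      corr <- sqrt(1 - b2^adam$t) / (1 - b1^adam$t)
      for (nm in names(acc)) {
        g <- acc[[nm]] / length(idx)
        if (is.null(adam$m[[nm]])) { adam$m[[nm]] <- g * 0; adam$v[[nm]] <- g * 0 }
        adam$m[[nm]] <- b1 * adam$m[[nm]] + (1 - b1) * g
        adam$v[[nm]] <- b2 * adam$v[[nm]] + (1 - b2) * g * g
        model$ps$params[[nm]] <- model$ps$params[[nm]] -
          lr * corr * adam$m[[nm]] / (sqrt(adam$v[[nm]]) + eps)
      }
    }
    vl <- 0; vm <- c(); vi <- c()
    for (j in sp$val) {
      s <- tset[[j]]
      tape <- new_tape()
      out <- model_forward(model, s$x, tape, training = FALSE)
      vl <- vl + sample_loss_nodes(tape, out, s, config$loss_weights)$value
      met <- val_metrics_sample(out, s)
      vm <- c(vm, met$mape); vi <- c(vi, met$iou)
    }
    val_mape <- if (all(is.na(vm))) Inf else mean(vm, na.rm = TRUE)
    hist <- rbind(hist, data.frame(
      epoch = epoch, lr = lr, train_loss = tl / nb,
      val_loss = vl / length(sp$val), val_iou = mean(vi),
      val_mape = val_mape))
    if (val_mape <= best$mape) {
      best$mape <- val_mape
      best$params <- model$ps$params
      best$running <- model$state$running
      best$epoch <- epoch
    }
  }
  best_model <- structure(list(config = cfg, ps = new.env(parent = emptyenv()),
                               state = new.env(parent = emptyenv())),
                          class = "midline_model")
  best_model$ps$params <- best$params
  best_model$state$running <- best$running
  structure(list(model = best_model, final_model = model, history = hist,
                 best_epoch = best$epoch, val_idx = sp$val, train_idx = sp$train),
            class = "midline_fit")
}
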