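#' Model configuration
#'
#' Describes one member of the dual-decoder U-Net family. All variants share a
#' four-level encoder (two 3x3 convolutions, normalization, ReLU, then 2x2
#' max-pooling per level) ending in a latent space from which the decoders
#' grow. The variants differ in how late (or whether) the segmentation and
#' keypoint-map pathways separate:
#'
#' * `v2a` - one shared decoder; only the final 1x1 output convolutions
#'   differ between the segmentation map and the two keypoint maps.
#' * `v2b` - the pathways split before the second convolution of the last
#'   decoding step.
#' * `v2c` - like `v2a` but with three output heads: segmentation, anterior
#'   point map and posterior point map each get their own 1x1 convolution.
#' * `v2d` - the entire last decoder step (upsampling, skip concatenation and
#'   both convolutions) is duplicated per task.
#' * `v2e` - two complete decoders originate in the latent space and both
#'   receive skip connections from the single shared encoder.
#' * `v1_regression` - baseline: a segmentation decoder plus direct point
#'   regression from the latent space via global average pooling and a dense
#'   layer (4 scalars: ap_x, ap_y, pp_x, pp_y, in pixels).
#'
#' Temporal modes extend the `v2e` topology to video input:
#'
#' * `channels` - the frames of a clip are stacked in the channel dimension
#'   of a 2D network; outputs refer to the centre frame of the window.
#' * `conv3d` - 3x3x3 convolutions replace the 2D convolutions; pooling and
#'   upsampling act spatially, so one prediction is emitted per frame.
#' * `convlstm` - each level's double convolution is replaced by a single
#'   sequence-returning convolutional LSTM; the last decoder level uses two
#'   3D convolutions; one prediction per frame.
#'
#' @param variant one of `"v2a"`, `"v2b"`, `"v2c"`, `"v2d"`, `"v2e"`,
#'   `"v1_regression"`.
#' @param temporal_mode `"none"`, `"channels"`, `"conv3d"` or `"convlstm"`.
#' @param base_filters filter count of the first level; doubled at each of
#'   the four levels. The final 2D model of record uses 16.
#' @param normalization `"instance"` (default, used by the final model) or
#'   `"batch"`. With per-sample optimization both use per-sample statistics
#'   during training; `"batch"` additionally tracks running statistics that
#'   are used at inference time.
#' @param n_frames frames per clip for temporal modes (>= 2).
#' @param input_size `c(H, W)` in pixels; both must be divisible by 16
#'   (four 2x2 poolings).
#' @param in_channels input channels of a single frame (1 for grayscale).
#' @param seed integer seed for weight initialization.
#' @return a `midline_model_config` list.
#' @export
model_config <- function(variant = "v2e", temporal_mode = "none",
                         base_filters = 16, normalization = "instance",
                         n_frames = NULL, input_size = c(512, 256),
                         in_channels = 1, seed = 42) {
  variants <- c("v2a", "v2b", "v2c", "v2d", "v2e", "v1_regression")
  if (!is.character(variant) || length(variant) != 1 || !variant %in% variants)
    ml_config_error(sprintf("unknown variant '%s' (expected one of %s)",
                            paste(variant, collapse = ","),
                            paste(variants, collapse = ", ")))
  modes <- c("none", "channels", "conv3d", "convlstm")
  if (!temporal_mode %in% modes)
    ml_config_error(sprintf("unknown temporal_mode '%s'", temporal_mode))
  if (!normalization %in% c("batch", "instance"))
    ml_config_error(sprintf("unknown normalization '%s'", normalization))
  if (length(input_size) != 2 || any(input_size < 16) ||
      any(input_size %% 16 != 0))
    ml_config_error(paste0("input_size must be c(H, W) with both divisible ",
                           "by 16 (four pooling levels); got ",
                           paste(input_size, collapse = "x")))
  if (base_filters < 1) ml_config_error("base_filters must be >= 1")
  if (temporal_mode != "none") {
    if (is.null(n_frames) || n_frames < 2)
      ml_config_error("temporal modes require n_frames >= 2")
    if (temporal_mode %in% c("conv3d", "convlstm") && variant != "v2e")
      ml_config_error(paste0("temporal_mode '", temporal_mode,
                             "' is implemented for the dual-decoder (v2e) ",
                             "topology only"))
  }
  structure(list(variant = variant, temporal_mode = temporal_mode,
                 base_filters = as.integer(base_filters),
                 normalization = normalization, depth = 4L,
                 n_frames = if (is.null(n_frames)) NULL else as.integer(n_frames),
                 input_size = as.integer(input_size),
                 in_channels = as.integer(in_channels),
                 seed = as.integer(seed)),
            class = "midline_model_config")
}

# ---- parameter store and layer helpers ------------------------------------

new_ctx <- function(model, tape, init = FALSE, training = FALSE) {
  list(tape = tape, ps = model$ps, cfg = model$config, init = init,
       training = training, state = model$state)
}

param <- function(ctx, name, shape, init = c("he", "glorot", "zero", "one"),
                  fan_in = NULL, forget_bias = FALSE) {
  if (is.null(ctx$ps$params[[name]])) {
    if (!ctx$init)
      ml_config_error(sprintf("parameter '%s' missing from model", name))
    init <- match.arg(init)
    n <- prod(shape)
    v <- switch(init,
      he = stats::rnorm(n, sd = sqrt(2 / fan_in)),
      glorot = stats::rnorm(n, sd = sqrt(2 / (fan_in + shape[length(shape)]))),
      zero = rep(0, n),
      one = rep(1, n))
    v <- if (length(shape) > 1) array(v, dim = shape) else as.numeric(v)
    if (forget_bias) {
      # convolutional LSTM bias: start with an open forget gate
      cout <- length(v) / 4
      v[seq.int(cout + 1, 2 * cout)] <- 1
    }
    ctx$ps$params[[name]] <- v
  }
  tp_param(ctx$tape, ctx$ps$params, name)
}

ly_conv <- function(ctx, x, name, cout, kh = 3L) {
  cin <- dim(x$value)[length(dim(x$value))]
  w <- param(ctx, paste0(name, ".w"), c(kh, kh, cin, cout), "he",
             fan_in = kh * kh * cin)
  b <- param(ctx, paste0(name, ".b"), cout, "zero")
  op_conv2d(ctx$tape, x, w, b, kh, kh, cache_cols = isTRUE(ctx$training))
}

ly_conv3 <- function(ctx, x, name, cout) {
  cin <- dim(x$value)[4]
  w <- param(ctx, paste0(name, ".w"), c(3, 3, 3, cin, cout), "he",
             fan_in = 27 * cin)
  b <- param(ctx, paste0(name, ".b"), cout, "zero")
  op_conv3d(ctx$tape, x, w, b)
}

ly_head <- function(ctx, x, name, cout) {
  cin <- dim(x$value)[length(dim(x$value))]
  w <- param(ctx, paste0(name, ".w"), c(cin, cout), "glorot", fan_in = cin)
  b <- param(ctx, paste0(name, ".b"), cout, "zero")
  op_sigmoid(ctx$tape, op_conv1x1(ctx$tape, x, w, b))
}

ly_norm <- function(ctx, x, name) {
  C <- dim(x$value)[length(dim(x$value))]
  g <- param(ctx, paste0(name, ".g"), C, "one")
  b <- param(ctx, paste0(name, ".b"), C, "zero")
  if (ctx$cfg$normalization == "batch" && !ctx$training && !ctx$init &&
      !is.null(ctx$state$running[[name]])) {
    rs <- ctx$state$running[[name]]
    d <- dim(x$value)
    n <- prod(d) / C
    xm <- matrix(x$value, n, C)
    xhat <- sweep(sweep(xm, 2, rs$mean), 2, sqrt(rs$var + 1e-5), "/")
    ym <- sweep(sweep(xhat, 2, g$value, "*"), 2, b$value, "+")
    # affine in x: gradient not needed at inference
    return(tp_node(ctx$tape, array(ym, dim = d)))
  }
  out <- op_instnorm(ctx$tape, x, g, b)
  if (ctx$cfg$normalization == "batch" && (ctx$training || ctx$init)) {
    d <- dim(x$value)
    n <- prod(d) / C
    xm <- matrix(x$value, n, C)
    mu <- colMeans(xm)
    vr <- colMeans(sweep(xm, 2, mu)^2)
    old <- ctx$state$running[[name]]
    if (is.null(old)) ctx$state$running[[name]] <- list(mean = mu, var = vr)
    else ctx$state$running[[name]] <-
        list(mean = 0.9 * old$mean + 0.1 * mu, var = 0.9 * old$var + 0.1 * vr)
  }
  out
}

ly_block <- function(ctx, x, name, cout) {
  x <- op_relu(ctx$tape, ly_norm(ctx, ly_conv(ctx, x, paste0(name, ".c1"), cout),
                                 paste0(name, ".n1")))
  op_relu(ctx$tape, ly_norm(ctx, ly_conv(ctx, x, paste0(name, ".c2"), cout),
                            paste0(name, ".n2")))
}

ly_block3 <- function(ctx, x, name, cout) {
  x <- op_relu(ctx$tape, ly_norm(ctx, ly_conv3(ctx, x, paste0(name, ".c1"), cout),
                                 paste0(name, ".n1")))
  op_relu(ctx$tape, ly_norm(ctx, ly_conv3(ctx, x, paste0(name, ".c2"), cout),
                            paste0(name, ".n2")))
}

ly_tconv <- function(ctx, x, name, cout) {
  cin <- dim(x$value)[length(dim(x$value))]
  w <- param(ctx, paste0(name, ".w"), c(2, 2, cin, cout), "he",
             fan_in = 4 * cin)
  b <- param(ctx, paste0(name, ".b"), cout, "zero")
  if (length(dim(x$value)) == 4) op_tconv2_s(ctx$tape, x, w, b)
  else op_tconv2(ctx$tape, x, w, b)
}

ly_convlstm <- function(ctx, xs, name, cout) {
  cin <- dim(xs[[1]]$value)[3]
  d <- dim(xs[[1]]$value)
  wx <- param(ctx, paste0(name, ".wx"), c(3, 3, cin, 4 * cout), "he",
              fan_in = 9 * cin)
  wh <- param(ctx, paste0(name, ".wh"), c(3, 3, cout, 4 * cout), "glorot",
              fan_in = 9 * cout)
  b <- param(ctx, paste0(name, ".b"), 4 * cout, "zero", forget_bias = TRUE)
  bz <- tp_const(ctx$tape, rep(0, 4 * cout))
  h <- tp_const(ctx$tape, array(0, c(d[1], d[2], cout)))
  cc <- tp_const(ctx$tape, array(0, c(d[1], d[2], cout)))
  out <- vector("list", length(xs))
  for (t in seq_along(xs)) {
    gates <- op_add(ctx$tape,
                    op_conv2d(ctx$tape, xs[[t]], wx, b),
                    op_conv2d(ctx$tape, h, wh, bz))
    gi <- op_sigmoid(ctx$tape, op_slice_c(ctx$tape, gates, 1, cout))
    gf <- op_sigmoid(ctx$tape, op_slice_c(ctx$tape, gates, cout + 1, 2 * cout))
    gc <- op_tanh(ctx$tape, op_slice_c(ctx$tape, gates, 2 * cout + 1, 3 * cout))
    go <- op_sigmoid(ctx$tape, op_slice_c(ctx$tape, gates, 3 * cout + 1, 4 * cout))
    cc <- op_add(ctx$tape, op_mul(ctx$tape, gf, cc), op_mul(ctx$tape, gi, gc))
    h <- op_mul(ctx$tape, go, op_tanh(ctx$tape, cc))
    out[[t]] <- h
  }
  out
}

# ---- forward graphs -------------------------------------------------------

filters_at <- function(cfg) cfg$base_filters * 2^(0:4)

fw_encoder <- function(ctx, x) {
  f <- filters_at(ctx$cfg)
  skips <- vector("list", 4)
  for (l in 1:4) {
    x <- ly_block(ctx, x, sprintf("enc%d", l), f[l])
    skips[[l]] <- x
    x <- op_maxpool2(ctx$tape, x)
  }
  latent <- ly_block(ctx, x, "latent", f[5])
  list(latent = latent, skips = skips)
}

fw_decoder <- function(ctx, x, skips, prefix, to_level = 1L) {
  f <- filters_at(ctx$cfg)
  for (l in 4:to_level) {
    x <- ly_tconv(ctx, x, sprintf("%s%d.up", prefix, l), f[l])
    x <- op_concat_c(ctx$tape, x, skips[[l]])
    x <- ly_block(ctx, x, sprintf("%s%d", prefix, l), f[l])
  }
  x
}

forward_2d <- function(ctx, x) {
  cfg <- ctx$cfg
  tape <- ctx$tape
  enc <- fw_encoder(ctx, x)
  f <- filters_at(cfg)
  if (cfg$variant == "v2a") {
    d <- fw_decoder(ctx, enc$latent, enc$skips, "dec")
    list(seg = ly_head(ctx, d, "seg_head", 1),
         kp = ly_head(ctx, d, "kp_head", 2))
  } else if (cfg$variant == "v2c") {
    d <- fw_decoder(ctx, enc$latent, enc$skips, "dec")
    ap <- ly_head(ctx, d, "ap_head", 1)
    pp <- ly_head(ctx, d, "pp_head", 1)
    list(seg = ly_head(ctx, d, "seg_head", 1),
         kp = op_concat_c(tape, ap, pp), n_heads = 3L)
  } else if (cfg$variant == "v2b") {
    d <- fw_decoder(ctx, enc$latent, enc$skips, "dec", to_level = 2L)
    d <- ly_tconv(ctx, d, "dec1.up", f[1])
    d <- op_concat_c(tape, d, enc$skips[[1]])
    d <- op_relu(tape, ly_norm(ctx, ly_conv(ctx, d, "dec1.c1", f[1]), "dec1.n1"))
    segb <- op_relu(tape, ly_norm(ctx, ly_conv(ctx, d, "seg1.c2", f[1]), "seg1.n2"))
    kpb <- op_relu(tape, ly_norm(ctx, ly_conv(ctx, d, "kp1.c2", f[1]), "kp1.n2"))
    list(seg = ly_head(ctx, segb, "seg_head", 1),
         kp = ly_head(ctx, kpb, "kp_head", 2))
  } else if (cfg$variant == "v2d") {
    d <- fw_decoder(ctx, enc$latent, enc$skips, "dec", to_level = 2L)
    segb <- ly_tconv(ctx, d, "seg1.up", f[1])
    segb <- ly_block(ctx, op_concat_c(tape, segb, enc$skips[[1]]), "seg1", f[1])
    kpb <- ly_tconv(ctx, d, "kp1.up", f[1])
    kpb <- ly_block(ctx, op_concat_c(tape, kpb, enc$skips[[1]]), "kp1", f[1])
    list(seg = ly_head(ctx, segb, "seg_head", 1),
         kp = ly_head(ctx, kpb, "kp_head", 2))
  } else if (cfg$variant == "v2e") {
    dseg <- fw_decoder(ctx, enc$latent, enc$skips, "dseg")
    dkp <- fw_decoder(ctx, enc$latent, enc$skips, "dkp")
    list(seg = ly_head(ctx, dseg, "seg_head", 1),
         kp = ly_head(ctx, dkp, "kp_head", 2))
  } else { # v1_regression
    dseg <- fw_decoder(ctx, enc$latent, enc$skips, "dseg")
    g <- op_gap(tape, enc$latent)
    wd <- param(ctx, "pts.w", c(length(g$value), 4), "glorot",
                fan_in = length(g$value))
    bd <- param(ctx, "pts.b", 4, "zero")
    pts <- op_sigmoid(tape, op_dense(tape, g, wd, bd))
    scale <- tp_const(tape, c(cfg$input_size[2] - 1, cfg$input_size[1] - 1,
                              cfg$input_size[2] - 1, cfg$input_size[1] - 1))
    list(seg = ly_head(ctx, dseg, "seg_head", 1),
         points = op_mul(tape, pts, scale))
  }
}

# v2e topology with 3D convolutions; pooling/upsampling act spatially so the
# time dimension is preserved end to end.
forward_conv3d <- function(ctx, x) {
  f <- filters_at(ctx$cfg)
  skips <- vector("list", 4)
  for (l in 1:4) {
    x <- ly_block3(ctx, x, sprintf("enc%d", l), f[l])
    skips[[l]] <- x
    x <- op_maxpool2_s(ctx$tape, x)
  }
  x <- ly_block3(ctx, x, "latent", f[5])
  dec <- function(prefix) {
    d <- x
    for (l in 4:1) {
      d <- ly_tconv(ctx, d, sprintf("%s%d.up", prefix, l), f[l])
      d <- op_concat_c(ctx$tape, d, skips[[l]])
      d <- ly_block3(ctx, d, sprintf("%s%d", prefix, l), f[l])
    }
    d
  }
  list(seg = ly_head(ctx, dec("dseg"), "seg_head", 1),
       kp = ly_head(ctx, dec("dkp"), "kp_head", 2))
}

# v2e topology where each level's double convolution is one sequence-returning
# convolutional LSTM; the last decoder level uses two 3D convolutions.
forward_convlstm <- function(ctx, x4) {
  tape <- ctx$tape
  f <- filters_at(ctx$cfg)
  T_ <- dim(x4$value)[3]
  xs <- lapply(seq_len(T_), function(t) op_slice_frame(tape, x4, t))
  skips <- vector("list", 4)
  for (l in 1:4) {
    xs <- ly_convlstm(ctx, xs, sprintf("enc%d", l), f[l])
    skips[[l]] <- xs
    xs <- lapply(xs, function(z) op_maxpool2(tape, z))
  }
  xs <- ly_convlstm(ctx, xs, "latent", f[5])
  dec <- function(prefix) {
    d <- xs
    for (l in 4:2) {
      d <- lapply(d, function(z) ly_tconv(ctx, z, sprintf("%s%d.up", prefix, l), f[l]))
      d <- lapply(seq_len(T_), function(t) op_concat_c(tape, d[[t]], skips[[l]][[t]]))
      d <- ly_convlstm(ctx, d, sprintf("%s%d", prefix, l), f[l])
    }
    d <- lapply(d, function(z) ly_tconv(ctx, z, sprintf("%s1.up", prefix), f[1]))
    d <- lapply(seq_len(T_), function(t) op_concat_c(tape, d[[t]], skips[[1]][[t]]))
    ly_block3(ctx, op_stack_frames(tape, d), sprintf("%s1", prefix), f[1])
  }
  list(seg = ly_head(ctx, dec("dseg"), "seg_head", 1),
       kp = ly_head(ctx, dec("dkp"), "kp_head", 2))
}

# Run the forward graph; x is an array shaped per the temporal mode:
# (H, W, C) for "none"/"channels", (H, W, T, C) for "conv3d"/"convlstm".
model_forward <- function(model, x, tape, training = FALSE, init = FALSE) {
  ctx <- new_ctx(model, tape, init = init, training = training)
  xn <- tp_const(tape, x)
  switch(model$config$temporal_mode,
         none = forward_2d(ctx, xn),
         channels = forward_2d(ctx, xn),
         conv3d = forward_conv3d(ctx, xn),
         convlstm = forward_convlstm(ctx, xn))
}

zero_input <- function(cfg) {
  H <- cfg$input_size[1]; W <- cfg$input_size[2]
  switch(cfg$temporal_mode,
         none = array(0, c(H, W, cfg$in_channels)),
         channels = array(0, c(H, W, cfg$n_frames)),
         array(0, c(H, W, cfg$n_frames, cfg$in_channels)))
}

#' Build a model
#'
#' Materializes all weights of the configured network (seeded He/Glorot
#' initialization) by tracing the forward graph once on a zero input.
#'
#' @param config a [model_config()].
#' @return a `midline_model` with elements `config`, `ps` (parameter store)
#'   and `state` (running statistics for batch normalization).
#' @export
build_model <- function(config) {
  if (!inherits(config, "midline_model_config"))
    config <- do.call(model_config, config)
  model <- structure(list(config = config,
                          ps = new.env(parent = emptyenv()),
                          state = new.env(parent = emptyenv())),
                     class = "midline_model")
  model$ps$params <- list()
  model$state$running <- list()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(config$seed)
  tape <- new_tape()
  invisible(model_forward(model, zero_input(config), tape, init = TRUE))
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  model
}

#' Build a temporal model
#'
#' Convenience wrapper over [build_model()] for video input. `channels` stacks
#' the clip in the input channel dimension and predicts the centre frame;
#' `conv3d` and `convlstm` emit one prediction per frame.
#'
#' @param config a [model_config()] with `temporal_mode != "none"`.
#' @return a `midline_model`.
#' @export
build_temporal_model <- function(config) {
  if (!inherits(config, "midline_model_config"))
    config <- do.call(model_config, config)
  if (config$temporal_mode == "none")
    ml_config_error("build_temporal_model requires temporal_mode != 'none'")
  build_model(config)
}

#' Count trainable parameters
#'
#' @param model a `midline_model`.
#' @return total number of trainable scalars.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$ps$params, length, integer(1)))
}

#' Forward pass on one input
#'
#' @param model a `midline_model`.
#' @param x input array shaped for the model's temporal mode: `(H, W, C)` for
#'   2D and channels modes, `(H, W, T, C)` for `conv3d`/`convlstm`.
#' @return list with `seg` (segmentation map in `[0,1]`) and either
#'   `keypoint_maps` (anterior map in channel 1, posterior in channel 2) or,
#'   for `v1_regression`, `points` (ap_x, ap_y, pp_x, pp_y in pixels).
#' @export
predict_frame <- function(model, x) {
  tape <- new_tape()
  out <- model_forward(model, x, tape, training = FALSE)
  res <- list(seg = out$seg$value)
  if (!is.null(out$points)) res$points <- out$points$value
  else res$keypoint_maps <- out$kp$value
  res
}

#' Save / load a model
#'
#' Weights are stored with `saveRDS`; the configuration is additionally
#' written as JSON next to the checkpoint for inspection.
#'
#' @param model a `midline_model`.
#' @param path checkpoint file path (`.rds`).
#' @return `path`, invisibly (`save_model`); a `midline_model` (`load_model`).
#' @export
save_model <- function(model, path) {
  obj <- list(config = unclass(model$config), params = model$ps$params,
              running = model$state$running)
  saveRDS(obj, path)
  jsonlite::write_json(obj$config, paste0(sub("\\.rds$", "", path), "_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  cfg <- do.call(model_config, obj$config[setdiff(names(obj$config), "depth")])
  model <- structure(list(config = cfg,
                          ps = new.env(parent = emptyenv()),
                          state = new.env(parent = emptyenv())),
                     class = "midline_model")
  model$ps$params <- obj$params
  model$state$running <- obj$running
  model
}

#' @export
print.midline_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<midline_model> variant=%s temporal=%s filters=%d norm=%s input=%s params=%d\n",
              cfg$variant, cfg$temporal_mode, cfg$base_filters,
              cfg$normalization, paste(cfg$input_size, collapse = "x"),
              count_parameters(x)))
  invisible(x)
}
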