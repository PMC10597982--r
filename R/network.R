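# The two-stage predictor: a shared-weight U-Net applied independently to
# every input frame (10 feature maps per frame), and a pointwise 1x1-conv
# head mapping each voxel's concatenated feature vector to either the five
# 2TCM parameters (full, physics-constrained variant) or directly to the six
# target frames (the "without model" ablation).

unet_init <- function(in_ch = 1, channels = c(64, 128, 256, 512, 1024),
                      out_ch = 10) {
  stopifnot(length(channels) == 5)
  net <- list(inc = dc_init(in_ch, channels[1]))
  for (i in 1:4) {
    net[[paste0("down", i)]] <- dc_init(channels[i], channels[i + 1])
  }
  for (i in 1:4) {
    net[[paste0("up", i)]] <- list(
      up = convt2_init(channels[6 - i], channels[5 - i]),
      dc = dc_init(2 * channels[5 - i], channels[5 - i]))
  }
  net$outc <- conv1_init(channels[1], out_ch)
  net
}

unet_fw <- function(net, x, gsize = 16, keep = TRUE) {
  enc <- vector("list", 5)
  caches <- list()
  s <- dc_fw(net$inc, x, gsize)
  enc[[1]] <- s$y; caches$inc <- s$cache
  for (i in 1:4) {
    p <- maxpool_fw(enc[[i]])
    s <- dc_fw(net[[paste0("down", i)]], p$y, gsize)
    enc[[i + 1]] <- s$y
    caches[[paste0("pool", i)]] <- p$cache
    caches[[paste0("down", i)]] <- s$cache
  }
  y <- enc[[5]]
  for (i in 1:4) {
    u <- convt2_fw(net[[paste0("up", i)]]$up, y)
    skip <- enc[[5 - i]]
    cat_in <- concat_c(u$y, skip)
    s <- dc_fw(net[[paste0("up", i)]]$dc, cat_in, gsize)
    y <- s$y
    caches[[paste0("upc", i)]] <- u$cache
    caches[[paste0("updc", i)]] <- s$cache
    caches[[paste0("upsplit", i)]] <- dim(u$y)[3]
  }
  o <- conv1_fw(net$outc, y)
  caches$outc <- o$cache
  caches$bottleneck_dim <- dim(enc[[5]])
  list(y = o$y, cache = if (keep) caches else NULL,
       bottleneck_dim = dim(enc[[5]]))
}

unet_bw <- function(net, cache, dy, gsize = 16) {
  grads <- list()
  o <- conv1_bw(net$outc, cache$outc, dy)
  grads$outc <- o$grad
  dy <- o$dx
  dskip <- vector("list", 5)  # gradients w.r.t. encoder outputs
  for (i in 4:1) {
    s <- dc_bw(net[[paste0("up", i)]]$dc, cache[[paste0("updc", i)]], dy,
               gsize)
    parts <- split_c(s$dx, cache[[paste0("upsplit", i)]])
    u <- convt2_bw(net[[paste0("up", i)]]$up, cache[[paste0("upc", i)]],
                   parts$a)
    grads[[paste0("up", i)]] <- list(up = u$grad, dc = s$grad)
    dskip[[5 - i]] <- parts$b
    dy <- u$dx
  }
  # dy now reaches the bottleneck (enc5)
  for (i in 4:1) {
    s <- dc_bw(net[[paste0("down", i)]], cache[[paste0("down", i)]], dy,
               gsize)
    grads[[paste0("down", i)]] <- s$grad
    dp <- maxpool_bw(cache[[paste0("pool", i)]], s$dx)
    dy <- dp + if (!is.null(dskip[[i]])) dskip[[i]] else 0
  }
  s <- dc_bw(net$inc, cache$inc, dy, gsize)
  grads$inc <- s$grad
  list(dx = s$dx, grads = grads)
}

# The output layer starts near zero so a bounded (sigmoid) head begins at
# the middle of its parameter ranges with healthy gradients instead of at a
# saturated extreme.
head_init <- function(in_ch, hidden = c(256, 128, 64), out_ch,
                      final_scale = 0.01) {
  chs <- c(in_ch, hidden, out_ch)
  layers <- list()
  for (i in seq_len(length(chs) - 1)) {
    layers[[paste0("l", i)]] <- conv1_init(chs[i], chs[i + 1])
  }
  nl <- length(chs) - 1
  layers[[paste0("l", nl)]]$w <- layers[[paste0("l", nl)]]$w * final_scale
  layers
}

head_fw <- function(head, x, final = c("sigmoid", "linear"), ranges = NULL) {
  final <- match.arg(final)
  nl <- length(head)
  caches <- list()
  for (i in seq_len(nl)) {
    s <- conv1_fw(head[[paste0("l", i)]], x)
    caches[[paste0("l", i)]] <- s$cache
    if (i < nl) {
      r <- relu_fw(s$y)
      caches[[paste0("r", i)]] <- r$cache
      x <- r$y
    } else {
      x <- s$y
    }
  }
  if (final == "sigmoid") {
    sg <- sigmoid_fw(x)
    caches$sig <- sg$cache
    lo <- ranges[1, ]; hi <- ranges[2, ]
    d <- dim(sg$y)
    y <- sg$y * array(rep(hi - lo, each = d[1] * d[2]), d) +
      array(rep(lo, each = d[1] * d[2]), d)
  } else {
    y <- x
  }
  list(y = y, cache = caches)
}

head_bw <- function(head, cache, dy, final = c("sigmoid", "linear"),
                    ranges = NULL) {
  final <- match.arg(final)
  if (final == "sigmoid") {
    d <- dim(dy)
    lo <- ranges[1, ]; hi <- ranges[2, ]
    dy <- dy * array(rep(hi - lo, each = d[1] * d[2]), d)
    dy <- sigmoid_bw(cache$sig, dy)
  }
  nl <- length(grep("^l", names(cache)))
  grads <- list()
  for (i in nl:1) {
    if (i < nl) dy <- relu_bw(cache[[paste0("r", i)]], dy)
    s <- conv1_bw(head[[paste0("l", i)]], cache[[paste0("l", i)]], dy)
    grads[[paste0("l", i)]] <- s$grad
    dy <- s$dx
  }
  list(dx = dy, grads = grads)
}

#' Default output ranges of the kinetic-parameter head
#'
#' The head's final sigmoid is scaled into per-parameter bounds so predicted
#' parameters are always physiological: `f_v` in `[0, 1]`, `K1`, `k2` in
#' `[0, 2]`, `k3` in `[0, 0.5]`, `k4` in `[0, 0.2]` (1/min) -- the phantom's
#' sampling bounds with headroom.
#'
#' @return A `2 x 5` matrix (rows `lo`, `hi`; columns the parameter order
#'   `f_v, K1, k2, k3, k4`).
#' @export
default_param_ranges <- function() {
  m <- rbind(lo = c(0, 0, 0, 0, 0), hi = c(1, 2, 2, 0.5, 0.2))
  colnames(m) <- c("f_v", "K1", "k2", "k3", "k4")
  m
}

#' Build the two-stage dynamic-PET predictor
#'
#' A shared-weight U-Net (DoubleConv blocks; 4 max-pool downsamplings to
#' 1/16 resolution; 4 transposed-convolution upsamplings with skip
#' connections; GroupNorm with 16 channels per group + ReLU) extracts
#' `features_per_frame` maps from each input frame independently; the
#' concatenated per-voxel feature vector (`22 x 10 = 220`-dim by default)
#' feeds a pointwise 1x1-convolution head.  With `variant = "kinetic"` the
#' head emits the five 2TCM parameters through a range-scaled sigmoid and the
#' differentiable kinetic layer renders all frames; with
#' `variant = "direct"` ("without model" ablation) the head emits the six
#' target frames directly with no final activation.
#'
#' @param variant `"kinetic"` (full model) or `"direct"` (ablation).
#' @param input_frames number of input frames (default 22).
#' @param target_frames number of directly predicted frames for the ablation
#'   head (default 6).
#' @param features_per_frame U-Net output channels per frame (default 10).
#' @param base_channels full-fidelity encoder widths (default
#'   `64, 128, 256, 512, 1024`).
#' @param channel_scale multiplier shrinking all widths for CPU-scale
#'   training (default 1 = full width); scaled widths are kept `>= 4`.
#' @param head_hidden hidden widths of the pointwise head.
#' @param param_ranges `2 x 5` bounds matrix, see [default_param_ranges()].
#' @param gn_channels_per_group GroupNorm group size (default 16).
#' @param seed RNG seed for the fan-in-scaled random initialization.
#' @return A `pet_predictor` object.
#' @export
pet_predictor <- function(variant = c("kinetic", "direct"),
                          input_frames = 22, target_frames = 6,
                          features_per_frame = 10,
                          base_channels = c(64, 128, 256, 512, 1024),
                          channel_scale = 1,
                          head_hidden = c(256, 128, 64),
                          param_ranges = default_param_ranges(),
                          gn_channels_per_group = 16, seed = 1) {
  variant <- match.arg(variant)
  channels <- pmax(4L, as.integer(round(base_channels * channel_scale)))
  feat_dim <- input_frames * features_per_frame
  out_ch <- if (variant == "kinetic") ncol(param_ranges) else target_frames
  with_seed(seed, {
    unet <- unet_init(1, channels, features_per_frame)
    head <- head_init(feat_dim, head_hidden, out_ch)
  })
  structure(list(
    unet = unet, head = head,
    config = list(variant = variant, input_frames = input_frames,
                  target_frames = target_frames,
                  features_per_frame = features_per_frame,
                  channels = channels, head_hidden = head_hidden,
                  param_ranges = param_ranges,
                  gn_channels_per_group = gn_channels_per_group,
                  seed = seed)),
    class = "pet_predictor")
}

#' @export
print.pet_predictor <- function(x, ...) {
  cfg <- x$config
  np <- sum(vapply(flatten_params(x$unet), length, numeric(1))) +
    sum(vapply(flatten_params(x$head), length, numeric(1)))
  cat(sprintf("pet_predictor (%s): channels %s; %d-dim features; %s params\n",
              cfg$variant, paste(cfg$channels, collapse = "/"),
              cfg$input_frames * cfg$features_per_frame,
              format(np, big.mark = ",")))
  invisible(x)
}

series_to_batch <- function(input) {
  # T x H x W -> (H, W, 1, T): each frame is one single-channel sample
  frames <- if (inherits(input, "dynamic_series")) input$frames else input
  d <- dim(frames)
  array(aperm(frames, c(2, 3, 1)), c(d[2], d[3], 1, d[1]))
}

#' Extract the per-voxel feature stack from the input frames
#'
#' Runs every input frame independently through the shared-weight U-Net and
#' concatenates the per-frame feature maps along channels, giving each voxel
#' a `input_frames x features_per_frame`-dimensional descriptor.
#'
#' @param model a [pet_predictor()].
#' @param input a [dynamic_series()] (or `T x H x W` array) of the input
#'   frames; `H`, `W` must be divisible by 16.
#' @param keep_cache keep layer caches for backprop (internal).
#' @return `(H, W, F, 1)` array with `F = input_frames * features_per_frame`
#'   channels; attribute `bottleneck_dim` records the deepest encoder shape.
#' @export
extract_features <- function(model, input, keep_cache = FALSE) {
  x <- series_to_batch(input)
  d <- dim(x)
  if (d[1] %% 16 != 0 || d[2] %% 16 != 0) {
    stop("bad-shape: H and W must be divisible by 16")
  }
  if (d[4] != model$config$input_frames) {
    stop(sprintf("bad-shape: expected %d input frames, got %d",
                 model$config$input_frames, d[4]))
  }
  r <- unet_fw(model$unet, x, model$config$gn_channels_per_group,
               keep = keep_cache)
  fy <- r$y  # (H, W, features_per_frame, T): flatten (C, N) to channels
  dn <- dim(fy)
  stack <- array(fy, c(dn[1], dn[2], dn[3] * dn[4], 1))
  attr(stack, "bottleneck_dim") <- r$bottleneck_dim
  if (keep_cache) attr(stack, "cache") <- r$cache
  stack
}

#' Predict per-voxel kinetic parameters from a feature stack
#'
#' The pointwise head: 1x1 convolutions with ReLU between layers and a
#' range-scaled sigmoid on the output, so each voxel is mapped independently
#' and all parameters respect the configured bounds.
#'
#' @param model a [pet_predictor()] with `variant = "kinetic"`.
#' @param features feature stack from [extract_features()].
#' @param keep_cache keep caches for backprop (internal).
#' @return `H x W x 5` parameter array (order `f_v, K1, k2, k3, k4`).
#' @export
predict_params <- function(model, features, keep_cache = FALSE) {
  stopifnot(model$config$variant == "kinetic")
  r <- head_fw(model$head, features, final = "sigmoid",
               ranges = model$config$param_ranges)
  d <- dim(r$y)
  maps <- array(r$y, c(d[1], d[2], d[3]),
                dimnames = list(NULL, NULL, colnames(model$config$param_ranges)))
  if (keep_cache) attr(maps, "cache") <- r$cache
  maps
}

#' Full forward pass: input frames to predicted dynamic series
#'
#' For the kinetic variant, predicted parameters are pushed through the
#' analytic kinetic layer to render every frame of `schedule` (28 by
#' default), so the output is differentiable end-to-end.  For the direct
#' ablation the head emits the target frames as image channels.
#'
#' @param model a [pet_predictor()].
#' @param input a [dynamic_series()] of input frames.
#' @param blood a [blood_input()] (kinetic variant only).
#' @param schedule the full output [frame_schedule()] (kinetic variant only;
#'   defaults to the input's schedule).
#' @param dt kinetic-layer quadrature step (min).
#' @return A list: `series` (predicted [dynamic_series()]; all frames for
#'   the kinetic variant, target frames only for the direct variant) and
#'   `maps` (parameter array, kinetic variant only).
#' @export
predict_series <- function(model, input, blood = NULL, schedule = NULL,
                           dt = 0.05) {
  cfg <- model$config
  feats <- extract_features(model, input)
  if (cfg$variant == "kinetic") {
    stopifnot(!is.null(blood))
    schedule <- schedule %||% (if (inherits(input, "dynamic_series"))
      input$schedule else NULL)
    stopifnot(inherits(schedule, "frame_schedule"))
    maps <- predict_params(model, feats)
    series <- simulate_dynamic_frames(maps, blood, schedule, dt = dt)
    list(series = series, maps = maps)
  } else {
    r <- head_fw(model$head, feats, final = "linear")
    d <- dim(r$y)
    frames <- aperm(array(r$y, d[1:3]), c(3, 1, 2))
    out <- list(series = frames, maps = NULL)
    if (!is.null(schedule)) {
      Tn <- length(schedule$starts)
      tgt <- seq.int(Tn - cfg$target_frames + 1, Tn)
      sub <- frame_schedule(schedule$starts[tgt], schedule$ends[tgt],
                            schedule$decay_lambda)
      out$series <- dynamic_series(frames, sub)
    }
    out
  }
}

# Kinetic layer with gradient bookkeeping: params (H x W x 5) -> frames
# (T x H x W) plus partials d frame / d param for backprop.
kinetic_layer_fw <- function(maps, blood, schedule, dt = 0.05,
                             decay_corrected = TRUE, eps = 1e-9) {
  d <- dim(maps)
  grid <- quadrature_grid(schedule, dt)
  c0 <- blood_value(blood, grid)
  idx <- schedule_index(grid, schedule)
  w <- decay_weights(grid, schedule, decay_corrected)
  P <- matrix(maps, nrow = d[1] * d[2], ncol = 5)
  res <- cpp_kinetic_forward(grid, c0, w, idx$s, idx$e, P, TRUE, eps, TRUE)
  Tn <- length(schedule$starts)
  list(frames = array(res$frames, c(Tn, d[1], d[2])),
       partials = res$partials, dims = d)
}

kinetic_layer_bw <- function(cache, dframes) {
  # dframes: T x H x W; partials: T x Npix x 5
  d <- cache$dims
  Tn <- dim(dframes)[1]
  dfm <- matrix(dframes, nrow = Tn)
  dmaps <- array(0, d)
  for (p in 1:5) {
    part <- matrix(cache$partials[, , p], nrow = Tn)
    dmaps[, , p] <- matrix(colSums(dfm * part), d[1], d[2])
  }
  dmaps
}
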