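# Composite training objective and the end-to-end loop.  The loss is
#   loss = loss_SUV + lambda * loss_diff
# with loss_SUV a mean Huber over the supervised (last-6) frames and
# loss_diff a mean Huber between successive-frame differences of the Patlak
# ordinate of the prediction and of the reference slope times the abscissa
# differences, over the linear-portion frames.

#' Huber loss
#'
#' Quadratic (`r^2/2`) below `delta`, linear (`delta (|r| - delta/2)`) above;
#' continuous with continuous first derivative.
#'
#' @param residual numeric vector/array of residuals.
#' @param delta threshold (`> 0`, default 1).
#' @return Elementwise loss values (same shape).
#' @export
huber <- function(residual, delta = 1) {
  if (delta <= 0) stop("delta must be > 0")
  a <- abs(residual)
  ifelse(a <= delta, 0.5 * residual^2, delta * (a - delta / 2))
}

huber_grad <- function(residual, delta = 1) {
  pmax(pmin(residual, delta), -delta)
}

#' Loss configuration
#'
#' @param huber_delta Huber threshold (SUV units; default 1).
#' @param lambda_weight weight of the Patlak time-difference term (default 1).
#' @param target_frame_indices supervised frames (default 23..28, the last 6
#'   of the 28-frame protocol).
#' @param linear_frame_indices Patlak linear-portion frames (default 16..28,
#'   the last 13).
#' @param ki_reference `"prediction"` (the slope target is re-fitted from the
#'   current prediction's own linear frames each step, treated as a constant)
#'   or `"truth"` (the ground-truth Ki map is the slope target).
#' @return A `loss_config` list.
#' @export
loss_config <- function(huber_delta = 1, lambda_weight = 1,
                        target_frame_indices = 23:28,
                        linear_frame_indices = 16:28,
                        ki_reference = c("prediction", "truth")) {
  if (lambda_weight < 0) stop("lambda_weight must be >= 0")
  structure(list(huber_delta = huber_delta, lambda_weight = lambda_weight,
                 target_frame_indices = as.integer(target_frame_indices),
                 linear_frame_indices = as.integer(linear_frame_indices),
                 ki_reference = match.arg(ki_reference)),
            class = "loss_config")
}

#' Optimizer configuration
#'
#' Adam with a step learning-rate schedule: start at `initial_lr`, multiply
#' by `decay_factor` every `decay_every_iters` iterations, never below
#' `lr_floor`.
#'
#' @param initial_lr initial learning rate (default `1e-4`).
#' @param decay_every_iters decay period (default 10000 iterations).
#' @param decay_factor multiplicative decay (default 0.1).
#' @param lr_floor lower bound (default `1e-7`).
#' @param epochs passes over the dataset (default 10).
#' @param clip_norm global gradient-norm ceiling (default 5; `Inf` disables).
#'   Keeps the bounded parameter head out of sigmoid saturation early in
#'   training.
#' @param seed RNG seed for the run.
#' @return An `optimizer_config` list.
#' @export
optimizer_config <- function(initial_lr = 1e-4, decay_every_iters = 10000,
                             decay_factor = 0.1, lr_floor = 1e-7,
                             epochs = 10, clip_norm = 5, seed = 1) {
  structure(list(initial_lr = initial_lr,
                 decay_every_iters = as.integer(decay_every_iters),
                 decay_factor = decay_factor, lr_floor = lr_floor,
                 epochs = as.integer(epochs), clip_norm = clip_norm,
                 seed = as.integer(seed)),
            class = "optimizer_config")
}

clip_gradients <- function(grads, max_norm) {
  if (!is.finite(max_norm)) return(grads)
  total <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (total > max_norm) {
    grads <- lapply(grads, function(g) g * (max_norm / total))
  }
  grads
}

#' Learning rate at a given iteration
#'
#' @param iteration 0-based iteration counter.
#' @param cfg an [optimizer_config()].
#' @return The learning rate.
#' @examples
#' lr_at(0, optimizer_config())      # 1e-4
#' lr_at(10000, optimizer_config())  # 1e-5
#' lr_at(1e6, optimizer_config())    # clamped at 1e-7
#' @export
lr_at <- function(iteration, cfg = optimizer_config()) {
  k <- floor(iteration / cfg$decay_every_iters)
  pmax(cfg$initial_lr * cfg$decay_factor^k, cfg$lr_floor)
}

frames_of <- function(x) if (inherits(x, "dynamic_series")) x$frames else x

#' SUV frame loss
#'
#' Mean Huber loss between predicted and ground-truth frames over the
#' supervised target frames and all pixels (`T` in the normalization counts
#' the supervised frames only); other frames do not contribute.
#'
#' @param pred,truth [dynamic_series()] or `T x H x W` arrays on the same
#'   schedule.
#' @param cfg a [loss_config()].
#' @param gradient when `TRUE` the result carries a `"grad"` attribute with
#'   the derivative w.r.t. every predicted frame value.
#' @return Scalar loss.
#' @export
loss_suv <- function(pred, truth, cfg = loss_config(), gradient = FALSE) {
  p <- frames_of(pred); g <- frames_of(truth)
  tgt <- cfg$target_frame_indices
  tgt <- tgt[tgt <= dim(p)[1] & tgt <= dim(g)[1]]
  if (!identical(dim(p)[2:3], dim(g)[2:3])) stop("shape mismatch")
  r <- p[tgt, , , drop = FALSE] - g[tgt, , , drop = FALSE]
  n <- length(r)
  val <- sum(huber(r, cfg$huber_delta)) / n
  if (gradient) {
    gr <- array(0, dim(p))
    gr[tgt, , ] <- huber_grad(r, cfg$huber_delta) / n
    attr(val, "grad") <- gr
  }
  val
}

#' Patlak time-difference loss
#'
#' Converts the predicted frames over the linear portion to Patlak ordinates
#' `y_k = pred_k / C_p(t_k)` and penalizes (Huber) the mismatch between their
#' successive differences and the differences `Ki(x, y) * (x_{k+1} - x_k)`
#' predicted by a reference slope map.  Differencing removes the intercept,
#' so the loss constrains only the late-time slope.  The slope target is
#' taken from `ki_ref` and treated as a constant (no gradient flows into it).
#'
#' @param pred predicted [dynamic_series()] or `T x H x W` array covering the
#'   linear-portion frames.
#' @param blood the [blood_input()] plasma curve.
#' @param ki_ref reference slope map (`H x W` matrix), or `NULL` to fit it
#'   from the prediction's own linear frames (per `cfg$ki_reference`).
#' @param cfg a [loss_config()].
#' @param schedule required when `pred` is a bare array.
#' @param gradient attach the derivative w.r.t. predicted frames.
#' @return Scalar loss.
#' @export
loss_diff <- function(pred, blood, ki_ref = NULL, cfg = loss_config(),
                      schedule = NULL, gradient = FALSE) {
  p <- frames_of(pred)
  schedule <- schedule %||% pred$schedule
  stopifnot(inherits(schedule, "frame_schedule"))
  lin <- cfg$linear_frame_indices
  if (length(lin) < 2) stop("too-few-frames")
  mid <- frame_mid_times(schedule)[lin]
  cp <- blood_value(blood, mid)
  if (any(cp <= 0)) stop("zero-plasma at a linear-portion frame")
  x <- blood_integral(blood, mid) / cp
  dx <- diff(x)
  if (is.null(ki_ref)) {
    fit <- ki_map(dynamic_series(p, schedule), blood, n_tail = length(lin))
    ki_ref <- fit$ki
  }
  d <- dim(p)
  L <- length(lin)
  y <- p[lin, , , drop = FALSE] / cp  # recycles cp along frames (dim 1)
  dy <- y[-1, , , drop = FALSE] - y[-L, , , drop = FALSE]
  tgt <- outer(dx, ki_ref)            # (L-1) x H x W (outer flattens H*W)
  dim(tgt) <- dim(dy)
  r <- dy - tgt
  n <- length(r)
  val <- sum(huber(r, cfg$huber_delta)) / n
  if (gradient) {
    hg <- huber_grad(r, cfg$huber_delta) / n
    gy <- array(0, c(L, d[2], d[3]))
    gy[-L, , ] <- gy[-L, , , drop = FALSE] - hg
    gy[-1, , ] <- gy[-1, , , drop = FALSE] + hg
    gr <- array(0, d)
    gr[lin, , ] <- gy / cp
    attr(val, "grad") <- gr
  }
  val
}

#' Total composite loss
#'
#' @param suv,diff the two loss terms.
#' @param lambda_weight weight of the difference term.
#' @return `suv + lambda_weight * diff`.
#' @export
total_loss <- function(suv, diff, lambda_weight = 1) {
  as.numeric(suv) + lambda_weight * as.numeric(diff)
}

# ---- Adam ----

adam_init <- function(flat) {
  list(m = lapply(flat, function(p) p * 0),
       v = lapply(flat, function(p) p * 0), t = 0)
}

adam_step <- function(flat, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(flat)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    flat[[nm]] <- flat[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(flat = flat, state = state)
}

model_flat <- function(model) {
  c(flatten_params(model$unet, "unet."),
    flatten_params(model$head, "head."))
}

model_unflat <- function(model, flat) {
  model$unet <- unflatten_into(model$unet, flat, "unet.")
  model$head <- unflatten_into(model$head, flat, "head.")
  model
}

# One forward+backward pass for a single training sample; returns losses and
# the flat gradient list.
training_step <- function(model, sample, loss_cfg, dt = 0.1) {
  cfg <- model$config
  input <- sample$input
  truth <- frames_of(sample$truth)
  blood <- sample$blood
  schedule <- sample$schedule
  gsize <- cfg$gn_channels_per_group
  feats <- extract_features(model, input, keep_cache = TRUE)
  unet_cache <- attr(feats, "cache")
  d <- dim(feats)
  if (cfg$variant == "kinetic") {
    hr <- head_fw(model$head, feats, final = "sigmoid",
                  ranges = cfg$param_ranges)
    maps <- array(hr$y, c(d[1], d[2], 5))
    kin <- kinetic_layer_fw(maps, blood, schedule, dt = dt)
    pred <- kin$frames
    ls <- loss_suv(pred, truth, loss_cfg, gradient = TRUE)
    ki_ref <- if (loss_cfg$ki_reference == "truth") sample$ki_true else NULL
    ld <- loss_diff(pred, blood, ki_ref, loss_cfg, schedule = schedule,
                    gradient = TRUE)
    dframes <- attr(ls, "grad") + loss_cfg$lambda_weight * attr(ld, "grad")
    dmaps <- kinetic_layer_bw(kin, dframes)
    hb <- head_bw(model$head, hr$cache, array(dmaps, c(d[1], d[2], 5, 1)),
                  final = "sigmoid", ranges = cfg$param_ranges)
  } else {
    hr <- head_fw(model$head, feats, final = "linear")
    predt <- aperm(array(hr$y, c(d[1], d[2], cfg$target_frames)), c(3, 1, 2))
    # assemble a full stack: known input frames + predicted target frames
    full <- array(0, dim(truth))
    ti <- seq_len(cfg$input_frames)
    full[ti, , ] <- frames_of(input)[ti, , ]
    full[loss_cfg$target_frame_indices, , ] <- predt
    ls <- loss_suv(full, truth, loss_cfg, gradient = TRUE)
    ki_ref <- if (loss_cfg$ki_reference == "truth") sample$ki_true else NULL
    ld <- loss_diff(full, blood, ki_ref, loss_cfg, schedule = schedule,
                    gradient = TRUE)
    dfull <- attr(ls, "grad") + loss_cfg$lambda_weight * attr(ld, "grad")
    dpred <- dfull[loss_cfg$target_frame_indices, , , drop = FALSE]
    dhead <- array(aperm(dpred, c(2, 3, 1)),
                   c(d[1], d[2], cfg$target_frames, 1))
    hb <- head_bw(model$head, hr$cache, dhead, final = "linear")
  }
  # dfeats (H, W, 220, 1) -> per-frame (H, W, 10, 22) for the U-Net
  dfeats <- array(hb$dx, c(d[1], d[2], cfg$features_per_frame,
                           cfg$input_frames))
  ub <- unet_bw(model$unet, unet_cache, dfeats, gsize)
  grads <- c(flatten_params(ub$grads, "unet."),
             flatten_params(hb$grads, "head."))
  list(loss_suv = as.numeric(ls), loss_diff = as.numeric(ld),
       loss = total_loss(ls, ld, loss_cfg$lambda_weight), grads = grads)
}

#' Train a predictor end-to-end
#'
#' Seeded, deterministic-given-seed loop: Adam with the step learning-rate
#' schedule, iterating over the dataset's slices in order.  Both variants
#' train under identical hyperparameters and the same composite loss.
#'
#' @param model a [pet_predictor()].
#' @param dataset list of samples, each a list with `input` (22-frame
#'   [dynamic_series()], SUV units), `truth` (full 28-frame series),
#'   `blood`, `schedule`, and optionally `ki_true` (for
#'   `ki_reference = "truth"`).
#' @param loss_cfg a [loss_config()].
#' @param opt_cfg an [optimizer_config()].
#' @param iterations total iteration count (default `epochs * length(dataset)`).
#' @param dt kinetic-layer quadrature step during training (min; coarser than
#'   the simulation default to save CPU).
#' @param verbose print progress every `verbose` iterations (0 = silent).
#' @return A `pet_fit` object: the trained `model`, the per-iteration `log`
#'   (tibble: iteration, sample, lr, loss terms) and the configs.
#' @export
train_predictor <- function(model, dataset, loss_cfg = loss_config(),
                            opt_cfg = optimizer_config(),
                            iterations = NULL, dt = 0.1, verbose = 0) {
  stopifnot(inherits(model, "pet_predictor"), length(dataset) >= 1)
  iterations <- iterations %||% (opt_cfg$epochs * length(dataset))
  flat <- model_flat(model)
  state <- adam_init(flat)
  log <- vector("list", iterations)
  with_seed(opt_cfg$seed, {
    for (it in seq_len(iterations) - 1L) {
      si <- (it %% length(dataset)) + 1L
      model <- model_unflat(model, flat)
      step <- training_step(model, dataset[[si]], loss_cfg, dt = dt)
      if (!is.finite(step$loss)) {
        stop(sprintf("non-finite loss at iteration %d", it))
      }
      lr <- lr_at(it, opt_cfg)
      upd <- adam_step(flat, clip_gradients(step$grads, opt_cfg$clip_norm),
                       state, lr)
      flat <- upd$flat
      state <- upd$state
      log[[it + 1L]] <- tibble::tibble(
        iteration = it, sample = si, lr = lr,
        loss_suv = step$loss_suv, loss_diff = step$loss_diff,
        loss = step$loss)
      if (verbose > 0 && it %% verbose == 0) {
        message(sprintf("iter %5d  lr %.2g  loss %.6f", it, lr, step$loss))
      }
    }
  })
  model <- model_unflat(model, flat)
  if (iterations == 0) {
    log <- list(tibble::tibble(iteration = integer(), sample = integer(),
                               lr = numeric(), loss_suv = numeric(),
                               loss_diff = numeric(), loss = numeric()))
  }
  structure(list(model = model, log = do.call(rbind, log),
                 loss_cfg = loss_cfg, opt_cfg = opt_cfg,
                 iterations = iterations),
            class = "pet_fit")
}

#' @export
print.pet_fit <- function(x, ...) {
  n <- nrow(x$log)
  cat(sprintf("pet_fit: %d iterations; loss %.5f -> %.5f\n", n,
              x$log$loss[1], x$log$loss[n]))
  invisible(x)
}

#' Save / load a training checkpoint
#'
#' The checkpoint records the model (weights + config), optimizer/loss
#' configuration, seed and a fingerprint of the frame schedule, so a restored
#' model can refuse inputs from a different protocol.
#'
#' @param fit a `pet_fit` or `pet_predictor`.
#' @param path destination file (RDS).
#' @param schedule the [frame_schedule()] the model was trained for.
#' @return `path`, invisibly (`read_checkpoint` returns the stored list).
#' @export
write_checkpoint <- function(fit, path, schedule = NULL) {
  obj <- list(fit = fit,
              schedule_fingerprint = if (!is.null(schedule))
                schedule_fingerprint(schedule) else NULL,
              package_version = as.character(utils::packageVersion("petkin")))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) readRDS(path)

schedule_fingerprint <- function(schedule) {
  paste(format(c(schedule$starts, schedule$ends, schedule$decay_lambda),
               digits = 12), collapse = ",")
}
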