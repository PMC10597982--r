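# Composite loss (Huber SUV term + Patlak time-difference term), learning
# rate schedule, gradient correctness through the kinetic layer, and the
# training loop's contracts.

test_that("Huber loss branches and derivative continuity", {
  expect_equal(huber(0), 0)
  expect_equal(huber(0.5, 1), 0.125)
  expect_equal(huber(2, 1), 1.5)
  expect_equal(huber(-2, 1), 1.5)
  # value and first derivative continuous at the branch point
  eps <- 1e-8
  expect_equal(huber(1 - eps), huber(1 + eps), tolerance = 1e-7)
  expect_equal(petkin:::huber_grad(1 - eps), petkin:::huber_grad(1 + eps),
               tolerance = 1e-7)
  expect_error(huber(1, delta = 0), "delta")
})

test_that("SUV loss masks to the target frames and matches a loop oracle", {
  cfg <- loss_config()
  set.seed(11)
  pred <- array(rnorm(28 * 5 * 4), c(28, 5, 4))
  truth <- array(rnorm(28 * 5 * 4), c(28, 5, 4))
  expect_equal(loss_suv(pred, pred, cfg), 0)

  val <- loss_suv(pred, truth, cfg)
  # naive triple loop over the supervised frames
  acc <- 0
  for (t in 23:28) for (i in 1:5) for (j in 1:4) {
    acc <- acc + huber(pred[t, i, j] - truth[t, i, j], 1)
  }
  expect_equal(val, acc / (6 * 5 * 4), tolerance = 1e-10)

  # perturbing a non-target frame changes nothing
  pred2 <- pred
  pred2[3, , ] <- pred2[3, , ] + 100
  expect_equal(loss_suv(pred2, truth, cfg), val)

  # analytic gradient vs central differences
  g <- attr(loss_suv(pred, truth, cfg, gradient = TRUE), "grad")
  for (k in 1:5) {
    t <- sample(23:28, 1); i <- sample(5, 1); j <- sample(4, 1)
    h <- 1e-6
    pp <- pred; pp[t, i, j] <- pp[t, i, j] + h
    pm <- pred; pm[t, i, j] <- pm[t, i, j] - h
    fd <- (loss_suv(pp, truth, cfg) - loss_suv(pm, truth, cfg)) / (2 * h)
    expect_equal(g[t, i, j], fd, tolerance = 1e-6)
  }
  expect_true(all(g[1:22, , ] == 0))
})

test_that("Patlak difference loss vanishes on-slope and matches a loop oracle", {
  blood <- fixture_blood(0.05)
  sch <- fixture_schedule()
  cfg <- loss_config()
  lin <- cfg$linear_frame_indices
  mid <- frame_mid_times(sch)
  cp <- blood_value(blood, mid)
  x <- blood_integral(blood, mid) / cp

  # frames built exactly as C_p(t) K x(t): zero loss against that K
  K <- matrix(0.03, 3, 2)
  frames <- array(0, c(28, 3, 2))
  for (t in 1:28) frames[t, , ] <- cp[t] * 0.03 * x[t]
  expect_equal(loss_diff(frames, blood, K, cfg, schedule = sch), 0,
               tolerance = 1e-20)

  # adding a constant to y on all linear frames leaves the loss unchanged
  frames2 <- frames
  for (t in lin) frames2[t, , ] <- frames2[t, , ] + 0.4 * cp[t]
  expect_equal(loss_diff(frames2, blood, K, cfg, schedule = sch), 0,
               tolerance = 1e-20)

  # random frames vs an explicit elementwise oracle
  set.seed(12)
  frames3 <- array(abs(rnorm(28 * 3 * 2, mean = 2)), c(28, 3, 2))
  val <- loss_diff(frames3, blood, K, cfg, schedule = sch)
  acc <- 0
  for (i in 1:3) for (j in 1:2) {
    y <- frames3[lin, i, j] / cp[lin]
    for (k in seq_len(length(lin) - 1)) {
      acc <- acc + huber((y[k + 1] - y[k]) - K[i, j] * (x[lin][k + 1] -
                                                         x[lin][k]), 1)
    }
  }
  expect_equal(val, acc / ((length(lin) - 1) * 3 * 2), tolerance = 1e-10)

  # gradient vs central differences
  g <- attr(loss_diff(frames3, blood, K, cfg, schedule = sch,
                      gradient = TRUE), "grad")
  for (t in c(16, 22, 28)) {
    h <- 1e-6
    fp <- frames3; fp[t, 2, 1] <- fp[t, 2, 1] + h
    fm <- frames3; fm[t, 2, 1] <- fm[t, 2, 1] - h
    fd <- (loss_diff(fp, blood, K, cfg, schedule = sch) -
             loss_diff(fm, blood, K, cfg, schedule = sch)) / (2 * h)
    expect_equal(g[t, 2, 1], fd, tolerance = 1e-6)
  }
})

test_that("total loss composes the two terms linearly", {
  expect_equal(total_loss(0.3, 0.2, 0), 0.3)
  expect_equal(total_loss(0, 0, 1), 0)
  expect_equal(total_loss(0.3, 0.2, 2), 0.7)
})

test_that("learning-rate schedule: 1e-4, tenth every 10k, floored at 1e-7", {
  cfg <- optimizer_config()
  expect_identical(lr_at(0, cfg), 1e-4)
  expect_identical(lr_at(9999, cfg), 1e-4)
  expect_equal(lr_at(10000, cfg), 1e-5, tolerance = 1e-12)
  expect_equal(lr_at(20000, cfg), 1e-6, tolerance = 1e-12)
  expect_identical(lr_at(1e6, cfg), 1e-7)
})

test_that("composite-loss gradient through the kinetic layer matches finite
          differences on a 4x4 toy", {
  blood <- fixture_blood(0.05)
  sch <- fixture_schedule()
  cfg <- loss_config()
  set.seed(13)
  H <- 4
  arr <- array(runif(H * H * 5, 0.05, 0.35), c(H, H, 5))
  arr[, , 1] <- arr[, , 1] / 3
  maps <- param_maps(arr[, , 1], arr[, , 2], arr[, , 3], arr[, , 4],
                     arr[, , 5])
  truth <- array(abs(rnorm(28 * H * H, mean = 2)), c(28, H, H))
  K <- matrix(0.02, H, H)  # detached slope target

  composite <- function(maps) {
    kin <- petkin:::kinetic_layer_fw(maps, blood, sch, dt = 0.1)
    total_loss(loss_suv(kin$frames, truth, cfg),
               loss_diff(kin$frames, blood, K, cfg, schedule = sch), 1)
  }
  kin <- petkin:::kinetic_layer_fw(maps, blood, sch, dt = 0.1)
  ls <- loss_suv(kin$frames, truth, cfg, gradient = TRUE)
  ld <- loss_diff(kin$frames, blood, K, cfg, schedule = sch, gradient = TRUE)
  dmaps <- petkin:::kinetic_layer_bw(kin, attr(ls, "grad") + attr(ld, "grad"))

  h <- 1e-5
  for (probe in 1:8) {
    i <- sample(H, 1); j <- sample(H, 1); k <- sample(5, 1)
    mp <- maps; mp[i, j, k] <- mp[i, j, k] + h
    mm <- maps; mm[i, j, k] <- mm[i, j, k] - h
    fd <- (composite(mp) - composite(mm)) / (2 * h)
    expect_equal(dmaps[i, j, k], fd, tolerance = 1e-4)
  }
})

test_that("training is deterministic, decreases the loss, and flags blow-ups", {
  ph <- fixture_small_phantom(21, shape = c(32, 32))
  sample1 <- fixture_sample(ph)
  model <- pet_predictor(channel_scale = 1 / 16, seed = 8)

  # zero iterations: the checkpoint is the initialization
  fit0 <- train_predictor(model, list(sample1), iterations = 0)
  expect_identical(petkin:::model_flat(fit0$model),
                   petkin:::model_flat(model))
  expect_identical(nrow(fit0$log), 0L)

  # short smoke run: the composite loss decreases on a single slice
  fit <- train_predictor(model, list(sample1), iterations = 30, dt = 0.15)
  expect_lt(fit$log$loss[30], fit$log$loss[1])

  # same seed, same data -> identical loss curves
  fit2 <- train_predictor(model, list(sample1), iterations = 10, dt = 0.15)
  fit3 <- train_predictor(model, list(sample1), iterations = 10, dt = 0.15)
  expect_identical(fit2$log$loss, fit3$log$loss)

  # a non-finite target blows up with the iteration index in the message
  bad <- sample1
  bad$truth$frames[25, 1, 1] <- Inf
  expect_error(train_predictor(model, list(bad), iterations = 1, dt = 0.15),
               "non-finite loss at iteration 0")
})

test_that("checkpoints round-trip with a schedule fingerprint", {
  model <- pet_predictor(channel_scale = 1 / 16, seed = 9)
  sch <- fixture_schedule()
  path <- tempfile(fileext = ".rds")
  write_checkpoint(model, path, sch)
  ck <- read_checkpoint(path)
  expect_identical(petkin:::model_flat(ck$fit), petkin:::model_flat(model))
  expect_identical(ck$schedule_fingerprint,
                   petkin:::schedule_fingerprint(sch))
})
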