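# Architecture fidelity of the two-stage predictor and the differentiable
# kinetic layer's agreement with the reference simulator.

test_that("full-width network has the documented geometry", {
  model <- pet_predictor(seed = 1)  # full widths: 64..1024
  expect_identical(model$config$channels, c(64L, 128L, 256L, 512L, 1024L))
  H <- 16
  set.seed(1)
  inp <- array(abs(rnorm(22 * H * H)), c(22, H, H))
  feats <- extract_features(model, inp)
  # 22 frames x 10 feature maps = a 220-dim vector per voxel
  expect_equal(dim(feats), c(H, H, 220, 1))
  # deepest encoder map: side H/16, 1024 channels, one per input frame
  expect_equal(attr(feats, "bottleneck_dim")[1:3], c(H / 16, H / 16, 1024))
  # 5-channel parameter head in the documented order, bounded by the ranges
  maps <- predict_params(model, feats)
  expect_equal(dim(maps), c(H, H, 5))
  expect_identical(dimnames(maps)[[3]], c("f_v", "K1", "k2", "k3", "k4"))
  rng <- model$config$param_ranges
  for (k in 1:5) {
    expect_true(all(maps[, , k] >= rng[1, k] & maps[, , k] <= rng[2, k]))
  }
})

test_that("shape preconditions are enforced", {
  model <- pet_predictor(channel_scale = 1 / 16, seed = 2)
  expect_error(extract_features(model, array(0, c(22, 20, 20))), "bad-shape")
  expect_error(extract_features(model, array(0, c(10, 16, 16))), "bad-shape")
})

test_that("the head is pointwise: identical feature vectors, identical params", {
  model <- pet_predictor(channel_scale = 1 / 16, seed = 3)
  set.seed(3)
  feats <- array(rnorm(16 * 16 * 220), c(16, 16, 220, 1))
  # copy one voxel's features onto another voxel
  feats[5, 7, , 1] <- feats[2, 3, , 1]
  maps <- predict_params(model, feats)
  expect_equal(maps[5, 7, ], maps[2, 3, ], tolerance = 1e-14)
})

test_that("U-Net processes batch samples independently", {
  model <- pet_predictor(channel_scale = 1 / 16, seed = 4)
  set.seed(4)
  x <- array(rnorm(16 * 16 * 1 * 3), c(16, 16, 1, 3))
  y <- petkin:::unet_fw(model$unet, x, 16, keep = FALSE)$y
  perm <- c(3, 1, 2)
  y2 <- petkin:::unet_fw(model$unet, x[, , , perm, drop = FALSE], 16,
                         keep = FALSE)$y
  expect_equal(y2, y[, , , perm, drop = FALSE], tolerance = 1e-12)
})

test_that("the ablation head emits 6 unbounded frames deterministically", {
  model <- pet_predictor("direct", channel_scale = 1 / 16, seed = 5)
  ph <- fixture_small_phantom(5, shape = c(16, 16))
  input <- fixture_sample(ph)$input
  out1 <- predict_series(model, input, schedule = ph$schedule)
  out2 <- predict_series(model, input, schedule = ph$schedule)
  expect_identical(dim(out1$series$frames), c(6L, 16L, 16L))
  expect_identical(out1$series$frames, out2$series$frames)
  # no final sigmoid: outputs are not confined to a positive range
  expect_true(any(out1$series$frames < 0))
})

test_that("kinetic layer agrees with the reference simulator exactly", {
  blood <- fixture_blood(0.05)
  sch <- fixture_schedule()
  set.seed(6)
  arr <- array(runif(4 * 4 * 5, 0.01, 0.4), c(4, 4, 5))
  arr[, , 1] <- arr[, , 1] / 2  # f_v small
  maps <- param_maps(arr[, , 1], arr[, , 2], arr[, , 3], arr[, , 4],
                     arr[, , 5])
  kin <- petkin:::kinetic_layer_fw(maps, blood, sch, dt = 0.05)
  ref <- simulate_dynamic_frames(maps, blood, sch, dt = 0.05)
  expect_equal(kin$frames, ref$frames, tolerance = 1e-6)

  # full forward pass count: predicted series covers all 28 frames and
  # equals pushing the predicted maps through the simulator
  model <- pet_predictor(channel_scale = 1 / 16, seed = 7)
  ph <- fixture_small_phantom(7, shape = c(16, 16))
  s <- fixture_sample(ph)
  pred <- predict_series(model, s$input, blood, sch, dt = 0.1)
  expect_identical(dim(pred$series$frames)[1], 28L)
  direct <- simulate_dynamic_frames(pred$maps, blood, sch, dt = 0.1)
  expect_equal(pred$series$frames, direct$frames, tolerance = 1e-12)
})
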