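# Patlak graphical transform, tail OLS fit, and Ki map generation.

test_that("coordinates reduce correctly for constant and proportional inputs", {
  sch <- frame_schedule(c(0, 2, 5), c(2, 5, 10))
  blood <- blood_input(c(0, 10), c(1, 1))
  mids <- frame_mid_times(sch)

  # tissue == C_p == 1: y == 1, x == mid-times
  pts <- patlak_coordinates(rep(1, 3), blood, schedule = sch)
  expect_equal(pts$y, rep(1, 3))
  expect_equal(pts$x, mids)

  # tissue = V0 * C_p exactly (no trapping): slope 0, intercept V0
  blood2 <- fixture_blood(0.05)
  sch28 <- fixture_schedule()
  cp <- blood_value(blood2, frame_mid_times(sch28))
  fit <- fit_ki(patlak_coordinates(0.7 * cp, blood2, schedule = sch28),
                n_tail = 13)
  expect_equal(fit$ki, 0, tolerance = 1e-12)
  expect_equal(fit$v0, 0.7, tolerance = 1e-10)

  expect_error(
    patlak_coordinates(rep(1, 3), blood_input(c(0, 10), c(0, 0)),
                       schedule = sch),
    "zero-plasma")
})

test_that("OLS recovers an exact affine relation to machine precision", {
  x <- seq(2, 40, length.out = 20)
  y <- 0.03 * x + 0.5
  fit <- fit_ki(list(x = x, y = y), n_tail = 13)
  expect_equal(fit$ki, 0.03, tolerance = 1e-12)
  expect_equal(fit$v0, 0.5, tolerance = 1e-12)
  expect_error(fit_ki(list(x = x, y = y), n_tail = 1), "insufficient-points")
  expect_error(fit_ki(list(x = x[1:5], y = y[1:5]), n_tail = 13),
               "insufficient-points")
})

test_that("irreversible simulation recovers K1 k3 / (k2 + k3) within 5%", {
  blood <- fixture_blood(0.05)
  sch <- fixture_schedule()
  p <- kinetic_params(0, 0.5, 0.3, 0.05, 0)
  grid <- petkin:::quadrature_grid(sch, 0.05)
  tc <- tissue_concentration(p, blood, grid)
  vc <- voxel_concentration(tc, blood, 0)
  tac <- frame_activity(vc, sch, mode = "average")
  pts <- patlak_coordinates(tac, blood, schedule = sch)
  fit <- fit_ki(pts, n_tail = 13)
  truth <- 0.5 * 0.05 / 0.35
  expect_equal(fit$ki, truth, tolerance = 0.05)

  # the tail really is linear: R^2 of the last-13-point fit
  use <- fit$fit_frames
  pred <- fit$ki * pts$x[use] + fit$v0
  r2 <- 1 - sum((pts$y[use] - pred)^2) / sum((pts$y[use] - mean(pts$y[use]))^2)
  expect_gt(r2, 0.99)

  # later tail starts reduce the residual transient: |error| decreases
  # monotonically across tail lengths 13 -> 10 -> 6
  errs <- vapply(c(13, 10, 6), function(n) {
    abs(fit_ki(pts, n_tail = n)$ki - truth)
  }, numeric(1))
  expect_true(all(diff(errs) <= 0))

  # the fit ignores everything before the tail window
  tac2 <- tac
  tac2[1:10] <- tac2[1:10] * 5 + 1
  fit2 <- fit_ki(patlak_coordinates(tac2, blood, schedule = sch), n_tail = 13)
  expect_equal(fit2$ki, fit$ki, tolerance = 1e-12)
})

test_that("OLS slope is unbiased under zero-mean frame noise", {
  blood <- fixture_blood(0.05)
  sch <- fixture_schedule()
  p <- kinetic_params(0, 0.5, 0.3, 0.05, 0)
  grid <- petkin:::quadrature_grid(sch, 0.05)
  tc <- voxel_concentration(tissue_concentration(p, blood, grid), blood, 0)
  tac <- frame_activity(tc, sch, mode = "average")
  pts0 <- patlak_coordinates(tac, blood, schedule = sch)
  ki0 <- fit_ki(pts0, n_tail = 13)$ki
  set.seed(515)
  kis <- replicate(200, {
    noisy <- tac + rnorm(length(tac), sd = 0.5)
    fit_ki(patlak_coordinates(noisy, blood, schedule = sch), n_tail = 13)$ki
  })
  se <- sd(kis) / sqrt(length(kis))
  expect_lt(abs(mean(kis) - ki0), 2 * se)
})

test_that("ki_map vectorization matches the scalar loop and handles edge voxels", {
  blood <- fixture_blood(0.05)
  sch <- fixture_schedule()
  set.seed(616)
  frames <- array(abs(rnorm(28 * 4 * 3, mean = 3)), c(28, 4, 3))
  ser <- dynamic_series(frames, sch)
  km <- ki_map(ser, blood, n_tail = 13)
  for (i in 1:4) for (j in 1:3) {
    fit <- fit_ki(patlak_coordinates(frames[, i, j], blood, schedule = sch),
                  n_tail = 13)
    expect_equal(km$ki[i, j], fit$ki, tolerance = 1e-10)
    expect_equal(km$v0[i, j], fit$v0, tolerance = 1e-10)
  }

  # uniform image -> uniform map equal to the scalar result
  uni <- dynamic_series(array(rep(frames[, 1, 1], 12), c(28, 4, 3)), sch)
  kmu <- ki_map(uni, blood)
  expect_equal(max(kmu$ki) - min(kmu$ki), 0)

  # all-zero series -> zero map; non-finite voxel -> NaN, not an abort
  zer <- dynamic_series(array(0, c(28, 2, 2)), sch)
  kmz <- ki_map(zer, blood)
  expect_true(all(kmz$ki == 0) && all(kmz$v0 == 0))
  bad <- frames
  bad[5, 2, 2] <- NA
  kmb <- ki_map(dynamic_series(bad, sch), blood)
  expect_true(is.nan(kmb$ki[2, 2]))
  expect_false(anyNA(kmb$ki[-c(6)]))
})

test_that("patlak differences equal naive successive subtraction", {
  blood <- fixture_blood(0.05)
  sch <- fixture_schedule()

  # y constant across frames -> all differences 0
  cp <- blood_value(blood, frame_mid_times(sch))
  d0 <- patlak_differences(2.5 * cp, blood, schedule = sch)
  expect_equal(max(abs(d0$dy)), 0)

  # y = K x exactly -> diff(y) = K diff(x)
  pts_x <- patlak_coordinates(cp, blood, schedule = sch)$x
  tac <- 0.04 * pts_x * cp
  dk <- patlak_differences(tac, blood, schedule = sch)
  expect_equal(dk$dy, 0.04 * dk$dx, tolerance = 1e-12)

  # random series vs a direct loop
  set.seed(717)
  frames <- array(abs(rnorm(28 * 3 * 2, mean = 2)), c(28, 3, 2))
  dd <- patlak_differences(dynamic_series(frames, sch), blood)
  lin <- dd$linear_frames
  for (i in 1:3) for (j in 1:2) {
    y <- frames[lin, i, j] / cp[lin]
    expect_equal(dd$dy[, i, j], diff(y), tolerance = 1e-12)
  }
  expect_error(patlak_differences(frames[, 1, 1], blood, linear_frames = 5,
                                  schedule = sch),
               "too-few-frames")
})
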