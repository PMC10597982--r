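# Forward model of the two-tissue compartment system: macro-rate
# decomposition, analytic solution vs independent ODE integration, voxel
# mixing, frame integration, and the vectorized simulator.

test_that("macro rates reproduce the closed form and the quadratic roots", {
  # k4 = 0: discriminant collapses, alpha1 = 0, alpha2 = k2 + k3
  mr <- macro_rates(kinetic_params(0, 0.1, 0.1, 0.05, 0))
  expect_equal(mr$alpha1, 0)
  expect_equal(mr$alpha2, 0.15)
  expect_equal(mr$a, 0.1 * 0.05 / 0.15)
  expect_equal(mr$b, 0.1 * 0.1 / 0.15)

  # both amplitudes scale with K1, so K1 = 0 kills them
  mr0 <- macro_rates(kinetic_params(0, 0, 0.3, 0.1, 0.05))
  expect_equal(mr0$a, 0)
  expect_equal(mr0$b, 0)

  # eigenvalues equal the roots of s^2 + (k2+k3+k4) s + k2 k4 = 0 (polyroot
  # oracle, independent of the quadratic formula in the implementation)
  mr2 <- macro_rates(kinetic_params(0, 0.3, 0.4, 0.1, 0.05))
  roots <- sort(Re(polyroot(c(0.4 * 0.05, -(0.4 + 0.1 + 0.05), 1))))
  expect_equal(mr2$alpha1, roots[1], tolerance = 1e-10)
  expect_equal(mr2$alpha2, roots[2], tolerance = 1e-10)
})

test_that("eigenvalues satisfy ordering and Vieta relations over random draws", {
  set.seed(101)
  for (i in 1:50) {
    p <- fixture_random_params()
    mr <- macro_rates(p)
    expect_lte(mr$alpha1, mr$alpha2)
    expect_gte(mr$alpha1, 0)
    expect_equal(mr$alpha1 + mr$alpha2, p$k2 + p$k3 + p$k4, tolerance = 1e-10)
    expect_equal(mr$alpha1 * mr$alpha2, p$k2 * p$k4, tolerance = 1e-10)
    # alpha1 = 0 exactly when k4 = 0
    mr0 <- macro_rates(kinetic_params(0, p$K1, p$k2, p$k3, 0))
    expect_identical(mr0$alpha1, 0)
  }
})

test_that("analytic tissue curves match the RK4 oracle and their limits", {
  blood <- fixture_blood()
  grid <- seq(0, 65, by = 0.05)

  # zero input -> zero output
  zero <- blood_input(c(0, 65), c(0, 0))
  tc0 <- tissue_concentration(kinetic_params(0, 0.5, 0.3, 0.05, 0.01),
                              zero, grid)
  expect_equal(max(abs(tc0$ct)), 0)

  # k2 = k3 = k4 = 0 exercises the repeated-root guard: ct = K1 int C0
  # (input sampled on the evaluation grid itself, so the two quadratures see
  # the same piecewise-linear curve)
  blood05 <- analytic_input_function(grid = grid)
  tci <- tissue_concentration(kinetic_params(0, 0.4, 0, 0, 0), blood05, grid)
  expect_equal(tci$ct, 0.4 * blood_integral(blood05, grid), tolerance = 1e-6)

  # worked parameter set vs 4th-order Runge-Kutta integration of the ODEs
  p <- kinetic_params(0.05, 0.5, 0.3, 0.05, 0.01)
  tc <- tissue_concentration(p, blood, grid)
  oc <- ode_tissue_concentration(p, blood, grid, step = 0.0025)
  expect_lt(rel_l2(tc$ct, oc$ct), 1e-3)

  # compartments are recovered consistently
  expect_equal(tc$ct, tc$c1 + tc$c2, tolerance = 1e-12)
  expect_true(all(tc$c1 >= -1e-12) && all(tc$c2 >= -1e-12))

  expect_error(tissue_concentration(p, blood, c(-1, 0, 1)), "invalid-grid")
})

test_that("ODE oracle limits: K1 = 0 and the one-tissue reduction", {
  blood <- fixture_blood()
  grid <- seq(0, 40, by = 0.05)
  oc0 <- ode_tissue_concentration(kinetic_params(0, 0, 0.3, 0.1, 0.05),
                                  blood, grid)
  expect_equal(max(abs(oc0$ct)), 0)

  # k3 = 0: C2 stays empty and C1 solves the one-compartment model whose
  # closed form is K1 * C0 (x) e^{-k2 t}; evaluate that convolution by a
  # direct Riemann sum, independent of both implementations
  p <- kinetic_params(0, 0.3, 0.25, 0, 0)
  oc <- ode_tissue_concentration(p, blood, grid, step = 0.0025)
  expect_equal(max(abs(oc$c2)), 0)
  # evaluate the closed-form convolution with a fine trapezoid at a handful
  # of probe times
  probes <- c(2, 5, 10, 20, 40)
  fine <- 0.002
  closed <- vapply(probes, function(tp) {
    tau <- seq(0, tp, by = fine)
    f <- blood_value(blood, tau) * exp(-p$k2 * (tp - tau))
    p$K1 * sum((f[-1] + f[-length(f)]) / 2) * fine
  }, numeric(1))
  got <- oc$c1[vapply(probes, function(tp) which.min(abs(grid - tp)),
                      integer(1))]
  expect_lt(max(abs(got - closed)) / max(closed), 1e-4)

  # step-halving guard trips on an absurdly coarse step (sparse output grid
  # so the integrator really takes the requested step)
  expect_error(
    ode_tissue_concentration(p, blood, seq(0, 40, by = 5), step = 5,
                             check = TRUE),
    "too coarse")
})

test_that("analytic and ODE paths agree across seeded random parameters", {
  blood <- fixture_blood()
  grid <- seq(0, 65, by = 0.05)  # the package's default quadrature step
  set.seed(202)
  for (i in 1:20) {
    p <- fixture_random_params()
    tc <- tissue_concentration(p, blood, grid)
    oc <- ode_tissue_concentration(p, blood, grid, step = 0.0025)
    expect_lt(rel_l2(tc$ct, oc$ct), 1e-3)
  }
})

test_that("voxel mixing is the stated affine combination", {
  curve <- structure(list(times = 0:5, c1 = rep(2, 6), c2 = rep(2, 6),
                          ct = rep(4, 6)), class = "tissue_curve")
  cwb <- blood_input(c(0, 5), c(8, 8))
  expect_equal(voxel_concentration(curve, cwb, 0)$cpet, rep(4, 6))
  expect_equal(voxel_concentration(curve, cwb, 1)$cpet, rep(8, 6))
  expect_equal(voxel_concentration(curve, cwb, 0.25)$cpet, rep(5, 6))
  expect_error(voxel_concentration(curve, cwb, 1.5), "out-of-range")
})

test_that("frame activity integrates the decay-weighted curve", {
  flat <- list(times = c(0, 5), values = c(1, 1))
  sch0 <- frame_schedule(0, 5, decay_lambda = 0)
  expect_equal(frame_activity(flat, sch0, mode = "integral"), 5)
  expect_equal(frame_activity(flat, sch0, mode = "average"), 1)

  # constant c with decay: closed form c (e^{-l ts} - e^{-l te}) / l
  lam <- 0.12
  sch <- frame_schedule(2, 7, decay_lambda = lam)
  cv <- list(times = c(0, 10), values = c(3, 3))
  expect_equal(
    frame_activity(cv, sch, mode = "integral", decay_corrected = FALSE,
                   dt = 0.01),
    3 * (exp(-lam * 2) - exp(-lam * 7)) / lam, tolerance = 1e-6)

  # smooth curve vs a 10x finer trapezoid oracle
  tt <- seq(0, 20, by = 0.05)
  curve <- list(times = tt, values = 5 * tt * exp(-0.3 * tt))
  schs <- frame_schedule(c(0, 4, 9), c(4, 9, 20), decay_lambda = 0.06)
  got <- frame_activity(curve, schs, mode = "integral",
                        decay_corrected = FALSE, dt = 0.05)
  fine <- seq(0, 20, by = 0.005)
  fv <- approx(tt, curve$values, fine)$y * exp(-0.06 * fine)
  oracle <- vapply(seq_along(schs$starts), function(m) {
    keep <- fine >= schs$starts[m] & fine <= schs$ends[m]
    f <- fv[keep]
    sum((f[-1] + f[-length(f)]) / 2) * 0.005
  }, numeric(1))
  expect_equal(got, oracle, tolerance = 1e-5)

  expect_error(frame_activity(flat, frame_schedule(0, 9), mode = "integral"),
               "schedule-outside-grid")
})

test_that("vectorized simulator equals the scalar chain voxel by voxel", {
  blood <- fixture_blood(0.05)
  sch <- fixture_schedule()
  set.seed(303)

  # identical parameters everywhere -> identical TACs
  p <- fixture_random_params()
  maps <- param_maps(p$f_v, p$K1, p$k2, p$k3, p$k4, shape = c(2, 2))
  ser <- simulate_dynamic_frames(maps, blood, sch, dt = 0.1)
  for (i in 1:2) for (j in 1:2) {
    expect_equal(ser$frames[, i, j], ser$frames[, 1, 1])
  }

  # a dead voxel stays dead
  maps0 <- maps
  maps0[1, 2, ] <- 0
  ser0 <- simulate_dynamic_frames(maps0, blood, sch, dt = 0.1)
  expect_equal(max(abs(ser0$frames[, 1, 2])), 0)

  # random 8x8 map against an explicit scalar loop
  H <- 8; W <- 8
  arr <- array(0, c(H, W, 5))
  for (i in seq_len(H)) for (j in seq_len(W)) {
    q <- fixture_random_params()
    arr[i, j, ] <- c(q$f_v, q$K1, q$k2, q$k3, q$k4)
  }
  maps2 <- param_maps(arr[, , 1], arr[, , 2], arr[, , 3], arr[, , 4],
                      arr[, , 5])
  fast <- simulate_dynamic_frames(maps2, blood, sch, dt = 0.1)
  grid <- petkin:::quadrature_grid(sch, 0.1)
  for (idx in list(c(1, 1), c(3, 7), c(8, 8))) {
    q <- kinetic_params(arr[idx[1], idx[2], 1], arr[idx[1], idx[2], 2],
                        arr[idx[1], idx[2], 3], arr[idx[1], idx[2], 4],
                        arr[idx[1], idx[2], 5])
    tc <- tissue_concentration(q, blood, grid)
    vc <- voxel_concentration(tc, blood, q$f_v)
    tac <- frame_activity(vc, sch, mode = "average", dt = 0.1)
    expect_equal(fast$frames[, idx[1], idx[2]], tac, tolerance = 1e-10)
  }
})

test_that("positivity and K1-linearity hold; irreversible limit approached", {
  blood <- fixture_blood(0.05)
  grid <- seq(0, 65, by = 0.05)
  set.seed(404)
  for (i in 1:5) {
    p <- fixture_random_params()
    tc <- tissue_concentration(p, blood, grid)
    expect_true(all(tc$ct >= -1e-10))
    p2 <- kinetic_params(p$f_v, 2 * p$K1, p$k2, p$k3, p$k4)
    tc2 <- tissue_concentration(p2, blood, grid)
    expect_equal(tc2$ct, 2 * tc$ct, tolerance = 1e-12)
  }

  # k4 = 0, fast-equilibrating (small k2/k3 ratio so the distribution-volume
  # term has decayed): C_T / int C_p -> K1 k3 / (k2 + k3) at 60 min
  p <- kinetic_params(0, 0.6, 0.2, 0.3, 0)
  tc <- tissue_concentration(p, blood, grid)
  at60 <- which.min(abs(grid - 60))
  ratio <- tc$ct[at60] / blood_integral(blood, 60)
  expect_equal(ratio, 0.6 * 0.3 / 0.5, tolerance = 0.05)
})

test_that("domain constructors enforce their invariants", {
  expect_error(kinetic_params(-0.1, 1, 1, 1, 0), "non-negative")
  expect_error(kinetic_params(1.2, 1, 1, 1, 0), "f_v")
  expect_error(blood_input(c(0, 1, 1), c(1, 1, 1)), "increasing")
  expect_error(blood_input(c(0, 1), c(-1, 1)), "non-negative")
  expect_error(frame_schedule(c(0, 1), c(2, 2)), "overlap")
  expect_error(frame_schedule(1, 1), "starts")
  expect_error(dynamic_series(array(0, c(3, 2, 2)), frame_schedule(0, 1)),
               "frame-count-mismatch")
  # blood interpolation rules: zero before 0, constant beyond the last sample
  b <- blood_input(c(0, 1, 2), c(0, 10, 4))
  expect_equal(blood_value(b, c(-1, 0.5, 5)), c(0, 5, 4))
})
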