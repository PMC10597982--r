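#' Per-voxel two-tissue-compartment parameter set
#'
#' Bundles the five parameters of the 2TCM voxel model: the fractional blood
#' volume `f_v` (unitless, in `[0, 1]`) and the four rate constants `K1`
#' (plasma -> tissue influx, ml/min/ml, treated as 1/min), `k2` (efflux),
#' `k3` (nondisplaceable -> specific transfer) and `k4` (specific ->
#' nondisplaceable transfer), all in 1/min.
#'
#' @param f_v fractional blood volume, in `[0, 1]`.
#' @param K1,k2,k3,k4 non-negative rate constants (1/min).
#' @return A `kinetic_params` object (named list).
#' @examples
#' kinetic_params(f_v = 0.05, K1 = 0.5, k2 = 0.3, k3 = 0.05, k4 = 0)
#' @export
kinetic_params <- function(f_v = 0, K1, k2, k3, k4 = 0) {
  vals <- c(f_v = f_v, K1 = K1, k2 = k2, k3 = k3, k4 = k4)
  if (any(!is.finite(vals))) stop("kinetic parameters must be finite")
  if (any(vals < 0)) stop("kinetic parameters must be non-negative")
  if (f_v > 1) stop("f_v must lie in [0, 1]")
  structure(as.list(vals), class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("2TCM parameters (1/min; f_v unitless):\n")
  print(unlist(x))
  invisible(x)
}

#' Macro-rate (biexponential) decomposition of 2TCM rate constants
#'
#' The 2TCM impulse response is `a e^{-alpha1 t} + b e^{-alpha2 t}` where
#' `alpha1 <= alpha2` are the eigenvalues of the compartment system,
#' `alpha_{1,2} = (k2+k3+k4 -/+ sqrt((k2+k3+k4)^2 - 4 k2 k4))/2`, with
#' amplitudes `a = K1 (k3+k4-alpha1)/(alpha2-alpha1)` and `b = K1 - a`.
#' When the two eigenvalues coincide to within `eps` the amplitudes of the
#' distinct-root form are undefined; the returned object is flagged
#' `degenerate` and downstream code switches to the repeated-root limit
#' (a `t e^{-alpha t}` term).
#'
#' @param params a [kinetic_params()] object.
#' @param eps eigenvalue-spread guard below which the repeated-root limit is
#'   used (default `1e-9` 1/min).
#' @return A list with `a`, `b`, `alpha1`, `alpha2`, `degenerate`.
#' @examples
#' macro_rates(kinetic_params(K1 = 0.1, k2 = 0.1, k3 = 0.05, k4 = 0))
#' @export
macro_rates <- function(params, eps = 1e-9) {
  stopifnot(inherits(params, "kinetic_params"))
  s <- params$k2 + params$k3 + params$k4
  disc <- max(s^2 - 4 * params$k2 * params$k4, 0)
  r <- sqrt(disc)
  alpha1 <- max((s - r) / 2, 0)
  alpha2 <- (s + r) / 2
  degenerate <- (alpha2 - alpha1) < eps
  if (!degenerate) {
    a <- params$K1 * (params$k3 + params$k4 - alpha1) / (alpha2 - alpha1)
    b <- params$K1 - a
  } else {
    # repeated root: C_T = K1 (1 + (k3+k4-alpha) t) e^{-alpha t} (x) C0;
    # report the total amplitude in `a` and 0 in `b`
    a <- params$K1
    b <- 0
  }
  structure(list(a = a, b = b, alpha1 = alpha1, alpha2 = alpha2,
                 degenerate = degenerate),
            class = "macro_rates")
}

#' Arterial/whole-blood input curve
#'
#' The tracer concentration in blood driving tissue uptake, sampled on a
#' strictly increasing time grid starting at (or after) zero.  One curve
#' serves as plasma (`C_p`) and whole-blood (`C_WB`) concentration.
#' Between samples the curve is piecewise linear; beyond the last sample it is
#' extrapolated as constant; before time zero it is zero.
#'
#' @param times sample times (min), strictly increasing, `>= 0`.
#' @param values activity concentrations at `times` (same length), `>= 0`.
#' @return A `blood_input` object.
#' @export
blood_input <- function(times, values) {
  if (length(times) != length(values)) stop("times and values lengths differ")
  if (length(times) < 2) stop("need at least two samples")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (times[1] < 0) stop("times must start at or after 0")
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("values must be finite and non-negative")
  }
  structure(list(times = as.numeric(times), values = as.numeric(values)),
            class = "blood_input")
}

#' Evaluate a blood input curve at arbitrary times
#'
#' @param blood a [blood_input()] object.
#' @param t times (min) at which to evaluate.
#' @return Numeric vector of concentrations.
#' @export
blood_value <- function(blood, t) {
  stopifnot(inherits(blood, "blood_input"))
  out <- approx(blood$times, blood$values, xout = pmax(t, blood$times[1]),
                rule = 2)$y
  out[t < 0] <- 0
  out
}

#' Running time-integral of a blood input curve
#'
#' Trapezoid integral of the piecewise-linear curve from time 0 to each `t`
#' (used for the Patlak abscissa).
#'
#' @inheritParams blood_value
#' @return Numeric vector, `integral_0^t C_p`.
#' @export
blood_integral <- function(blood, t) {
  stopifnot(inherits(blood, "blood_input"))
  grid <- sort(unique(c(blood$times, t, 0)))
  grid <- grid[grid >= 0]
  v <- blood_value(blood, grid)
  cum <- c(0, cumsum(0.5 * (v[-1] + v[-length(v)]) * diff(grid)))
  approx(grid, cum, xout = t, rule = 2)$y
}

#' Dynamic-scan frame schedule
#'
#' Ordered, non-overlapping acquisition intervals binning a dynamic scan into
#' frames, plus the radionuclide decay constant used by the decay-weighted
#' frame integral.
#'
#' @param starts frame start times (min).
#' @param ends frame end times (min); `starts[m] < ends[m]` and frames must
#'   not overlap.
#' @param decay_lambda decay constant lambda (1/min); defaults to the
#'   fluorine-18 value `log(2)/109.77`.
#' @return A `frame_schedule` object.
#' @export
frame_schedule <- function(starts, ends, decay_lambda = F18_DECAY_LAMBDA) {
  starts <- as.numeric(starts); ends <- as.numeric(ends)
  if (length(starts) != length(ends)) stop("starts/ends lengths differ")
  if (any(starts >= ends)) stop("each frame needs starts[m] < ends[m]")
  if (length(starts) > 1 && any(ends[-length(ends)] > starts[-1] + 1e-12)) {
    stop("frames must not overlap")
  }
  if (decay_lambda < 0) stop("decay_lambda must be >= 0")
  structure(list(starts = starts, ends = ends,
                 decay_lambda = decay_lambda),
            class = "frame_schedule")
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("frame schedule: %d frames, %.2f-%.2f min, lambda = %.5g/min\n",
              length(x$starts), x$starts[1], x$ends[length(x$ends)],
              x$decay_lambda))
  invisible(x)
}

#' Frame durations and mid-times
#' @param schedule a [frame_schedule()] object.
#' @return Numeric vector (min).
#' @export
frame_durations <- function(schedule) schedule$ends - schedule$starts

#' @rdname frame_durations
#' @export
frame_mid_times <- function(schedule) (schedule$starts + schedule$ends) / 2

# Dense quadrature grid covering [0, t_end], refined to dt and containing all
# frame boundaries exactly.
quadrature_grid <- function(schedule, dt = 0.05) {
  t_end <- max(schedule$ends)
  g <- sort(unique(c(seq(0, t_end, by = dt), schedule$starts, schedule$ends,
                     t_end)))
  g[g <= t_end + 1e-12]
}

schedule_index <- function(grid, schedule) {
  nearest <- function(x) {
    i <- vapply(x, function(v) which.min(abs(grid - v)), integer(1))
    if (any(abs(grid[i] - x) > 1e-9)) stop("schedule-outside-grid")
    i
  }
  list(s = nearest(schedule$starts) - 1L, e = nearest(schedule$ends) - 1L)
}

decay_weights <- function(grid, schedule, decay_corrected = TRUE) {
  if (decay_corrected || schedule$decay_lambda == 0) {
    rep(1, length(grid))
  } else {
    exp(-schedule$decay_lambda * grid)
  }
}

#' Tissue concentration curves from the analytic 2TCM solution
#'
#' Evaluates the analytic solution of the compartment ODEs,
#' `C_T(t) = a C0(t) (x) e^{-alpha1 t} + b C0(t) (x) e^{-alpha2 t}`,
#' by exact per-segment convolution of the piecewise-linear input with the two
#' exponentials, and recovers the nondisplaceable (`c1`) and specific (`c2`)
#' compartments consistently (`ct = c1 + c2`).
#'
#' @param params a [kinetic_params()] object (`f_v` ignored here).
#' @param blood a [blood_input()] object.
#' @param grid evaluation times (min), non-negative, increasing.
#' @param eps repeated-eigenvalue guard passed to the macro-rate split.
#' @return A `tissue_curve` object with `times`, `c1`, `c2`, `ct`.
#' @seealso [ode_tissue_concentration()] for the independent ODE oracle.
#' @export
tissue_concentration <- function(params, blood, grid, eps = 1e-9) {
  stopifnot(inherits(params, "kinetic_params"), inherits(blood, "blood_input"))
  grid <- as.numeric(grid)
  if (any(grid < 0)) stop("invalid-grid: grid precedes time 0")
  if (any(diff(grid) <= 0)) stop("invalid-grid: grid must be increasing")
  c0 <- blood_value(blood, grid)
  res <- cpp_tissue_curves(grid, c0, params$K1, params$k2, params$k3,
                           params$k4, eps)
  structure(list(times = grid, c1 = as.numeric(res$c1),
                 c2 = as.numeric(res$c2), ct = as.numeric(res$ct)),
            class = "tissue_curve")
}

#' Tissue concentration by direct ODE integration (verification oracle)
#'
#' Fixed-step 4th-order Runge-Kutta integration of the compartment ODEs
#' `dC1/dt = K1 C0 - (k2+k3) C1 + k4 C2`, `dC2/dt = k3 C1 - k4 C2`.
#' Exists solely as an independent check on [tissue_concentration()]; it
#' shares no code with the analytic path.
#'
#' @inheritParams tissue_concentration
#' @param step RK4 step (min, default 0.005).
#' @param check when `TRUE`, re-integrates at half the step and signals
#'   `"step-size too coarse"` if the relative L2 change exceeds `tol`.
#' @param tol step-halving tolerance (default `1e-4` relative).
#' @return A `tissue_curve` object.
#' @export
ode_tissue_concentration <- function(params, blood, grid, step = 0.005,
                                     check = FALSE, tol = 1e-4) {
  stopifnot(inherits(params, "kinetic_params"), inherits(blood, "blood_input"))
  grid <- as.numeric(grid)
  if (any(grid < 0)) stop("invalid-grid: grid precedes time 0")
  run <- function(h) {
    cpp_ode_rk4(blood$times, blood$values, params$K1, params$k2, params$k3,
                params$k4, grid, h)
  }
  res <- run(step)
  if (check) {
    res2 <- run(step / 2)
    ref <- sqrt(sum((res2$c1 + res2$c2)^2))
    dev <- sqrt(sum(((res$c1 + res$c2) - (res2$c1 + res2$c2))^2))
    if (ref > 0 && dev / ref > tol) stop("step-size too coarse")
  }
  structure(list(times = grid, c1 = as.numeric(res$c1),
                 c2 = as.numeric(res$c2),
                 ct = as.numeric(res$c1) + as.numeric(res$c2)),
            class = "tissue_curve")
}

#' Voxel concentration: blood-volume mixing
#'
#' `C_PET(t) = (1 - f_v) C_T(t) + f_v C_WB(t)`; the blood input curve serves
#' as the whole-blood concentration.
#'
#' @param curve a `tissue_curve` from [tissue_concentration()].
#' @param blood a [blood_input()] object (whole-blood curve).
#' @param f_v fractional blood volume in `[0, 1]`.
#' @return The curve with an added `cpet` component.
#' @export
voxel_concentration <- function(curve, blood, f_v) {
  stopifnot(inherits(curve, "tissue_curve"))
  if (!is.finite(f_v) || f_v < 0 || f_v > 1) {
    stop("out-of-range f_v: must lie in [0, 1]")
  }
  cwb <- blood_value(blood, curve$times)
  curve$cpet <- (1 - f_v) * curve$ct + f_v * cwb
  curve
}

#' Decay-weighted frame activity of a concentration curve
#'
#' Bins a continuous voxel concentration into scan frames.  With
#' `mode = "integral"` the value of frame `m` is the decay-weighted integral
#' `x_m = integral_{t_{m,s}}^{t_{m,e}} C_PET(tau) e^{-lambda tau} d tau`
#' (units concentration x time); `mode = "average"` divides by the frame
#' duration, the convention matching SUV frame images.  When
#' `decay_corrected = TRUE` (default) the input curve is taken as already
#' decay-corrected and the `e^{-lambda tau}` weight is skipped.
#'
#' @param curve a `tissue_curve` (its `cpet` component is used when present,
#'   else `ct`), or a list with `times` and `values`.
#' @param schedule a [frame_schedule()] within the curve's time coverage.
#' @param mode `"average"` (default) or `"integral"`.
#' @param decay_corrected logical; skip the decay weight (default `TRUE`).
#' @param dt quadrature refinement step (min): the curve is linearly resampled
#'   onto a grid at least this fine so the decay weight is integrated
#'   accurately even for sparsely sampled curves.
#' @return Numeric vector of `length(schedule$starts)` frame values.
#' @export
frame_activity <- function(curve, schedule, mode = c("average", "integral"),
                           decay_corrected = TRUE, dt = 0.05) {
  mode <- match.arg(mode)
  stopifnot(inherits(schedule, "frame_schedule"))
  if (!is.null(curve$values)) {
    times <- curve$times; vals <- curve$values
  } else {
    times <- curve$times; vals <- curve$cpet %||% curve$ct
  }
  if (min(schedule$starts) < min(times) - 1e-9 ||
      max(schedule$ends) > max(times) + 1e-9) {
    stop("schedule-outside-grid")
  }
  grid <- sort(unique(c(times, schedule$starts, schedule$ends,
                        seq(min(times), max(times), by = dt))))
  v <- approx(times, vals, xout = grid, rule = 2)$y
  idx <- schedule_index(grid, schedule)
  w <- decay_weights(grid, schedule, decay_corrected)
  as.numeric(cpp_frame_integrals(grid, v, w, idx$s, idx$e,
                                 mode == "average"))
}

#' Stack of dynamic frame images
#'
#' The pipeline currency: a `T x H x W` array of frame values together with
#' its [frame_schedule()].
#'
#' @param frames numeric array `T x H x W`.
#' @param schedule a [frame_schedule()] with `T` frames.
#' @return A `dynamic_series` object.
#' @export
dynamic_series <- function(frames, schedule) {
  stopifnot(inherits(schedule, "frame_schedule"))
  d <- dim(frames)
  if (length(d) != 3) stop("frames must be a T x H x W array")
  if (d[1] != length(schedule$starts)) {
    stop("frame-count-mismatch between frames and schedule")
  }
  if (d[2] < 1 || d[3] < 1) stop("H and W must be positive")
  structure(list(frames = frames, schedule = schedule),
            class = "dynamic_series")
}

#' @export
print.dynamic_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("dynamic series: %d frames of %d x %d, %.1f-%.1f min\n",
              d[1], d[2], d[3], x$schedule$starts[1],
              max(x$schedule$ends)))
  invisible(x)
}

#' @export
dim.dynamic_series <- function(x) dim(x$frames)

#' Per-voxel parameter maps
#'
#' Packs five `H x W` matrices (`f_v`, `K1`, `k2`, `k3`, `k4`) into the
#' `H x W x 5` array consumed by the vectorized simulator and emitted by the
#' network head.
#'
#' @param f_v,K1,k2,k3,k4 `H x W` matrices (scalars are recycled).
#' @param shape required when all arguments are scalar: `c(H, W)`.
#' @return Numeric array `H x W x 5` with parameter names on the 3rd axis.
#' @export
param_maps <- function(f_v, K1, k2, k3, k4, shape = NULL) {
  mats <- list(f_v = f_v, K1 = K1, k2 = k2, k3 = k3, k4 = k4)
  if (is.null(shape)) {
    dims <- lapply(mats, dim)
    dims <- dims[!vapply(dims, is.null, logical(1))]
    if (length(dims) == 0) stop("give `shape` when all parameters are scalar")
    shape <- dims[[1]]
  }
  arr <- array(0, c(shape, 5), dimnames = list(NULL, NULL, names(mats)))
  for (i in seq_along(mats)) {
    arr[, , i] <- mats[[i]]
  }
  if (any(!is.finite(arr)) || any(arr < 0) || any(arr[, , "f_v"] > 1)) {
    bad <- which(!is.finite(arr) | arr < 0, arr.ind = TRUE)
    stop(sprintf("invalid parameter map at voxel (%s)",
                 paste(bad[1, 1:2], collapse = ", ")))
  }
  arr
}

#' Simulate a dynamic frame series from per-voxel parameter maps
#'
#' Vectorizes the scalar chain (analytic tissue curves -> blood-volume mixing
#' -> decay-weighted frame integration) over all voxels of a parameter map.
#' Voxelwise identical to calling the scalar functions per voxel.
#'
#' @param maps `H x W x 5` array from [param_maps()].
#' @param blood a [blood_input()] object.
#' @param schedule a [frame_schedule()].
#' @param dt quadrature step (min, default 0.05; resolves the 10-s early
#'   frames with several points).
#' @param mode frame value convention, `"average"` (default) or `"integral"`.
#' @param decay_corrected skip the `e^{-lambda tau}` weight (default `TRUE`).
#' @param eps repeated-eigenvalue guard.
#' @return A [dynamic_series()] (`T x H x W`).
#' @export
simulate_dynamic_frames <- function(maps, blood, schedule, dt = 0.05,
                                    mode = c("average", "integral"),
                                    decay_corrected = TRUE, eps = 1e-9) {
  mode <- match.arg(mode)
  stopifnot(inherits(blood, "blood_input"), inherits(schedule, "frame_schedule"))
  d <- dim(maps)
  if (length(d) != 3 || d[3] != 5) stop("maps must be H x W x 5")
  H <- d[1]; W <- d[2]
  grid <- quadrature_grid(schedule, dt)
  c0 <- blood_value(blood, grid)
  idx <- schedule_index(grid, schedule)
  w <- decay_weights(grid, schedule, decay_corrected)
  P <- matrix(maps, nrow = H * W, ncol = 5)
  res <- cpp_kinetic_forward(grid, c0, w, idx$s, idx$e, P,
                             mode == "average", eps, FALSE)
  Tn <- length(schedule$starts)
  dynamic_series(array(res$frames, c(Tn, H, W)), schedule)
}
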