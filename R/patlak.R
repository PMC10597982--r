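#' Patlak plot coordinates
#'
#' For an irreversibly trapped tracer the Patlak transform linearizes the
#' tissue curve: plotting `y(t) = C_tissue(t)/C_p(t)` against the "stretched
#' time" `x(t) = integral_0^t C_p(tau) d tau / C_p(t)` yields a straight line
#' `y = Ki x + V0` once the reversible compartments have equilibrated, with
#' slope the net influx rate `Ki` and intercept the apparent distribution
#' volume `V0`.  Each frame contributes one point, evaluated at its mid-time;
#' the tissue term is the frame-average activity concentration.
#'
#' @param series a [dynamic_series()] (frame values in average-mode
#'   concentration units), or a numeric vector holding a single TAC (then
#'   `schedule` is required).
#' @param blood a [blood_input()] plasma curve, covering all frame mid-times
#'   with strictly positive values.
#' @param schedule only used when `series` is a bare TAC vector.
#' @return A `patlak_points` object: `x` (min, length `T`), `y` (`T` vector
#'   for a TAC, `T x H x W` array for a series), `frame_mid_times`.
#' @export
patlak_coordinates <- function(series, blood, schedule = NULL) {
  stopifnot(inherits(blood, "blood_input"))
  if (inherits(series, "dynamic_series")) {
    schedule <- series$schedule
    yv <- series$frames
  } else {
    if (is.null(schedule)) stop("give `schedule` with a bare TAC vector")
    yv <- as.numeric(series)
    if (length(yv) != length(schedule$starts)) {
      stop("frame-count-mismatch between TAC and schedule")
    }
  }
  mid <- frame_mid_times(schedule)
  cp <- blood_value(blood, mid)
  if (any(cp <= 0)) stop("zero-plasma: C_p vanishes at a frame mid-time")
  x <- blood_integral(blood, mid) / cp
  if (is.array(yv)) {
    y <- sweep(yv, 1, cp, "/")
  } else {
    y <- yv / cp
  }
  structure(list(x = x, y = y, frame_mid_times = mid),
            class = "patlak_points")
}

#' Ordinary least-squares Patlak fit over the linear tail
#'
#' Fits `y = Ki x + V0` by OLS over the last `n_tail` Patlak points (the
#' linear portion; default 13 frames of the one-hour protocol).
#'
#' @param points a `patlak_points` object with vector `y`, or a list with
#'   numeric `x` and `y`.
#' @param n_tail number of tail points used (default 13, `>= 2`).
#' @return A list with `ki` (1/min), `v0` (unitless) and `fit_frames`
#'   (indices of the points used).
#' @export
fit_ki <- function(points, n_tail = 13) {
  x <- points$x
  y <- points$y
  if (is.array(y) && length(dim(y)) > 1) {
    stop("fit_ki expects a single TAC; use ki_map() for images")
  }
  n <- length(x)
  if (n_tail < 2) stop("insufficient-points: n_tail must be >= 2")
  if (n < n_tail) stop("insufficient-points: fewer points than n_tail")
  use <- seq.int(n - n_tail + 1, n)
  xs <- x[use]; ys <- y[use]
  xc <- xs - mean(xs)
  ki <- sum(xc * ys) / sum(xc^2)
  v0 <- mean(ys) - ki * mean(xs)
  list(ki = ki, v0 = v0, fit_frames = use)
}

#' Voxelwise Patlak Ki/V0 map
#'
#' Applies the Patlak transform and tail OLS fit to every voxel of a dynamic
#' series.  Voxels whose TAC contains a non-finite value yield `NaN` rather
#' than aborting; all-zero voxels yield `ki = v0 = 0`.
#'
#' @param series a [dynamic_series()].
#' @param blood a [blood_input()] plasma curve.
#' @param n_tail number of tail frames in the linear fit (default 13).
#' @return A `ki_map` object: matrices `ki` and `v0` (`H x W`), `fit_frames`,
#'   and `n_tail`.
#' @export
ki_map <- function(series, blood, n_tail = 13) {
  stopifnot(inherits(series, "dynamic_series"))
  pts <- patlak_coordinates(series, blood)
  d <- dim(series$frames)
  Tn <- d[1]
  if (n_tail < 2 || n_tail > Tn) stop("insufficient-points")
  use <- seq.int(Tn - n_tail + 1, Tn)
  xs <- pts$x[use]
  # a voxel with any non-finite Patlak point (any frame) yields NaN
  bad <- colSums(!is.finite(matrix(pts$y, nrow = Tn))) > 0
  Y <- matrix(pts$y[use, , , drop = FALSE], nrow = n_tail)
  Y[, bad] <- 0
  xc <- xs - mean(xs)
  ki <- colSums(xc * Y) / sum(xc^2)
  v0 <- colMeans(Y) - ki * mean(xs)
  ki[bad] <- NaN
  v0[bad] <- NaN
  structure(list(ki = matrix(ki, d[2], d[3]), v0 = matrix(v0, d[2], d[3]),
                 fit_frames = use, n_tail = n_tail),
            class = "ki_map")
}

#' @export
print.ki_map <- function(x, ...) {
  cat(sprintf("Ki map %d x %d, fitted on %d tail frames (%d..%d)\n",
              nrow(x$ki), ncol(x$ki), x$n_tail, min(x$fit_frames),
              max(x$fit_frames)))
  cat(sprintf("  Ki range: %.4g .. %.4g /min\n",
              min(x$ki, na.rm = TRUE), max(x$ki, na.rm = TRUE)))
  invisible(x)
}

#' Successive-frame Patlak differences
#'
#' First differences of the Patlak ordinate `y` along the linear-portion
#' frames, paired with the first differences of the abscissa `x` (so that a
#' reference slope `Ki` predicts `diff(y) = Ki * diff(x)`).  This is the
#' quantity the Patlak time-difference training loss penalizes; differencing
#' removes the intercept `V0`.
#'
#' @param series a [dynamic_series()] or a bare TAC vector (with `schedule`).
#' @param blood a [blood_input()] plasma curve.
#' @param linear_frames indices of the linear-portion frames (default the
#'   last 13); at least 2.
#' @param schedule only used when `series` is a bare TAC vector.
#' @return A list with `dy` (differences of `y`; `(L-1) x H x W` array or
#'   vector), `dx` (length `L-1`), and `linear_frames`.
#' @export
patlak_differences <- function(series, blood, linear_frames = NULL,
                               schedule = NULL) {
  pts <- patlak_coordinates(series, blood, schedule)
  Tn <- length(pts$x)
  if (is.null(linear_frames)) {
    linear_frames <- seq.int(max(1, Tn - 12), Tn)
  }
  if (length(linear_frames) < 2) stop("too-few-frames: need >= 2")
  if (any(linear_frames < 1 | linear_frames > Tn)) {
    stop("linear_frames outside schedule")
  }
  dx <- diff(pts$x[linear_frames])
  if (is.array(pts$y)) {
    sel <- pts$y[linear_frames, , , drop = FALSE]
    dy <- sel[-1, , , drop = FALSE] - sel[-length(linear_frames), , ,
                                          drop = FALSE]
  } else {
    dy <- diff(pts$y[linear_frames])
  }
  list(dy = dy, dx = dx, linear_frames = linear_frames)
}
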