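# Seeded synthetic dynamic-PET phantoms emulating a one-hour, 28-frame
# clinical FDG protocol, so training and every test run at desk scale without
# any data download.

#' The 28-frame one-hour dynamic protocol
#'
#' Contiguous frames of 6 x 10 s, 4 x 30 s, 4 x 60 s, 4 x 120 s and
#' 10 x 300 s starting at injection (65 min total).  The first 22 frames
#' (35 min) form the network input split and the last 6 frames (30 min) the
#' prediction target split; the split is defined by frame count.
#'
#' @param decay_lambda decay constant (1/min); default fluorine-18.
#' @return A [frame_schedule()] with attributes `input_frames` (1..22) and
#'   `target_frames` (23..28).
#' @export
default_schedule <- function(decay_lambda = F18_DECAY_LAMBDA) {
  dur_s <- c(rep(10, 6), rep(30, 4), rep(60, 4), rep(120, 4), rep(300, 10))
  ends <- cumsum(dur_s) / 60
  starts <- c(0, ends[-length(ends)])
  sch <- frame_schedule(starts, ends, decay_lambda)
  attr(sch, "input_frames") <- 1:22
  attr(sch, "target_frames") <- 23:28
  sch
}

#' Analytic arterial input function specification (Feng model)
#'
#' A Feng-type analytic family,
#' `C0(t) = (A1 t - A2 - A3) e^{-l1 t} + A2 e^{-l2 t} + A3 e^{-l3 t}`,
#' standing in for an image-derived descending-aorta curve: zero at injection,
#' a sharp bolus peak within the first two minutes, then a slowly decaying
#' tail.  Defaults are the classic FDG population values (concentration units
#' are nominal kBq/ml; the kinetic model is linear in the input scale).
#'
#' @param A1 bolus slope (kBq/ml/min); `A2`, `A3` tail amplitudes (kBq/ml).
#' @param l1,l2,l3 decay rates (1/min), `l1 > l2 > l3`.
#' @return An `input_function_spec` object.
#' @export
feng_input_spec <- function(A1 = 851.1, A2 = 21.88, A3 = 20.81,
                            l1 = 4.134, l2 = 0.1191, l3 = 0.0104) {
  structure(list(model = "feng", A1 = A1, A2 = A2, A3 = A3,
                 l1 = l1, l2 = l2, l3 = l3),
            class = "input_function_spec")
}

#' Evaluate an analytic input function on a time grid
#'
#' @param spec an [feng_input_spec()] object.
#' @param grid sample times (min); default a 0.01-min grid over 0-65 min.
#' @return A [blood_input()] object.
#' @export
analytic_input_function <- function(spec = feng_input_spec(),
                                    grid = seq(0, 65, by = 0.01)) {
  stopifnot(inherits(spec, "input_function_spec"))
  v <- (spec$A1 * grid - spec$A2 - spec$A3) * exp(-spec$l1 * grid) +
    spec$A2 * exp(-spec$l2 * grid) + spec$A3 * exp(-spec$l3 * grid)
  if (any(v < -1e-9)) stop("negative-curve: invalid input-function parameters")
  v[v < 0] <- 0
  if (grid[which.max(v)] > 2) {
    stop("negative-curve: bolus peak later than 2 min")
  }
  blood_input(grid, v)
}

# Physiological FDG parameter bounds used for region sampling (1/min; f_v
# unitless).  The clinical reference gives none; these are standard ranges.
phantom_param_bounds <- function() {
  list(f_v = c(0, 0.3), K1 = c(0.01, 1.5), k2 = c(0.01, 1.5),
       k3 = c(0.001, 0.5), k4 = c(0, 0.2))
}

phantom_region <- function(name, geometry, params,
                           center = NULL, radius = NULL, axes = NULL) {
  structure(list(name = name, geometry = geometry, center = center,
                 radius = radius, axes = axes, params = params),
            class = "phantom_region")
}

#' Default phantom regions
#'
#' Four-region anatomy on the unit square (coordinates as fractions of the
#' image side): air background (zero uptake), a soft-tissue body disk, a
#' liver-like high-`K1` ellipse and a lesion-like high-`k3` focus.  All
#' regions are irreversible (`k4 = 0`), matching the Patlak framing.
#'
#' @return A list of `phantom_region` objects (first entry is the background;
#'   later entries overwrite earlier ones where they overlap).
#' @export
default_phantom_regions <- function() {
  list(
    phantom_region("background", "background",
                   kinetic_params(0, 0, 0, 0, 0)),
    phantom_region("soft_tissue", "disk", center = c(0.5, 0.5), radius = 0.42,
                   params = kinetic_params(0.03, 0.3, 0.4, 0.03, 0)),
    phantom_region("liver", "ellipse", center = c(0.38, 0.60),
                   axes = c(0.20, 0.13),
                   params = kinetic_params(0.10, 0.8, 0.9, 0.02, 0)),
    phantom_region("lesion", "disk", center = c(0.68, 0.34), radius = 0.07,
                   params = kinetic_params(0.05, 0.5, 0.4, 0.15, 0))
  )
}

#' Phantom specification
#'
#' @param shape image shape `c(H, W)` (default 64 x 64 2-D slices).
#' @param regions list of regions from [default_phantom_regions()] or
#'   `phantom_region`-style entries.
#' @param seed RNG seed making the generated phantom fully reproducible.
#' @param noise_scale base noise s.d. at unit (1-min) frame duration, in frame
#'   value units; per-frame s.d. is `noise_scale / sqrt(duration)` so longer
#'   frames are cleaner.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(shape = c(64, 64),
                         regions = default_phantom_regions(),
                         seed = 1, noise_scale = 2.0) {
  stopifnot(length(shape) == 2, all(shape >= 4))
  bounds <- phantom_param_bounds()
  for (r in regions) {
    p <- r$params
    if (r$geometry == "background") next
    for (nm in names(bounds)) {
      if (p[[nm]] < bounds[[nm]][1] - 1e-12 ||
          p[[nm]] > bounds[[nm]][2] + 1e-12) {
        stop(sprintf("region '%s': %s outside physiological bounds", r$name, nm))
      }
    }
  }
  structure(list(shape = as.integer(shape), regions = regions,
                 seed = as.integer(seed), noise_scale = noise_scale),
            class = "phantom_spec")
}

#' Randomized phantom specification
#'
#' Jitters the default anatomy (region centers, sizes) and samples region
#' parameters uniformly within the physiological bounds, for building
#' training sets of distinct slices.  Irreversible (`k4 = 0`) by default.
#'
#' @param seed RNG seed (also stored in the spec).
#' @param shape image shape.
#' @param noise_scale see [phantom_spec()].
#' @param reversible when `TRUE`, sample `k4` within its bounds instead of 0.
#' @return A `phantom_spec` object.
#' @export
sample_phantom_spec <- function(seed, shape = c(64, 64), noise_scale = 2.0,
                                reversible = FALSE) {
  with_seed(seed, {
    jit <- function(x, s) x + runif(length(x), -s, s)
    rpar <- function(K1r, k2r, k3r, fvr) {
      kinetic_params(runif(1, fvr[1], fvr[2]), runif(1, K1r[1], K1r[2]),
                     runif(1, k2r[1], k2r[2]), runif(1, k3r[1], k3r[2]),
                     if (reversible) runif(1, 0, 0.2) else 0)
    }
    regions <- list(
      phantom_region("background", "background",
                     kinetic_params(0, 0, 0, 0, 0)),
      phantom_region("soft_tissue", "disk", center = jit(c(0.5, 0.5), 0.03),
                     radius = runif(1, 0.38, 0.45),
                     params = rpar(c(0.2, 0.5), c(0.3, 0.6), c(0.01, 0.05),
                                   c(0.01, 0.06))),
      phantom_region("liver", "ellipse", center = jit(c(0.38, 0.60), 0.05),
                     axes = c(runif(1, 0.15, 0.24), runif(1, 0.10, 0.16)),
                     params = rpar(c(0.6, 1.1), c(0.6, 1.2), c(0.01, 0.04),
                                   c(0.05, 0.15))),
      phantom_region("lesion", "disk", center = jit(c(0.68, 0.34), 0.06),
                     radius = runif(1, 0.05, 0.10),
                     params = rpar(c(0.3, 0.8), c(0.3, 0.6), c(0.08, 0.3),
                                   c(0.02, 0.08)))
    )
    phantom_spec(shape = shape, regions = regions, seed = seed,
                 noise_scale = noise_scale)
  })
}

# Region label matrix (integers indexing spec$regions; background = 1).
phantom_region_masks <- function(spec) {
  H <- spec$shape[1]; W <- spec$shape[2]
  rows <- matrix(seq_len(H) / H, H, W)
  cols <- matrix(rep(seq_len(W) / W, each = H), H, W)
  lab <- matrix(1L, H, W)
  for (i in seq_along(spec$regions)) {
    r <- spec$regions[[i]]
    if (r$geometry == "background") next
    inside <- switch(r$geometry,
      disk = (rows - r$center[1])^2 + (cols - r$center[2])^2 <= r$radius^2,
      ellipse = ((rows - r$center[1]) / r$axes[1])^2 +
        ((cols - r$center[2]) / r$axes[2])^2 <= 1,
      rect = abs(rows - r$center[1]) <= r$axes[1] &
        abs(cols - r$center[2]) <= r$axes[2],
      stop("unknown region geometry: ", r$geometry)
    )
    lab[inside] <- i
  }
  lab
}

#' Parameter maps of a phantom specification
#'
#' @param spec a [phantom_spec()].
#' @return `H x W x 5` array (see [param_maps()]) with a `region_labels`
#'   attribute (integer matrix indexing `spec$regions`).
#' @export
phantom_param_maps <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  lab <- phantom_region_masks(spec)
  pull <- function(nm) {
    vals <- vapply(spec$regions, function(r) r$params[[nm]], numeric(1))
    matrix(vals[lab], spec$shape[1], spec$shape[2])
  }
  maps <- param_maps(pull("f_v"), pull("K1"), pull("k2"), pull("k3"),
                     pull("k4"))
  attr(maps, "region_labels") <- lab
  maps
}

#' Generate a synthetic dynamic-PET phantom
#'
#' Simulates the clean frame series from the per-region 2TCM parameters via
#' the analytic forward model, then adds seeded Gaussian noise whose per-frame
#' standard deviation is `noise_scale / sqrt(frame duration)` (short early
#' frames are noisy, long late frames are clean, mimicking count statistics
#' after reconstruction).
#'
#' @param spec a [phantom_spec()].
#' @param schedule a [frame_schedule()]; default the 28-frame protocol.
#' @param blood a [blood_input()]; default the analytic Feng curve.
#' @param dt quadrature step (min).
#' @param decay_corrected passed to the simulator (default `TRUE`).
#' @return A list: `noisy` and `clean` [dynamic_series()], `maps` (truth
#'   parameter array with region labels), `ki_true` (analytic irreversible-
#'   limit `(1 - f_v) K1 k3/(k2+k3)` voxel-slope map; exact for `k4 = 0`
#'   regions), `blood`,
#'   `schedule`, `spec`.
#' @export
generate_phantom <- function(spec, schedule = default_schedule(),
                             blood = analytic_input_function(),
                             dt = 0.05, decay_corrected = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  maps <- phantom_param_maps(spec)
  clean <- simulate_dynamic_frames(maps, blood, schedule, dt = dt,
                                   decay_corrected = decay_corrected)
  durations <- frame_durations(schedule)
  noisy_frames <- clean$frames
  if (spec$noise_scale > 0) {
    with_seed(spec$seed, {
      d <- dim(clean$frames)
      for (m in seq_len(d[1])) {
        noisy_frames[m, , ] <- clean$frames[m, , ] +
          rnorm(d[2] * d[3], sd = spec$noise_scale / sqrt(durations[m]))
      }
    })
  }
  # irreversible-limit slope of the voxel TAC: the tissue slope K1 k3/(k2+k3)
  # diluted by the blood volume fraction (the f_v C_WB term adds intercept,
  # not slope)
  denom <- maps[, , "k2"] + maps[, , "k3"]
  ki_true <- ifelse(denom > 0, maps[, , "K1"] * maps[, , "k3"] / denom, 0) *
    (1 - maps[, , "f_v"])
  list(noisy = dynamic_series(noisy_frames, schedule), clean = clean,
       maps = maps, ki_true = ki_true, blood = blood, schedule = schedule,
       spec = spec)
}

#' SUV normalization of a dynamic series
#'
#' `SUV = C / (dose / weight)`: with frame values in kBq/ml, injected dose in
#' MBq and body weight in kg the scale factor is exactly
#' `weight_kg / dose_MBq` (1 g of tissue is taken as 1 ml).  Defaults match a
#' typical adult protocol (63 kg, 300 MBq).
#'
#' @param series a [dynamic_series()] with frame values in kBq/ml.
#' @param weight_kg body weight (kg), `> 0`.
#' @param dose_MBq injected activity (MBq), `> 0`.
#' @return The series scaled to SUV units.
#' @export
to_suv <- function(series, weight_kg = 63, dose_MBq = 300) {
  stopifnot(inherits(series, "dynamic_series"))
  if (weight_kg <= 0 || dose_MBq <= 0) {
    stop("non-positive weight/dose")
  }
  series$frames <- series$frames * (weight_kg / dose_MBq)
  series
}

#' @rdname to_suv
#' @export
from_suv <- function(series, weight_kg = 63, dose_MBq = 300) {
  stopifnot(inherits(series, "dynamic_series"))
  if (weight_kg <= 0 || dose_MBq <= 0) {
    stop("non-positive weight/dose")
  }
  series$frames <- series$frames * (dose_MBq / weight_kg)
  series
}

# Evaluate code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
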