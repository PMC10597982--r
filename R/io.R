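# On-disk formats.  Dynamic series travel as 4-D NIfTI-1 (frame as the 4th
# axis, float32) with a JSON schedule sidecar; times are seconds on disk and
# minutes in memory.  No NIfTI package ships with the target environment, so
# a minimal single-file NIfTI-1 codec lives here (little-endian, .nii or
# .nii.gz, datatypes float32/float64/int16/uint8, no extensions).

nifti_open <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

# Sequential, explicit header writer (used by write_nifti_impl).
nifti_header_bytes <- function(d, datatype = 16L, bitpix = 32L,
                               pixdim = rep(1, 4)) {
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  dim8 <- c(length(d), d, rep(1L, 7 - length(d)))
  wi(348, 4)                         # sizeof_hdr
  writeBin(raw(28), con)             # data_type[10] + db_name[18]
  wi(0, 4)                           # extents
  wi(0, 2)                           # session_error
  writeBin(charToRaw("r"), con)      # regular
  writeBin(raw(1), con)              # dim_info
  wi(dim8, 2)                        # dim[8]
  wf(c(0, 0, 0))                     # intent_p1..p3
  wi(0, 2)                           # intent_code
  wi(datatype, 2)                    # datatype
  wi(bitpix, 2)                      # bitpix
  wi(0, 2)                           # slice_start
  wf(c(0, pixdim, rep(1, 7 - length(pixdim))))  # pixdim[8] (qfac = 0)
  wf(352)                            # vox_offset
  wf(1); wf(0)                       # scl_slope, scl_inter
  wi(0, 2)                           # slice_end
  writeBin(raw(2), con)              # slice_code, xyzt_units
  wf(c(0, 0, 0))                     # cal_max, cal_min, slice_duration
  wf(0)                              # toffset
  wi(c(0, 0), 4)                     # glmax, glmin
  writeBin(raw(104), con)            # descrip[80] + aux_file[24]
  wi(c(0, 0), 2)                     # qform_code, sform_code
  wf(rep(0, 18))                     # quaternions + srow (identity-free)
  writeBin(raw(16), con)             # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)  # magic
  writeBin(raw(4), con)              # extension flag
  rawConnectionValue(con)
}

write_nifti_impl <- function(data, path, float64 = FALSE) {
  d <- dim(data) %||% length(data)
  hdr <- nifti_header_bytes(d, datatype = if (float64) 64L else 16L,
                            bitpix = if (float64) 64L else 32L)
  stopifnot(length(hdr) == 352)
  con <- nifti_open(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(as.numeric(data), con, size = if (float64) 8 else 4,
           endian = "little")
  invisible(path)
}

read_nifti_impl <- function(path) {
  con <- nifti_open(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 352)
  ri <- function(off, size, n = 1) {
    readBin(hdr[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = "little")
  }
  rf <- function(off, n = 1) {
    readBin(hdr[(off + 1):(off + 4 * n)], "double", n = n, size = 4,
            endian = "little")
  }
  if (ri(0, 4) != 348) stop("not a NIfTI-1 file (or wrong endianness)")
  dim8 <- ri(40, 2, 8)
  nd <- dim8[1]
  d <- dim8[2:(1 + nd)]
  datatype <- ri(70, 2)
  vox_offset <- rf(108)
  n <- prod(d)
  skip <- vox_offset - 352
  if (skip > 0) readBin(con, "raw", skip)
  data <- switch(as.character(datatype),
    "2" = as.numeric(readBin(con, "integer", n = n, size = 1, signed = FALSE)),
    "4" = as.numeric(readBin(con, "integer", n = n, size = 2,
                             endian = "little")),
    "16" = readBin(con, "double", n = n, size = 4, endian = "little"),
    "64" = readBin(con, "double", n = n, size = 8, endian = "little"),
    stop("unsupported NIfTI datatype: ", datatype))
  slope <- rf(112); inter <- rf(116)
  if (slope != 0 && !(slope == 1 && inter == 0)) data <- data * slope + inter
  array(data, d)
}

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' Write / read a frame schedule as a JSON sidecar
#'
#' On disk times are seconds and the nuclide is described by its half-life:
#' `{"starts_s": [...], "ends_s": [...], "half_life_s": ...}`; in memory
#' times are minutes and the decay constant is `log(2)/half-life`.
#'
#' @param schedule a [frame_schedule()].
#' @param path destination `.json` path.
#' @return `path` invisibly; `read_schedule` returns a [frame_schedule()].
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "frame_schedule"))
  half_life_s <- if (schedule$decay_lambda > 0) {
    log(2) / schedule$decay_lambda * 60
  } else NULL
  obj <- list(starts_s = schedule$starts * 60, ends_s = schedule$ends * 60,
              half_life_s = half_life_s)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lambda <- if (is.null(obj$half_life_s)) 0 else log(2) / (obj$half_life_s / 60)
  frame_schedule(obj$starts_s / 60, obj$ends_s / 60, lambda)
}

#' Write / read a dynamic series as 4-D NIfTI + JSON schedule sidecar
#'
#' Frames are stored float32 (round-trip within 1e-7 relative) on the 4th
#' axis as `(H, W, 1, T)`; the schedule goes to a same-named `.json` sidecar.
#'
#' @param series a [dynamic_series()].
#' @param path `.nii` or `.nii.gz` destination.
#' @return `path` invisibly; `read_series` returns the [dynamic_series()].
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "dynamic_series"))
  d <- dim(series$frames)
  vol <- array(aperm(series$frames, c(2, 3, 1)), c(d[2], d[3], 1, d[1]))
  write_nifti_impl(vol, path)
  write_schedule(series$schedule, sidecar_path(path))
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) stop("missing-sidecar: ", sp)
  schedule <- read_schedule(sp)
  vol <- read_nifti_impl(path)
  d <- dim(vol)
  if (length(d) == 3) d <- c(d, 1)
  Tn <- d[4]
  if (Tn != length(schedule$starts)) {
    stop(sprintf("frame-count-mismatch: image has %d frames, schedule %d",
                 Tn, length(schedule$starts)))
  }
  frames <- aperm(array(vol, c(d[1], d[2], d[4])), c(3, 1, 2))
  dynamic_series(frames, schedule)
}

#' Write a Ki map as NIfTI volumes plus JSON metadata
#'
#' Writes `<base>_ki.nii.gz` and `<base>_v0.nii.gz` (float64) and
#' `<base>_ki.json` recording the tail length and blood-input provenance.
#'
#' @param km a `ki_map` object.
#' @param base output path base (no extension).
#' @param blood_provenance free-text provenance string for the metadata.
#' @return Named character vector of written paths, invisibly.
#' @export
write_ki_map <- function(km, base, blood_provenance = "unspecified") {
  stopifnot(inherits(km, "ki_map"))
  paths <- c(ki = paste0(base, "_ki.nii.gz"), v0 = paste0(base, "_v0.nii.gz"),
             meta = paste0(base, "_ki.json"))
  write_nifti_impl(km$ki, paths["ki"], float64 = TRUE)
  write_nifti_impl(km$v0, paths["v0"], float64 = TRUE)
  jsonlite::write_json(list(n_tail = km$n_tail, fit_frames = km$fit_frames,
                            blood_input = blood_provenance),
                       paths["meta"], auto_unbox = TRUE)
  invisible(paths)
}

# ---- run configuration ----

run_config_defaults <- function() {
  list(
    seed = 1L,
    variant = "kinetic",
    shape = c(64L, 64L),
    noise_scale = 2.0,
    n_tail = 13L,
    dt = 0.05,
    decay_corrected = TRUE,
    channel_scale = 1.0,
    initial_lr = 1e-4,
    decay_every_iters = 10000L,
    decay_factor = 0.1,
    lr_floor = 1e-7,
    epochs = 10L,
    iterations = NULL,
    huber_delta = 1.0,
    lambda_weight = 1.0,
    weight_kg = 63.0,
    dose_MBq = 300.0,
    n_slices = 4L
  )
}

#' Run configuration: build, save, load
#'
#' A flat, JSON-serializable record of every tunable in the pipeline;
#' `read_run_config(write_run_config(cfg))` round-trips exactly and unknown
#' keys are rejected.
#'
#' @param ... overrides of the defaults (see `run_config_defaults`):
#'   `seed`, `variant`, `shape`, `noise_scale`, `n_tail`, `dt`,
#'   `decay_corrected`, `channel_scale`, learning-rate schedule fields,
#'   `huber_delta`, `lambda_weight`, `weight_kg`, `dose_MBq`, `n_slices`,
#'   `iterations`.
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  defaults <- run_config_defaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  structure(modifyList(defaults, over, keep.null = TRUE),
            class = "run_config")
}

#' @rdname run_config
#' @param cfg a `run_config`.
#' @param path JSON file path.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- run_config_defaults()
  unknown <- setdiff(names(obj), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  # restore integer-ness lost by JSON
  for (nm in names(obj)) {
    if (is.integer(defaults[[nm]]) && !is.null(obj[[nm]])) {
      obj[[nm]] <- as.integer(obj[[nm]])
    }
  }
  do.call(run_config, obj)
}
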