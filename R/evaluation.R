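# Image-quality and agreement metrics for SUV frames and Ki maps.
# PSNR and SSIM are anchored to the REFERENCE image's dynamic range; NMI uses
# a 64-bin joint histogram over the union range; Bland-Altman limits of
# agreement are mean(d) +/- 1.96 sd(d) with the n-1 denominator.

#' Root-mean-square error
#' @param a image (prediction).
#' @param b reference image, same shape.
#' @return Scalar RMSE.
#' @export
img_rmse <- function(a, b) {
  stopifnot(length(a) == length(b))
  sqrt(mean((a - b)^2))
}

#' Peak signal-to-noise ratio
#'
#' `10 log10(R^2 / MSE)` with the data range `R` taken from the reference
#' image `b` (documented convention); identical images give `Inf`.
#'
#' @inheritParams img_rmse
#' @param data_range override the reference-derived dynamic range.
#' @return Scalar PSNR (dB); `Inf` for identical inputs.
#' @export
img_psnr <- function(a, b, data_range = NULL) {
  stopifnot(length(a) == length(b))
  mse <- mean((a - b)^2)
  if (mse == 0) return(Inf)
  r <- data_range %||% (max(b) - min(b))
  10 * log10(r^2 / mse)
}

# separable gaussian filter, "valid" region, via banded matrix products
gaussian_kernel_1d <- function(size = 11, sigma = 1.5) {
  half <- (size - 1) / 2
  k <- exp(-((-half):half)^2 / (2 * sigma^2))
  k / sum(k)
}

gfilter_valid <- function(img, k) {
  n <- length(k)
  H <- nrow(img); W <- ncol(img)
  if (H < n || W < n) stop("image smaller than the filter window")
  A <- matrix(0, H - n + 1, H)
  for (i in seq_len(H - n + 1)) A[i, i:(i + n - 1)] <- k
  B <- matrix(0, W - n + 1, W)
  for (i in seq_len(W - n + 1)) B[i, i:(i + n - 1)] <- k
  A %*% img %*% t(B)
}

#' Structural similarity index (SSIM)
#'
#' Mean SSIM with the standard Gaussian window (11 x 11, sigma 1.5) and
#' stabilizers `C1 = (0.01 R)^2`, `C2 = (0.03 R)^2`, where the dynamic range
#' `R` comes from the reference image `b`.  The map is computed on the valid
#' (fully overlapped) region.
#'
#' @param a image matrix (prediction).
#' @param b reference image matrix, same shape.
#' @param data_range override the reference-derived dynamic range.
#' @param size,sigma Gaussian window parameters.
#' @return Scalar mean SSIM in `[-1, 1]`.
#' @export
img_ssim <- function(a, b, data_range = NULL, size = 11, sigma = 1.5) {
  stopifnot(identical(dim(a), dim(b)))
  r <- data_range %||% (max(b) - min(b))
  if (r == 0) r <- 1
  c1 <- (0.01 * r)^2
  c2 <- (0.03 * r)^2
  k <- gaussian_kernel_1d(size, sigma)
  mu_a <- gfilter_valid(a, k)
  mu_b <- gfilter_valid(b, k)
  va <- gfilter_valid(a * a, k) - mu_a^2
  vb <- gfilter_valid(b * b, k) - mu_b^2
  cab <- gfilter_valid(a * b, k) - mu_a * mu_b
  ssim_map <- ((2 * mu_a * mu_b + c1) * (2 * cab + c2)) /
    ((mu_a^2 + mu_b^2 + c1) * (va + vb + c2))
  mean(ssim_map)
}

#' Normalized mutual information
#'
#' `2 I(a; b) / (H(a) + H(b))` from a 64-bin joint histogram over the union
#' of the two images' ranges (a symmetric variant in `[0, 1]`, 1 for
#' identical images).
#'
#' @inheritParams img_rmse
#' @param bins histogram bins per axis (default 64).
#' @return Scalar NMI.
#' @export
img_nmi <- function(a, b, bins = 64) {
  stopifnot(length(a) == length(b))
  rng <- range(c(a, b))
  if (diff(rng) == 0) return(1)
  cut_idx <- function(x) {
    i <- floor((x - rng[1]) / diff(rng) * bins) + 1
    pmin(pmax(i, 1), bins)
  }
  ia <- cut_idx(as.numeric(a)); ib <- cut_idx(as.numeric(b))
  joint <- table(factor(ia, levels = 1:bins), factor(ib, levels = 1:bins))
  p <- joint / sum(joint)
  pa <- rowSums(p); pb <- colSums(p)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  ha <- ent(pa); hb <- ent(pb); hab <- ent(as.numeric(p))
  mi <- ha + hb - hab
  2 * mi / (ha + hb)
}

#' Bland-Altman agreement over an ROI
#'
#' Differences `d = a - b`; returns the mean difference and the 95% limits of
#' agreement `mean(d) +/- 1.96 sd(d)` (sample s.d., `n - 1` denominator).
#'
#' @param a,b equal-length finite samples (e.g. Ki values over a tumor ROI).
#' @return A list with `mean`, `loa_low`, `loa_high`, `sd`, `n`.
#' @export
bland_altman <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) == length(b), all(is.finite(a)), all(is.finite(b)))
  d <- a - b
  m <- mean(d)
  s <- if (length(d) > 1) sd(d) else 0
  list(mean = m, loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
       sd = s, n = length(d))
}

#' Image-pair metric report
#'
#' SSIM, PSNR, NMI and RMSE for a prediction/reference pair, plus
#' Bland-Altman statistics over an optional ROI.
#'
#' @param pred,ref image matrices of equal shape.
#' @param roi optional logical mask (same shape) for the Bland-Altman part.
#' @return A one-row tibble.
#' @export
metric_report <- function(pred, ref, roi = NULL) {
  out <- tibble::tibble(
    ssim = img_ssim(pred, ref),
    psnr = img_psnr(pred, ref),
    nmi = img_nmi(pred, ref),
    rmse = img_rmse(pred, ref))
  if (!is.null(roi)) {
    ba <- bland_altman(pred[roi], ref[roi])
    out$ba_mean <- ba$mean
    out$ba_loa_low <- ba$loa_low
    out$ba_loa_high <- ba$loa_high
  }
  out
}

#' Percent improvement of a method metric over a baseline
#'
#' `(method - baseline) / baseline * 100`, computed per image then averaged
#' -- the bookkeeping used to summarize method-vs-baseline gains on phantom
#' experiments.
#'
#' @param method,baseline numeric vectors of per-image metric values.
#' @return Mean percent change.
#' @export
percent_improvement <- function(method, baseline) {
  stopifnot(length(method) == length(baseline))
  mean((method - baseline) / baseline) * 100
}
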