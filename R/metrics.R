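# Image quality metrics (PSNR, SSIM) and the mean/SD/95%-CI aggregation
# used in comparison tables.

#' Peak signal-to-noise ratio
#'
#' `10 * log10(data_range^2 / MSE)` in decibels. Identical images (zero
#' MSE) return `Inf` as the perfect-reconstruction sentinel. Under the
#' pipeline's `[0, 1]` normalization `data_range` is 1.
#'
#' @param a,b Numeric matrices of equal shape.
#' @param data_range Dynamic range of the data (> 0, default 1).
#' @return PSNR in dB (possibly `Inf`).
#' @export
psnr <- function(a, b, data_range = 1.0) {
  check_image(a, "a"); check_image(b, "b"); check_same_shape(a, b)
  if (data_range <= 0) stop("data_range must be > 0", call. = FALSE)
  mse <- mean((a - b)^2)
  if (mse == 0) return(Inf)
  10 * log10(data_range^2 / mse)
}

# Separable valid-mode correlation with a 1D kernel along both axes.
filter_valid <- function(m, k) {
  r <- length(k)
  h <- nrow(m) - r + 1L
  out <- matrix(0, h, ncol(m))
  for (t in seq_len(r)) out <- out + k[t] * m[t:(t + h - 1L), , drop = FALSE]
  w <- ncol(out) - r + 1L
  out2 <- matrix(0, h, w)
  for (t in seq_len(r)) out2 <- out2 + k[t] * out[, t:(t + w - 1L), drop = FALSE]
  out2
}

#' Structural similarity index (SSIM)
#'
#' Mean local SSIM (Wang et al. index) with an 11x11 Gaussian window of
#' sigma 1.5 and stabilizers `K1 = 0.01`, `K2 = 0.03`. Local statistics
#' are computed in valid mode (no padding), matching the original
#' formulation, and the map is averaged over the valid interior.
#'
#' @inheritParams psnr
#' @param window Odd window size (default 11).
#' @param sigma Gaussian window sigma (default 1.5).
#' @param K1,K2 Stabilizing constants.
#' @return SSIM in `[-1, 1]`; 1 for identical images.
#' @export
ssim <- function(a, b, data_range = 1.0, window = 11L, sigma = 1.5,
                 K1 = 0.01, K2 = 0.03) {
  check_image(a, "a"); check_image(b, "b"); check_same_shape(a, b)
  window <- as.integer(window)
  if (min(dim(a)) < window)
    stop(sprintf("image smaller than %dx%d SSIM window", window, window),
         call. = FALSE)
  half <- (window - 1L) %/% 2L
  k <- exp(-((-half:half)^2) / (2 * sigma^2))
  k <- k / sum(k)
  c1 <- (K1 * data_range)^2
  c2 <- (K2 * data_range)^2
  mu1 <- filter_valid(a, k)
  mu2 <- filter_valid(b, k)
  s11 <- filter_valid(a * a, k) - mu1 * mu1
  s22 <- filter_valid(b * b, k) - mu2 * mu2
  s12 <- filter_valid(a * b, k) - mu1 * mu2
  num <- (2 * mu1 * mu2 + c1) * (2 * s12 + c2)
  den <- (mu1^2 + mu2^2 + c1) * (s11 + s22 + c2)
  mean(num / den)
}

#' Mean, SD and Student-t confidence interval of a metric
#'
#' The aggregation used for per-method score tables: sample mean, sample
#' standard deviation (n - 1 denominator) and a two-sided Student-t
#' interval `mean +/- t * SD / sqrt(n)`.
#'
#' @param values Numeric vector, `n >= 2` finite values.
#' @param confidence Confidence level in (0, 1), default 0.95.
#' @return An object of class `summary_stats` with fields `mean`, `sd`,
#'   `ci_low`, `ci_high`, `n`, `confidence`.
#' @export
summarize_metric <- function(values, confidence = 0.95) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("need at least 2 values for a confidence interval", call. = FALSE)
  if (confidence <= 0 || confidence >= 1)
    stop("confidence must be in (0, 1)", call. = FALSE)
  n <- length(values)
  m <- mean(values)
  s <- stats::sd(values)
  tq <- stats::qt((1 + confidence) / 2, df = n - 1)
  half <- tq * s / sqrt(n)
  structure(list(mean = m, sd = s, ci_low = m - half, ci_high = m + half,
                 n = n, confidence = confidence),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("mean %.4f, SD %.4f, %g%% CI [%.4f, %.4f] (n = %d)\n",
              x$mean, x$sd, 100 * x$confidence, x$ci_low, x$ci_high, x$n))
  invisible(x)
}
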