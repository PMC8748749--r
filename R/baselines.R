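# Classical interpolation baselines used as comparison columns.

#' Cubic-spline upsampling
#'
#' Interpolates a cubic spline surface through the LR samples
#' (separable natural splines along rows then columns, pixel centers
#' aligned with the bicubic resamplers). Splines reproduce constants and
#' linear ramps exactly.
#'
#' @param lr Numeric matrix.
#' @param scale Integer magnification factor (>= 2).
#' @return Matrix of size `dim(lr) * scale`.
#' @export
cubic_spline_upsample <- function(lr, scale = 2L) {
  check_image(lr, "lr")
  scale <- as.integer(scale)
  if (scale < 2L) stop("scale must be >= 2", call. = FALSE)
  interp_axis <- function(m) {
    n <- nrow(m)
    # HR pixel j (0-based) samples LR coordinate (j + 0.5)/scale - 0.5
    xout <- (seq_len(n * scale) - 0.5) / scale - 0.5
    if (n == 1L) return(m[rep(1L, n * scale), , drop = FALSE])
    apply(m, 2L, function(col)
      stats::splinefun(seq_len(n) - 1, col, method = "natural")(xout))
  }
  t(interp_axis(t(interp_axis(lr))))
}

#' Nearest-neighbor upsampling
#'
#' Pixel replication; the crudest baseline, kept for ordering checks.
#'
#' @inheritParams cubic_spline_upsample
#' @return Matrix of size `dim(lr) * scale`.
#' @export
nearest_upsample <- function(lr, scale = 2L) {
  check_image(lr, "lr")
  scale <- as.integer(scale)
  lr[rep(seq_len(nrow(lr)), each = scale),
     rep(seq_len(ncol(lr)), each = scale)]
}

# Mean of each scale x scale block.
block_means <- function(img, scale) {
  h <- nrow(img) %/% scale
  w <- ncol(img) %/% scale
  m <- matrix(0, h, w)
  for (a in seq_len(scale)) for (b in seq_len(scale))
    m <- m + img[seq(a, by = scale, length.out = h),
                 seq(b, by = scale, length.out = w)]
  m / scale^2
}

# One non-local-means pass: each pixel is replaced by a Gaussian-weighted
# average of pixels with similar patch neighborhoods, implemented by
# looping over search offsets (shift images, not pixels).
nlm_pass <- function(img, patch_radius, search_radius, h) {
  H <- nrow(img); W <- ncol(img)
  pr <- patch_radius
  shift <- function(m, dr, dc) {
    ri <- pmin(pmax(seq_len(H) + dr, 1L), H)
    ci <- pmin(pmax(seq_len(W) + dc, 1L), W)
    m[ri, ci]
  }
  acc <- matrix(0, H, W)
  wsum <- matrix(0, H, W)
  for (dr in -search_radius:search_radius) {
    for (dc in -search_radius:search_radius) {
      shifted <- shift(img, dr, dc)
      d2 <- matrix(0, H, W)
      for (a in -pr:pr) for (b in -pr:pr)
        d2 <- d2 + (shift(img, a, b) - shift(shifted, a, b))^2
      d2 <- d2 / (2 * pr + 1)^2
      wgt <- exp(-d2 / h^2)
      acc <- acc + wgt * shifted
      wsum <- wsum + wgt
    }
  }
  acc / wsum
}

#' Non-local-means upsampling (NMU)
#'
#' Iterative reconstruction: start from bicubic interpolation, then
#' alternate a non-local-means regularization pass (Gaussian-weighted
#' patch similarity) with a subsampling-consistency correction that adds
#' back, over each `scale x scale` block, the difference between the LR
#' value and the block mean of the current estimate. The final correction
#' makes the output's block means match the LR input to numerical
#' precision. This is a compact rendition of the classical NMU
#' reconstruction, not a line-by-line port.
#'
#' @inheritParams cubic_spline_upsample
#' @param patch_radius Patch half-width for similarity (default 1 =
#'   3x3 patches).
#' @param search_radius Search-window half-width (default 5 = 11x11).
#' @param h Similarity bandwidth (> 0, default 0.05 on `[0, 1]` data).
#' @param iterations Number of NLM + correction cycles (>= 1, default 4).
#' @return Matrix of size `dim(lr) * scale`.
#' @export
nmu_upsample <- function(lr, scale = 2L, patch_radius = 1L,
                         search_radius = 5L, h = 0.05, iterations = 4L) {
  check_image(lr, "lr")
  scale <- as.integer(scale)
  patch_radius <- as.integer(patch_radius)
  search_radius <- as.integer(search_radius)
  iterations <- as.integer(iterations)
  if (patch_radius < 0L || search_radius < 1L)
    stop("invalid radii", call. = FALSE)
  if (h <= 0) stop("h must be > 0", call. = FALSE)
  if (iterations < 1L) stop("iterations must be >= 1", call. = FALSE)
  est <- upsample_bicubic(lr, scale)
  correct <- function(est) {
    delta <- lr - block_means(est, scale)
    est + delta[rep(seq_len(nrow(lr)), each = scale),
                rep(seq_len(ncol(lr)), each = scale)]
  }
  est <- correct(est)
  for (it in seq_len(iterations)) {
    est <- nlm_pass(est, patch_radius, search_radius, h)
    est <- correct(est)
  }
  est
}

#' Look up a super-resolution method by name
#'
#' Registry used by the evaluation harness and the CLI. Each method is a
#' function `f(lr, scale)` returning the super-resolved image.
#'
#' @param name One of `"bicubic"`, `"cubic_spline"`, `"nmu"`,
#'   `"nearest"`.
#' @return The method function.
#' @export
sr_method <- function(name) {
  switch(name,
         bicubic = function(lr, scale) upsample_bicubic(lr, scale),
         cubic_spline = function(lr, scale) cubic_spline_upsample(lr, scale),
         nmu = function(lr, scale) nmu_upsample(lr, scale),
         nearest = function(lr, scale) nearest_upsample(lr, scale),
         stop(sprintf("unknown method '%s'", name), call. = FALSE))
}

#' Wrap a trained model as an evaluation method
#'
#' @param model A `model_state`.
#' @return A function `f(lr, scale)` running [predict_slice()] (the
#'   model's own scale must match the requested one).
#' @export
model_method <- function(model) {
  force(model)
  function(lr, scale) {
    if (scale != model$config$scale)
      stop("model scale does not match requested scale", call. = FALSE)
    predict_slice(model, lr)
  }
}
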