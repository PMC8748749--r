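# Degradation model: bicubic decimation/interpolation and LR/HR pairing.
#
# Convention: pixel centers are aligned between grids, so output pixel i
# (0-based) samples input coordinate (i + 0.5) * n_in / n_out - 0.5.
# Boundary handling is edge replication. The downsampler is a single
# bicubic decimation; an optional Gaussian pre-blur is available but off
# by default (see `pre_blur_sigma`).

# Keys cubic convolution kernel, a = -0.5 (the conventional "bicubic").
bicubic_kernel <- function(x, a = -0.5) {
  ax <- abs(x)
  ifelse(ax <= 1,
         (a + 2) * ax^3 - (a + 3) * ax^2 + 1,
         ifelse(ax < 2, a * ax^3 - 5 * a * ax^2 + 8 * a * ax - 4 * a, 0))
}

# n_out x n_in row-stochastic resampling matrix for one axis.
resample_matrix <- function(n_in, n_out) {
  m <- matrix(0, n_out, n_in)
  ratio <- n_in / n_out
  for (i in seq_len(n_out)) {
    src <- (i - 0.5) * ratio - 0.5          # 0-based source coordinate
    base <- floor(src)
    taps <- (base - 1):(base + 2)
    wts <- bicubic_kernel(src - taps)
    taps <- pmin(pmax(taps, 0), n_in - 1)   # edge replication
    for (t in seq_along(taps)) m[i, taps[t] + 1] <- m[i, taps[t] + 1] + wts[t]
  }
  m
}

#' Bicubic downsampling (the degradation operator)
#'
#' Decimates an image by an integer factor with the Keys `a = -0.5` cubic
#' kernel, pixel centers aligned, edges replicated. This is the operator
#' that derives the low-resolution observation from a high-resolution
#' slice in the pairing model.
#'
#' @param img Numeric matrix with finite values.
#' @param scale Integer decimation factor (>= 2); both image dimensions
#'   must be divisible by it (center-crop first, see [make_pair()]).
#' @param pre_blur_sigma Optional Gaussian pre-blur sigma in pixels applied
#'   before decimation (0 = none, the default).
#' @return Matrix of size `dim(img) / scale`.
#' @export
downsample_bicubic <- function(img, scale = 2L, pre_blur_sigma = 0) {
  check_image(img)
  scale <- as.integer(scale)
  if (scale < 2L) stop("scale must be >= 2", call. = FALSE)
  if (nrow(img) %% scale != 0L || ncol(img) %% scale != 0L)
    stop(sprintf("image dimensions %dx%d not divisible by scale %d",
                 nrow(img), ncol(img), scale), call. = FALSE)
  if (pre_blur_sigma > 0) img <- gaussian_blur(img, pre_blur_sigma)
  mr <- resample_matrix(nrow(img), nrow(img) %/% scale)
  mc <- resample_matrix(ncol(img), ncol(img) %/% scale)
  mr %*% img %*% t(mc)
}

#' Bicubic upsampling (the interpolation operator)
#'
#' Interpolates an image up by an integer factor with the Keys `a = -0.5`
#' cubic kernel; the conventional bicubic interpolation that the residual
#' formulation subtracts from the high-resolution target.
#'
#' @inheritParams downsample_bicubic
#' @param scale Integer magnification factor (>= 2).
#' @return Matrix of size `dim(img) * scale`.
#' @export
upsample_bicubic <- function(img, scale = 2L) {
  check_image(img)
  scale <- as.integer(scale)
  if (scale < 2L) stop("scale must be >= 2", call. = FALSE)
  mr <- resample_matrix(nrow(img), nrow(img) * scale)
  mc <- resample_matrix(ncol(img), ncol(img) * scale)
  mr %*% img %*% t(mc)
}

#' Build an aligned LR/HR training pair
#'
#' Applies the degradation model to a high-resolution slice `y`: the
#' low-resolution image is `x = downsample(y)`, the interpolated image is
#' `z = upsample(x)`, and the residual `r = y - z` is the detail the
#' network learns to restore, so `r + z` reconstructs `y` exactly by
#' construction. Odd dimensions are center-cropped to multiples of
#' `scale` first.
#'
#' @param hr High-resolution slice (numeric matrix, values in `[0, 1]`).
#' @param scale Integer scale factor (default 2).
#' @param pre_blur_sigma Passed to [downsample_bicubic()].
#' @return An object of class `image_pair` with fields `hr`, `lr`,
#'   `upsampled`, `residual`, `scale`.
#' @export
make_pair <- function(hr, scale = 2L, pre_blur_sigma = 0) {
  check_image(hr, "hr")
  scale <- as.integer(scale)
  h <- nrow(hr) - nrow(hr) %% scale
  w <- ncol(hr) - ncol(hr) %% scale
  if (h < scale || w < scale) stop("hr too small for scale", call. = FALSE)
  r0 <- (nrow(hr) - h) %/% 2L
  c0 <- (ncol(hr) - w) %/% 2L
  hr <- hr[r0 + seq_len(h), c0 + seq_len(w), drop = FALSE]
  lr <- downsample_bicubic(hr, scale, pre_blur_sigma)
  up <- upsample_bicubic(lr, scale)
  structure(list(hr = hr, lr = lr, upsampled = up, residual = hr - up,
                 scale = scale),
            class = "image_pair")
}

#' @export
print.image_pair <- function(x, ...) {
  cat(sprintf("image_pair: hr %dx%d, lr %dx%d (scale %d), residual sd %.4g\n",
              nrow(x$hr), ncol(x$hr), nrow(x$lr), ncol(x$lr), x$scale,
              stats::sd(x$residual)))
  invisible(x)
}

#' Randomly sample aligned HR/LR patch pairs
#'
#' Cuts `count` co-located patch pairs from a precomputed [make_pair()]
#' result. HR offsets are drawn uniformly (with replacement) over even
#' 0-based positions so every LR patch is positionally aligned with its HR
#' patch at `offset / scale`. Deterministic under `seed`.
#'
#' @param pair An `image_pair`.
#' @param patch_hr HR patch side in pixels (even; default 128).
#' @param count Number of patches (default 64).
#' @param seed Integer seed.
#' @return An object of class `patch_batch`: lists `hr_patches`
#'   (`patch_hr` square) and `lr_patches` (`patch_hr / scale` square),
#'   0-based even `offsets` (rows `row`, `col`), and `count`.
#' @export
sample_patches <- function(pair, patch_hr = 128L, count = 64L, seed = 0L) {
  stopifnot(inherits(pair, "image_pair"))
  patch_hr <- as.integer(patch_hr); count <- as.integer(count)
  if (patch_hr %% 2L != 0L) stop("patch_hr must be even", call. = FALSE)
  if (count < 1L) stop("count must be >= 1", call. = FALSE)
  h <- nrow(pair$hr); w <- ncol(pair$hr); s <- pair$scale
  if (patch_hr > h || patch_hr > w)
    stop(sprintf("patch %d exceeds image %dx%d", patch_hr, h, w),
         call. = FALSE)
  # even 0-based offsets: 0, 2, ..., dim - patch
  n_r <- (h - patch_hr) %/% 2L + 1L
  n_c <- (w - patch_hr) %/% 2L + 1L
  rng <- local_rng(seed)
  off_r <- (rng$sample_int(n_r, count, replace = TRUE) - 1L) * 2L
  off_c <- (rng$sample_int(n_c, count, replace = TRUE) - 1L) * 2L
  patch_lr <- patch_hr %/% s
  hr_patches <- vector("list", count)
  lr_patches <- vector("list", count)
  for (k in seq_len(count)) {
    hr_patches[[k]] <- pair$hr[off_r[k] + seq_len(patch_hr),
                               off_c[k] + seq_len(patch_hr), drop = FALSE]
    lr_patches[[k]] <- pair$lr[off_r[k] %/% s + seq_len(patch_lr),
                               off_c[k] %/% s + seq_len(patch_lr),
                               drop = FALSE]
  }
  structure(list(hr_patches = hr_patches, lr_patches = lr_patches,
                 offsets = data.frame(row = off_r, col = off_c),
                 count = count),
            class = "patch_batch")
}
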