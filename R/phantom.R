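#' Specification for a synthetic brain-like phantom
#'
#' Describes a piecewise-smooth 2D test image built from overlapping
#' ellipses: sharp intensity boundaries stand in for tissue interfaces
#' (e.g. the cortical ribbon) and optional band-limited texture stands in
#' for recoverable high-frequency anatomy. Phantoms let the whole
#' super-resolution pipeline run and be tested without any MRI downloads.
#'
#' @param height,width Image size in pixels; both must be >= 32.
#' @param n_ellipses Number of ellipses painted on the background (>= 1).
#' @param intensity_levels Numeric vector of gray levels in `[0, 1]`.
#'   Element 1 is the background; ellipse k takes level
#'   `intensity_levels[(k %% (length - 1)) + 2]`, cycling through the
#'   foreground levels in generation order.
#' @param texture_amplitude Peak-to-peak amplitude of additive band-limited
#'   texture inside the foreground (>= 0; 0 disables texture).
#' @param edge_smoothing_sigma Standard deviation (pixels) of a Gaussian
#'   blur applied to the painted label image; 0 keeps hard edges.
#'
#' @return An object of class `phantom_spec`.
#' @seealso [generate_phantom()], [generate_dataset()]
#' @export
phantom_spec <- function(height = 128L, width = 128L, n_ellipses = 6L,
                         intensity_levels = c(0, 0.35, 0.55, 0.8),
                         texture_amplitude = 0.1,
                         edge_smoothing_sigma = 0) {
  height <- as.integer(height); width <- as.integer(width)
  n_ellipses <- as.integer(n_ellipses)
  if (is.na(height) || is.na(width) || height < 32L || width < 32L)
    stop("phantom dimensions must be integers >= 32", call. = FALSE)
  if (is.na(n_ellipses) || n_ellipses < 1L)
    stop("n_ellipses must be >= 1", call. = FALSE)
  if (length(intensity_levels) < 2L ||
      any(intensity_levels < 0) || any(intensity_levels > 1))
    stop("intensity_levels must have >= 2 values, all in [0, 1]",
         call. = FALSE)
  if (texture_amplitude < 0) stop("texture_amplitude must be >= 0",
                                  call. = FALSE)
  if (edge_smoothing_sigma < 0) stop("edge_smoothing_sigma must be >= 0",
                                     call. = FALSE)
  structure(list(height = height, width = width, n_ellipses = n_ellipses,
                 intensity_levels = as.numeric(intensity_levels),
                 texture_amplitude = texture_amplitude,
                 edge_smoothing_sigma = edge_smoothing_sigma),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("phantom_spec: %dx%d, %d ellipses, levels {%s},\n",
              x$height, x$width, x$n_ellipses,
              paste(format(x$intensity_levels), collapse = ", ")))
  cat(sprintf("  texture amplitude %g, edge smoothing sigma %g\n",
              x$texture_amplitude, x$edge_smoothing_sigma))
  invisible(x)
}

# Separable Gaussian blur with edge replication; sigma in pixels.
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  radius <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-radius:radius)^2) / (2 * sigma^2))
  k <- k / sum(k)
  blur1 <- function(m) {
    n <- nrow(m)
    idx <- outer(seq_len(n), -radius:radius, `+`)
    idx[idx < 1L] <- 1L; idx[idx > n] <- n
    out <- matrix(0, n, ncol(m))
    for (t in seq_along(k)) out <- out + k[t] * m[idx[, t], , drop = FALSE]
    out
  }
  t(blur1(t(blur1(img))))
}

#' Generate a synthetic brain-like phantom slice
#'
#' Paints `n_ellipses` ellipses over a uniform background, later ellipses
#' over earlier ones. Ellipse centers, axes and rotations are drawn
#' uniformly within margins that keep each ellipse fully inside the frame,
#' so nested placements produce closed high-contrast boundaries. Texture,
#' when enabled, is smoothed white noise rescaled to the requested
#' peak-to-peak amplitude and added inside the foreground; the result is
#' clipped to `[0, 1]`. Generation is a pure function of `(spec, seed)`.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed; identical `(spec, seed)` give bit-identical
#'   output.
#' @return A `height x width` numeric matrix with values in `[0, 1]`.
#' @examples
#' img <- generate_phantom(phantom_spec(64, 64), seed = 1)
#' range(img)
#' @export
generate_phantom <- function(spec, seed) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  rng <- local_rng(seed)
  h <- spec$height; w <- spec$width
  levels <- spec$intensity_levels
  img <- matrix(levels[1], h, w)
  fg <- matrix(FALSE, h, w)
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  n_fg_levels <- length(levels) - 1L
  for (k in seq_len(spec$n_ellipses)) {
    # axes first, then a center leaving the whole ellipse inside the frame
    a <- rng$runif(1, 0.08, 0.35) * w / 2   # semi-axis along x
    b <- rng$runif(1, 0.08, 0.35) * h / 2   # semi-axis along y
    theta <- rng$runif(1, 0, pi)
    # bounding half-extents of the rotated ellipse
    ex <- sqrt((a * cos(theta))^2 + (b * sin(theta))^2)
    ey <- sqrt((a * sin(theta))^2 + (b * cos(theta))^2)
    cx <- rng$runif(1, 1 + ex, w - ex)
    cy <- rng$runif(1, 1 + ey, h - ey)
    ct <- cos(theta); st <- sin(theta)
    xr <- (xx - cx) * ct + (yy - cy) * st
    yr <- -(xx - cx) * st + (yy - cy) * ct
    inside <- (xr / a)^2 + (yr / b)^2 <= 1
    img[inside] <- levels[((k - 1L) %% n_fg_levels) + 2L]
    fg <- fg | inside
  }
  if (spec$edge_smoothing_sigma > 0)
    img <- gaussian_blur(img, spec$edge_smoothing_sigma)
  if (spec$texture_amplitude > 0) {
    noise <- gaussian_blur(matrix(rng$rnorm(h * w), h, w), 1.2)
    rng_pp <- diff(range(noise))
    if (rng_pp > 0) {
      noise <- (noise - mean(noise)) / rng_pp * spec$texture_amplitude
      img[fg] <- img[fg] + noise[fg]
    }
  }
  pmin(pmax(img, 0), 1)
}

#' Generate a deterministic list of phantom slices
#'
#' Item `k` uses a per-item seed derived purely from `(seed, k)`, so any
#' prefix of the dataset is stable under extension of `n`.
#'
#' @inheritParams generate_phantom
#' @param n Number of phantoms (>= 1).
#' @return List of `n` numeric matrices.
#' @export
generate_dataset <- function(n, spec, seed) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be >= 1", call. = FALSE)
  lapply(seq_len(n) - 1L,
         function(k) generate_phantom(spec, seed = derive_seed(seed, k)))
}
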