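# Shared fixtures and independent reference implementations used as
# oracles. These are deliberately naive (explicit loops) and share no
# code with the package internals.

tiny_spec <- function(...) phantom_spec(height = 64, width = 64, ...)

# Smooth low-frequency test image: a Gaussian blob.
gaussian_blob <- function(n = 64, sigma = n / 5) {
  c0 <- (n + 1) / 2
  g <- outer(seq_len(n), seq_len(n), function(i, j)
    exp(-((i - c0)^2 + (j - c0)^2) / (2 * sigma^2)))
  0.1 + 0.8 * g
}

# Loop-based Charbonnier: mean over batch items and pixels.
ref_charbonnier <- function(pred, target, eps) {
  if (!is.list(pred)) { pred <- list(pred); target <- list(target) }
  tot <- 0; n <- 0
  for (k in seq_along(pred)) {
    p <- pred[[k]]; y <- target[[k]]
    for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
      tot <- tot + sqrt((p[i, j] - y[i, j])^2 + eps^2)
      n <- n + 1
    }
  }
  tot / n
}

# Loop-based GDL: per-image sum over neighbor pairs, batch mean.
ref_gdl <- function(pred, target) {
  if (!is.list(pred)) { pred <- list(pred); target <- list(target) }
  tot <- 0
  for (k in seq_along(pred)) {
    p <- pred[[k]]; y <- target[[k]]
    acc <- 0
    for (i in 2:nrow(p)) for (j in seq_len(ncol(p)))
      acc <- acc + (abs(y[i, j] - y[i - 1, j]) -
                    abs(p[i, j] - p[i - 1, j]))^2
    for (i in seq_len(nrow(p))) for (j in 2:ncol(p))
      acc <- acc + (abs(y[i, j] - y[i, j - 1]) -
                    abs(p[i, j] - p[i, j - 1]))^2
    tot <- tot + acc
  }
  tot / length(pred)
}

# Loop-based mean local SSIM over valid 11x11 Gaussian windows.
ref_ssim <- function(a, b, data_range = 1, window = 11, sigma = 1.5,
                     K1 = 0.01, K2 = 0.03) {
  half <- (window - 1) / 2
  k1d <- exp(-((-half:half)^2) / (2 * sigma^2))
  w <- outer(k1d, k1d)
  w <- w / sum(w)
  c1 <- (K1 * data_range)^2; c2 <- (K2 * data_range)^2
  vals <- c()
  for (i in seq_len(nrow(a) - window + 1)) {
    for (j in seq_len(ncol(a) - window + 1)) {
      wa <- a[i:(i + window - 1), j:(j + window - 1)]
      wb <- b[i:(i + window - 1), j:(j + window - 1)]
      mu1 <- sum(w * wa); mu2 <- sum(w * wb)
      v1 <- sum(w * wa^2) - mu1^2
      v2 <- sum(w * wb^2) - mu2^2
      cv <- sum(w * wa * wb) - mu1 * mu2
      vals <- c(vals, ((2 * mu1 * mu2 + c1) * (2 * cv + c2)) /
                       ((mu1^2 + mu2^2 + c1) * (v1 + v2 + c2)))
    }
  }
  mean(vals)
}

# 1D Keys cubic kernel written out from the polynomial, for tap tables.
ref_cubic_taps <- function(x, a = -0.5) {
  sapply(x, function(t) {
    t <- abs(t)
    if (t <= 1) (a + 2) * t^3 - (a + 3) * t^2 + 1
    else if (t < 2) a * t^3 - 5 * a * t^2 + 8 * a * t - 4 * a
    else 0
  })
}

rand_img <- function(h, w, seed) {
  set.seed(seed)
  matrix(runif(h * w), h, w)
}
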