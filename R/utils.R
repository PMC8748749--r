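# Internal helpers shared across modules.

# Scoped RNG: draws are a pure function of `seed` and do not disturb the
# caller's .Random.seed.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  state <- get(".Random.seed", envir = globalenv())
  restore <- function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
  use <- function(f) function(...) {
    assign(".Random.seed", state, envir = globalenv())
    on.exit({
      state <<- get(".Random.seed", envir = globalenv())
      restore()
    })
    f(...)
  }
  list(runif = use(stats::runif), rnorm = use(stats::rnorm),
       sample_int = use(function(n, size, replace = FALSE)
         sample.int(n, size, replace = replace)))
}

# Pure per-item seed derivation; stays within a 31-bit range.
derive_seed <- function(seed, k) {
  s <- as.numeric(seed) %% 2147483629
  (s * 48271 + as.numeric(k) * 7919 + 11) %% 2147483629
}

# Validate a 2D image: finite numeric matrix.
check_image <- function(img, name = "img") {
  if (!is.matrix(img) || !is.numeric(img))
    stop(sprintf("%s must be a numeric matrix", name), call. = FALSE)
  if (!all(is.finite(img)))
    stop(sprintf("%s contains non-finite values", name), call. = FALSE)
  invisible(img)
}

check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("shape mismatch: %s vs %s",
                 paste(dim(a), collapse = "x"),
                 paste(dim(b), collapse = "x")), call. = FALSE)
  invisible(TRUE)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# Min-max normalization to [0, 1]; constant inputs map to all zeros.
normalize_minmax <- function(x) {
  r <- range(x)
  if (r[2] > r[1]) (x - r[1]) / (r[2] - r[1]) else x * 0
}
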