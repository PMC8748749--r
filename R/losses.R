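# Training losses: robust Charbonnier penalty, gradient difference loss
# (GDL), and their sum. Each exposes an analytic gradient with respect to
# the prediction so the optimizer can backpropagate through them.
#
# Reductions: Charbonnier is averaged over all pixels of all batch items
# (keeps its gradient scale independent of patch size); GDL is summed over
# neighbor pairs within an image and averaged over batch items only.

#' Loss configuration
#'
#' @param epsilon Charbonnier smoothing constant (> 0, default `1e-3`);
#'   the loss behaves like L2 for residuals below `epsilon` and like L1
#'   above it, which bounds the influence of outlier pixels.
#' @param gdl_weight Non-negative weight of the gradient-difference term
#'   in [combined_loss()]; 1 gives the plain unweighted sum, 0 disables
#'   GDL (the ablation setting).
#' @return An object of class `loss_config`.
#' @export
loss_config <- function(epsilon = 1e-3, gdl_weight = 1.0) {
  if (epsilon <= 0) stop("epsilon must be > 0", call. = FALSE)
  if (gdl_weight < 0) stop("gdl_weight must be >= 0", call. = FALSE)
  structure(list(epsilon = epsilon, gdl_weight = gdl_weight,
                 gdl_exponent = 2L),
            class = "loss_config")
}

as_batch <- function(x) if (is.list(x)) x else list(x)

#' Charbonnier loss
#'
#' Mean over all pixels and batch items of `sqrt(d^2 + epsilon^2)` where
#' `d = pred - target`: a differentiable surrogate for the absolute error
#' whose slope is bounded by 1, so outlier pixels cannot dominate
#' training. Equals `epsilon` exactly when `pred == target`.
#'
#' @param pred,target Numeric matrix or list of matrices (a batch); shapes
#'   must match elementwise.
#' @param cfg A [loss_config()].
#' @param grad If `TRUE`, also return the gradient with respect to `pred`.
#' @return The scalar loss, or if `grad` a list `(value, grad)` where
#'   `grad` mirrors the structure of `pred`.
#' @export
charbonnier_loss <- function(pred, target, cfg = loss_config(),
                             grad = FALSE) {
  pred <- as_batch(pred); target <- as_batch(target)
  stopifnot(length(pred) == length(target))
  eps2 <- cfg$epsilon^2
  n_total <- sum(vapply(pred, length, 0L))
  val <- 0
  grads <- if (grad) vector("list", length(pred))
  for (k in seq_along(pred)) {
    check_same_shape(pred[[k]], target[[k]])
    d <- pred[[k]] - target[[k]]
    rho <- sqrt(d * d + eps2)
    val <- val + sum(rho)
    if (grad) grads[[k]] <- d / rho / n_total
  }
  val <- val / n_total
  if (grad) list(value = val, grad = grads) else val
}

# Row/column finite differences used by the GDL.
diff_rows <- function(m) m[-1L, , drop = FALSE] - m[-nrow(m), , drop = FALSE]
diff_cols <- function(m) m[, -ncol(m), drop = FALSE] - m[, -1L, drop = FALSE]

#' Gradient difference loss (GDL)
#'
#' Penalizes the squared difference between the *magnitudes* of neighbor
#' differences of target and prediction, along both rows and columns:
#' `sum (| |grad y| - |grad yhat| |)^2` over all valid neighbor pairs,
#' averaged over batch items. It drives the prediction's edges to be as
#' strong as the target's, sharpening reconstructions; it is blind to
#' constant offsets.
#'
#' @inheritParams charbonnier_loss
#' @return Scalar loss (>= 0), or `(value, grad)` when `grad = TRUE`.
#' @export
gdl_loss <- function(pred, target, grad = FALSE) {
  pred <- as_batch(pred); target <- as_batch(target)
  stopifnot(length(pred) == length(target))
  n <- length(pred)
  val <- 0
  grads <- if (grad) vector("list", n)
  for (k in seq_len(n)) {
    p <- pred[[k]]; y <- target[[k]]
    check_same_shape(p, y)
    if (nrow(p) < 2L || ncol(p) < 2L)
      stop("GDL needs images of at least 2x2", call. = FALSE)
    dr_p <- diff_rows(p); dr_y <- diff_rows(y)
    dc_p <- diff_cols(p); dc_y <- diff_cols(y)
    er <- abs(dr_y) - abs(dr_p)
    ec <- abs(dc_y) - abs(dc_p)
    val <- val + sum(er * er) + sum(ec * ec)
    if (grad) {
      g <- matrix(0, nrow(p), ncol(p))
      # d/d(dr_p) = 2 * (|dr_p| - |dr_y|) * sign(dr_p); scatter to the
      # two pixels forming each difference
      gr <- 2 * (-er) * sign(dr_p)
      g[-1L, ] <- g[-1L, ] + gr
      g[-nrow(p), ] <- g[-nrow(p), ] - gr
      gc <- 2 * (-ec) * sign(dc_p)
      g[, -ncol(p)] <- g[, -ncol(p)] + gc
      g[, -1L] <- g[, -1L] - gc
      grads[[k]] <- g / n
    }
  }
  val <- val / n
  if (grad) list(value = val, grad = grads) else val
}

#' Combined training loss
#'
#' `charbonnier + gdl_weight * gdl`; with `gdl_weight = 0` it reduces
#' exactly to the Charbonnier loss alone.
#'
#' @inheritParams charbonnier_loss
#' @return Scalar loss, or `(value, grad)` when `grad = TRUE`.
#' @export
combined_loss <- function(pred, target, cfg = loss_config(), grad = FALSE) {
  ch <- charbonnier_loss(pred, target, cfg, grad = grad)
  if (cfg$gdl_weight == 0) return(ch)
  gd <- gdl_loss(pred, target, grad = grad)
  if (!grad) return(ch + cfg$gdl_weight * gd)
  list(value = ch$value + cfg$gdl_weight * gd$value,
       grad = Map(function(a, b) a + cfg$gdl_weight * b,
                  ch$grad, gd$grad))
}
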