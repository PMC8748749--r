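# Residual-learning super-resolution network.
#
# Two branches share one output grid:
#   * residual branch: a stack of 3x3 convolutions (zero padding, leaky
#     rectification) at LR resolution, closed by a 4x4 stride-2 transposed
#     convolution that upsamples the 64-channel features to a 1-channel
#     residual image;
#   * image branch: a single 4x4 stride-2 transposed convolution applied
#     to the LR input itself, a learned upsampler of the raw image.
# The SR estimate is their pixelwise sum, so the conv stack only has to
# learn the detail that plain interpolation loses.
#
# Engine layout: a batch of feature maps lives in a single matrix with
# (H*W*B) rows (pixel-major, batch blocks) and one column per channel.
# Convolutions gather shifted pixel rows with precomputed index vectors
# (im2col) and reduce to one BLAS matrix product per layer; transposed
# convolutions use the polyphase (sub-kernel) decomposition, with
# replicate padding of their input so borders behave like the fixed
# resamplers in the degradation model.

#' Network topology configuration
#'
#' @param n_feature_convs Number of 3x3 convolutions in the residual
#'   branch (default 13).
#' @param channels Feature channels throughout the branch (default 64).
#' @param conv_kernel Convolution kernel side (default 3).
#' @param leaky_slope Negative-region slope of the leaky rectifier
#'   (default 0.2).
#' @param transpose_kernel Transposed-convolution kernel side (default 4);
#'   must be divisible by `upsample_stride` so every output phase receives
#'   the same number of taps (no checkerboard-prone geometry).
#' @param upsample_stride Stride of the transposed convolutions (default
#'   2); equals `scale` for this single-level x2 network.
#' @param scale Super-resolution factor (default 2).
#' @param use_image_branch Keep the learned-upsampler image branch
#'   (default `TRUE`); turning it off is the "no bottom transposed
#'   convolution" ablation, in which the residual-branch output is read as
#'   the full SR image.
#' @param init_seed Seed for weight initialization.
#' @return An object of class `network_config`.
#' @export
network_config <- function(n_feature_convs = 13L, channels = 64L,
                           conv_kernel = 3L, leaky_slope = 0.2,
                           transpose_kernel = 4L, upsample_stride = 2L,
                           scale = 2L, use_image_branch = TRUE,
                           init_seed = 0L) {
  n_feature_convs <- as.integer(n_feature_convs)
  channels <- as.integer(channels)
  conv_kernel <- as.integer(conv_kernel)
  transpose_kernel <- as.integer(transpose_kernel)
  upsample_stride <- as.integer(upsample_stride)
  scale <- as.integer(scale)
  if (n_feature_convs < 1L || channels < 1L)
    stop("need >= 1 feature conv and >= 1 channel", call. = FALSE)
  if (conv_kernel %% 2L != 1L)
    stop("conv_kernel must be odd (size-preserving zero padding)",
         call. = FALSE)
  if (transpose_kernel %% upsample_stride != 0L)
    stop("transpose_kernel must be divisible by upsample_stride",
         call. = FALSE)
  if (scale != upsample_stride)
    stop("scale must equal upsample_stride (single-level network)",
         call. = FALSE)
  if (upsample_stride != 2L || transpose_kernel != 4L)
    stop("only 4x4 stride-2 transposed convolutions are supported",
         call. = FALSE)
  structure(list(n_feature_convs = n_feature_convs, channels = channels,
                 conv_kernel = conv_kernel, leaky_slope = leaky_slope,
                 transpose_kernel = transpose_kernel,
                 upsample_stride = upsample_stride, scale = scale,
                 use_image_branch = isTRUE(use_image_branch),
                 init_seed = as.integer(init_seed)),
            class = "network_config")
}

# --- gather-index machinery --------------------------------------------

# Memo for index vectors, keyed by geometry.
.idx_memo <- new.env(parent = emptyenv())

memo_get <- function(key, build) {
  if (is.null(.idx_memo[[key]])) .idx_memo[[key]] <- build()
  .idx_memo[[key]]
}

# Conv gather plan for an H x W grid, batch B, k x k kernel, "same" zero
# padding. $idx: list over the k*k taps of integer vectors (length
# H*W*B), 0 marking out-of-bounds; $perm maps the internal
# (tap-major, channel-minor) column order onto R's flattening of a
# (k, k, C, Cout) weight array.
conv_plan <- function(H, W, B, k, C) {
  key <- paste("conv", H, W, B, k, C, sep = "_")
  memo_get(key, function() {
    pad <- (k - 1L) %/% 2L
    hw <- H * W
    hh <- rep.int(seq_len(H), W)
    ww <- rep(seq_len(W), each = H)
    boff <- rep((seq_len(B) - 1L) * hw, each = hw)
    idx <- vector("list", k * k)
    o <- 0L
    for (dj in seq_len(k)) for (di in seq_len(k)) {
      o <- o + 1L
      sh <- hh + di - 1L - pad
      sw <- ww + dj - 1L - pad
      base <- ifelse(sh < 1L | sh > H | sw < 1L | sw > W,
                     0L, (sw - 1L) * H + sh)
      idx[[o]] <- ifelse(rep.int(base, B) == 0L, 0L, rep.int(base, B) + boff)
    }
    # tap order in idx is di fastest then dj, matching weight flattening
    perm <- integer(k * k * C)
    for (o in seq_len(k * k)) for (c in seq_len(C))
      perm[(o - 1L) * C + c] <- (c - 1L) * k * k + o
    list(idx = idx, perm = perm)
  })
}

# Convolution via the compiled gather/GEMM primitives. The permuted
# weight matrix puts R's (k, k, C, Cout) flattening into the tap-major
# column order of the gathered im2col matrix; the input matrix itself is
# cached for the backward pass (gathers are recomputed there).
conv_forward <- function(X, w, b, H, W, B) {
  k <- dim(w)[1]; C <- dim(w)[3]
  plan <- conv_plan(H, W, B, k, C)
  wm <- matrix(w, k * k * C, dim(w)[4])[plan$perm, , drop = FALSE]
  list(out = gemm_gather(X, plan$idx, wm, b), X = X)
}

conv_backward <- function(dout, X, w, H, W, B, need_dx = TRUE) {
  k <- dim(w)[1]; C <- dim(w)[3]; cout <- dim(w)[4]
  plan <- conv_plan(H, W, B, k, C)
  wm <- matrix(w, k * k * C, cout)[plan$perm, , drop = FALSE]
  dwp <- crossprod_gather(X, plan$idx, dout)
  dwm <- matrix(0, k * k * C, cout)
  dwm[plan$perm, ] <- dwp
  db <- colSums(dout)
  dX <- if (need_dx) mm_scatter(dout, plan$idx, wm, H * W * B)
  list(dx = dX, dw = array(dwm, dim(w)), db = db)
}

# Transposed-conv gather plan: replicate-pad indices, per-phase tap
# gathers over the padded grid, and output interleaving indices.
tconv_plan <- function(H, W, B) {
  key <- paste("tconv", H, W, B, sep = "_")
  memo_get(key, function() {
    n1 <- H + 2L; n2 <- W + 2L
    hw <- H * W
    # replicate padding as a gather from the unpadded grid
    pi_ <- pmin(pmax(rep.int(seq_len(n1), n2) - 1L, 1L), H)
    pj <- pmin(pmax(rep(seq_len(n2), each = n1) - 1L, 1L), W)
    pidx <- (pj - 1L) * H + pi_
    pidxb <- rep.int(pidx, B) + rep((seq_len(B) - 1L) * hw, each = n1 * n2)
    mm <- rep.int(seq_len(H), W)
    ll <- rep(seq_len(W), each = H)
    boffp <- rep((seq_len(B) - 1L) * (n1 * n2), each = hw)
    boffo <- rep((seq_len(B) - 1L) * (4L * hw), each = hw)
    phases <- vector("list", 4L)
    for (pr in 0:1) for (pc in 0:1) {
      taps <- vector("list", 4L)
      t <- 0L
      for (db_ in 0:1) for (da in 0:1) {
        t <- t + 1L
        taps[[t]] <- rep.int((pc + ll + db_ - 1L) * n1 + (pr + mm + da),
                             B) + boffp
      }
      outpix <- (2L * ll - 2L + pc) * 2L * H + (2L * mm - 1L + pr)
      phases[[pr * 2L + pc + 1L]] <-
        list(taps = taps, out = rep.int(outpix, B) + boffo,
             pr = pr, pc = pc)
    }
    list(pidxb = pidxb, phases = phases)
  })
}

# Phase weight matrix (4*Cin x Cout) of the 4x4 stride-2 kernel for
# output phase (pr, pc); tap (da, db_) uses w[(4-pr)-2da, (4-pc)-2db_],
# taps ordered da fastest to match the plan's tap list.
phase_wm <- function(w, pr, pc) {
  cin <- dim(w)[3]; cout <- dim(w)[4]
  km <- matrix(0, 4L * cin, cout)
  t <- 0L
  for (db_ in 0:1) for (da in 0:1) {
    t <- t + 1L
    km[(t - 1L) * cin + seq_len(cin), ] <-
      matrix(w[4L - pr - 2L * da, 4L - pc - 2L * db_, , ], cin, cout)
  }
  km
}

tconv_forward <- function(X, w, b, H, W, B) {
  plan <- tconv_plan(H, W, B)
  Xp <- X[plan$pidxb, , drop = FALSE]
  out <- matrix(0, 4L * H * W * B, dim(w)[4])
  for (q in seq_len(4L)) {
    ph <- plan$phases[[q]]
    out[ph$out, ] <- gemm_gather(Xp, ph$taps, phase_wm(w, ph$pr, ph$pc), b)
  }
  list(out = out, Xp = Xp)
}

tconv_backward <- function(dout, cache, w, H, W, B) {
  cin <- dim(w)[3]; cout <- dim(w)[4]
  plan <- tconv_plan(H, W, B)
  n1 <- H + 2L; n2 <- W + 2L
  dw <- array(0, dim(w))
  db <- numeric(cout)
  dXp <- matrix(0, n1 * n2 * B, cin)
  Xp <- cache$Xp
  for (q in seq_len(4L)) {
    ph <- plan$phases[[q]]
    dm <- dout[ph$out, , drop = FALSE]
    db <- db + colSums(dm)
    wmq <- phase_wm(w, ph$pr, ph$pc)
    dkm <- crossprod_gather(Xp, ph$taps, dm)
    t <- 0L
    for (db_ in 0:1) for (da in 0:1) {
      t <- t + 1L
      ia <- 4L - ph$pr - 2L * da
      ib <- 4L - ph$pc - 2L * db_
      dw[ia, ib, , ] <- dkm[(t - 1L) * cin + seq_len(cin), ]
    }
    dXp <- dXp + mm_scatter(dm, ph$taps, wmq, n1 * n2 * B)
  }
  # fold replicate-padding gradients back onto their source pixels
  dX <- rowsum(dXp, plan$pidxb, reorder = TRUE)
  list(dx = dX, dw = dw, db = db)
}

# --- model construction -------------------------------------------------

# 1D bilinear tap vector of the 4-wide stride-2 kernel.
bilinear_taps4 <- function() c(0.25, 0.75, 0.75, 0.25)

#' Build a randomly initialized model
#'
#' Residual branch: one `1 -> channels` convolution, then
#' `n_feature_convs - 1` `channels -> channels` convolutions, each
#' followed by leaky rectification, closed by a `channels -> 1` transposed
#' convolution. Image branch (if enabled): one `1 -> 1` transposed
#' convolution. Convolutions get seeded He-style initialization scaled for
#' the leaky slope; the image-branch transposed convolution starts at the
#' bilinear upsampling kernel and the residual-branch one at a small
#' random scale, so the untrained network already behaves like a plain
#' interpolator plus a near-zero residual.
#'
#' @param config A [network_config()].
#' @return An object of class `model_state` with fields `config`,
#'   `weights` and `n_parameters`.
#' @export
build_network <- function(config = network_config()) {
  stopifnot(inherits(config, "network_config"))
  rng <- local_rng(config$init_seed)
  k <- config$conv_kernel
  ch <- config$channels
  slope <- config$leaky_slope
  he <- function(kh, kw, cin, cout, gain = 1) {
    sd <- gain * sqrt(2 / (1 + slope^2) / (kh * kw * cin))
    list(w = array(rng$rnorm(kh * kw * cin * cout, 0, sd),
                   c(kh, kw, cin, cout)),
         b = numeric(cout))
  }
  convs <- vector("list", config$n_feature_convs)
  convs[[1]] <- he(k, k, 1L, ch)
  for (l in seq_len(config$n_feature_convs - 1L) + 1L)
    convs[[l]] <- he(k, k, ch, ch)
  tk <- config$transpose_kernel
  tconv_res <- he(tk, tk, ch, 1L, gain = 0.1)
  weights <- list(convs = convs, tconv_res = tconv_res)
  if (config$use_image_branch) {
    taps <- bilinear_taps4()
    weights$tconv_img <- list(w = array(outer(taps, taps), c(tk, tk, 1L, 1L)),
                              b = 0)
  }
  model <- structure(list(config = config, weights = weights),
                     class = "model_state")
  model$n_parameters <- count_parameters(model)
  model
}

#' Number of trainable parameters
#'
#' Sum over layers of `kernel_h * kernel_w * in_ch * out_ch + out_ch`.
#'
#' @param model A `model_state`.
#' @return Integer count.
#' @export
count_parameters <- function(model) {
  n <- 0
  for (layer in c(model$weights$convs,
                  list(model$weights$tconv_res, model$weights$tconv_img))) {
    if (is.null(layer)) next
    n <- n + length(layer$w) + length(layer$b)
  }
  as.integer(n)
}

#' Layer census of a model
#'
#' @param model A `model_state`.
#' @return Named integer vector with counts of `conv` and
#'   `transposed_conv` layers.
#' @export
layer_census <- function(model) {
  c(conv = length(model$weights$convs),
    transposed_conv = 1L + as.integer(!is.null(model$weights$tconv_img)))
}

#' @export
print.model_state <- function(x, ...) {
  census <- layer_census(x)
  cat(sprintf(paste0("model_state: %d conv + %d transposed-conv layers, ",
                     "%d channels, %d parameters\n"),
              census["conv"], census["transposed_conv"],
              x$config$channels, x$n_parameters))
  invisible(x)
}

# --- forward / backward -------------------------------------------------

lrelu <- function(x, slope) pmax(x, 0) + slope * pmin(x, 0)

# Batch container: matrix (H*W*B) x 1 plus geometry.
as_input_batch <- function(imgs) {
  if (is.matrix(imgs)) imgs <- list(imgs)
  d <- dim(imgs[[1]])
  list(mat = matrix(unlist(imgs, use.names = FALSE), ncol = 1L),
       H = d[1], W = d[2], B = length(imgs))
}

batch_to_list <- function(bat, H = NULL, W = NULL) {
  if (is.null(H)) { H <- bat$H; W <- bat$W }
  B <- length(bat$mat) / (H * W)
  lapply(seq_len(B), function(b)
    matrix(bat$mat[(b - 1L) * H * W + seq_len(H * W)], H, W))
}

net_forward_batch <- function(model, x, cache = FALSE) {
  cfg <- model$config
  w <- model$weights
  H <- x$H; W <- x$W; B <- x$B
  act <- x$mat
  conv_inputs <- if (cache) vector("list", length(w$convs))
  acts <- if (cache) vector("list", length(w$convs) + 1L)
  if (cache) acts[[1]] <- act
  for (l in seq_along(w$convs)) {
    cf <- conv_forward(act, w$convs[[l]]$w, w$convs[[l]]$b, H, W, B)
    act <- lrelu(cf$out, cfg$leaky_slope)
    if (cache) {
      conv_inputs[[l]] <- cf$X
      acts[[l + 1L]] <- act
    }
  }
  tr <- tconv_forward(act, w$tconv_res$w, w$tconv_res$b, H, W, B)
  out <- tr$out
  ti <- NULL
  if (cfg$use_image_branch) {
    ti <- tconv_forward(x$mat, w$tconv_img$w, w$tconv_img$b, H, W, B)
    out <- tr$out + ti$out
  }
  res <- list(out = list(mat = out, H = 2L * H, W = 2L * W, B = B),
              residual = list(mat = tr$out, H = 2L * H, W = 2L * W, B = B),
              image = if (!is.null(ti))
                list(mat = ti$out, H = 2L * H, W = 2L * W, B = B))
  if (cache)
    res$cache <- list(acts = acts, conv_inputs = conv_inputs,
                      tconv_res = tr, tconv_img = ti, x = x)
  res
}

# dout: matrix (4*H*W*B) x 1, gradient w.r.t. the network output.
net_backward_batch <- function(model, fwd, dout) {
  cfg <- model$config
  w <- model$weights
  cache <- fwd$cache
  x <- cache$x
  H <- x$H; W <- x$W; B <- x$B
  grads <- list(convs = vector("list", length(w$convs)))
  if (cfg$use_image_branch) {
    gi <- tconv_backward(dout, cache$tconv_img, w$tconv_img$w, H, W, B)
    grads$tconv_img <- list(w = gi$dw, b = gi$db)
  }
  gr <- tconv_backward(dout, cache$tconv_res, w$tconv_res$w, H, W, B)
  grads$tconv_res <- list(w = gr$dw, b = gr$db)
  dact <- gr$dx
  for (l in rev(seq_along(w$convs))) {
    post <- cache$acts[[l + 1L]]
    dpre <- dact * ((post > 0) + cfg$leaky_slope * (post <= 0))
    cb <- conv_backward(dpre, cache$conv_inputs[[l]], w$convs[[l]]$w,
                        H, W, B, need_dx = l > 1L)
    grads$convs[[l]] <- list(w = cb$dw, b = cb$db)
    dact <- cb$dx
  }
  grads
}

#' Run the network on a low-resolution image
#'
#' @param model A `model_state`.
#' @param lr Numeric matrix (or list of equally sized matrices for a
#'   batch).
#' @param components If `TRUE`, return the branch decomposition
#'   (`out`, `residual`, `image`) instead of just the output.
#' @return Matrix of size `scale * dim(lr)` (list thereof for a batch),
#'   or the component list when `components = TRUE`.
#' @export
net_forward <- function(model, lr, components = FALSE) {
  single <- is.matrix(lr)
  fwd <- net_forward_batch(model, as_input_batch(lr), cache = FALSE)
  take <- function(bat) {
    if (is.null(bat)) return(NULL)
    l <- batch_to_list(bat)
    if (single) l[[1]] else l
  }
  if (components)
    list(out = take(fwd$out), residual = take(fwd$residual),
         image = take(fwd$image))
  else take(fwd$out)
}

#' Super-resolve a slice with a trained model
#'
#' Forward pass followed by clipping to `[0, 1]`.
#'
#' @param model A `model_state`.
#' @param lr Low-resolution slice (numeric matrix in `[0, 1]`).
#' @return Super-resolved slice, `scale` times larger, clipped to
#'   `[0, 1]`.
#' @export
predict_slice <- function(model, lr) {
  check_image(lr, "lr")
  clip01(net_forward(model, lr))
}
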