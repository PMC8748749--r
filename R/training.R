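# Training recipe: SGD with classical momentum and L2 weight decay, a
# halving learning-rate schedule, random patch sampling, the 7:1:1:1
# dataset split, and the ablation runner.

#' Training configuration
#'
#' @param initial_lr Initial learning rate (default `1e-5`, the published
#'   value for warm-started training; desk-scale training from random
#'   initialization needs a larger rate — see [train_network()]).
#' @param lr_halving_period Epochs between halvings of the learning rate
#'   (default 50).
#' @param momentum Classical momentum coefficient (default 0.9).
#' @param weight_decay L2 penalty coefficient added to the gradient
#'   (default `1e-4`).
#' @param clip_grad_norm Global L2 gradient-norm ceiling; gradients with
#'   larger norm are rescaled to it before the update (default 10).
#'   `Inf` disables clipping. The gradient-difference term is a per-image
#'   sum, so early-training gradients can be orders of magnitude larger
#'   than late ones; clipping makes one learning rate serve both regimes.
#' @param batch_size Patches per SGD step (default 64).
#' @param patch_hr HR patch side in pixels (even, default 128).
#' @param epochs Number of training epochs.
#' @param steps_per_epoch SGD steps per epoch (default 1: an epoch is one
#'   step on `batch_size` freshly sampled patches).
#' @param seed Seed controlling patch sampling (and, combined with the
#'   network's `init_seed`, the whole run).
#' @param loss A [loss_config()].
#' @param network A [network_config()].
#' @return An object of class `train_config`.
#' @export
train_config <- function(initial_lr = 1e-5, lr_halving_period = 50L,
                         momentum = 0.9, weight_decay = 1e-4,
                         clip_grad_norm = 10, batch_size = 64L,
                         patch_hr = 128L, epochs = 10L,
                         steps_per_epoch = 1L, seed = 0L,
                         loss = loss_config(), network = network_config()) {
  if (initial_lr <= 0 || lr_halving_period < 1L)
    stop("initial_lr must be > 0, lr_halving_period >= 1", call. = FALSE)
  if (momentum < 0 || momentum >= 1) stop("momentum must be in [0, 1)",
                                          call. = FALSE)
  if (weight_decay < 0) stop("weight_decay must be >= 0", call. = FALSE)
  if (clip_grad_norm <= 0) stop("clip_grad_norm must be > 0", call. = FALSE)
  if (batch_size < 1L) stop("batch_size must be >= 1", call. = FALSE)
  if (patch_hr %% 2L != 0L) stop("patch_hr must be even", call. = FALSE)
  if (epochs < 1L || steps_per_epoch < 1L)
    stop("epochs and steps_per_epoch must be >= 1", call. = FALSE)
  structure(list(initial_lr = initial_lr,
                 lr_halving_period = as.integer(lr_halving_period),
                 momentum = momentum, weight_decay = weight_decay,
                 clip_grad_norm = clip_grad_norm,
                 batch_size = as.integer(batch_size),
                 patch_hr = as.integer(patch_hr),
                 epochs = as.integer(epochs),
                 steps_per_epoch = as.integer(steps_per_epoch),
                 seed = as.integer(seed), loss = loss, network = network),
            class = "train_config")
}

#' Learning-rate schedule
#'
#' `initial_lr * 2^(-floor(epoch / lr_halving_period))`: the rate is
#' halved every `lr_halving_period` epochs (0-based epoch index).
#'
#' @param epoch Epoch index (>= 0).
#' @param cfg A [train_config()].
#' @return The learning rate for that epoch.
#' @export
lr_schedule <- function(epoch, cfg) {
  if (any(epoch < 0)) stop("epoch must be >= 0", call. = FALSE)
  cfg$initial_lr * 2^(-(epoch %/% cfg$lr_halving_period))
}

#' Split a dataset 7:1:1:1 (or by other 4-way ratios)
#'
#' The first share gets `round(n * r1 / sum(ratios))` items; the
#' remainder is divided as evenly as possible among the other three
#' shares, ties resolved toward the earlier share. Membership is a
#' seeded random shuffle; sizes depend only on `(n, ratios)`.
#'
#' @param items A list (or vector) of items.
#' @param ratios Positive ratios of length 4 (default `c(7, 1, 1, 1)`:
#'   training, weight tuning, hyper-parameter tuning, testing).
#' @param seed Integer shuffle seed.
#' @return Named list `train`, `tune_weights`, `tune_hyper`, `test` of
#'   disjoint subsets covering `items`.
#' @export
split_dataset <- function(items, ratios = c(7, 1, 1, 1), seed = 0L) {
  if (length(ratios) != 4L || any(ratios <= 0))
    stop("ratios must be 4 positive numbers", call. = FALSE)
  n <- length(items)
  if (n < 4L) stop("need at least 4 items to split", call. = FALSE)
  first <- round(n * ratios[1] / sum(ratios))
  rest <- n - first
  base <- rest %/% 3L
  extra <- rest %% 3L
  sizes <- c(first, base + as.integer(seq_len(3L) <= extra))
  if (any(sizes < 1L)) stop("too few items for this split", call. = FALSE)
  rng <- local_rng(seed)
  ord <- rng$sample_int(n, n)
  bounds <- cumsum(c(0L, sizes))
  pick <- function(k) {
    idx <- ord[(bounds[k] + 1L):bounds[k + 1L]]
    if (is.list(items)) items[idx] else items[idx]
  }
  list(train = pick(1L), tune_weights = pick(2L), tune_hyper = pick(3L),
       test = pick(4L))
}

# --- optimizer ----------------------------------------------------------

# Map over (weights, ...) layer structures.
map_weights <- function(f, ...) {
  structs <- list(...)
  out <- structs[[1]]
  out$convs <- lapply(seq_along(out$convs), function(l) {
    parts <- lapply(structs, function(s) s$convs[[l]])
    list(w = do.call(f, lapply(parts, `[[`, "w")),
         b = do.call(f, lapply(parts, `[[`, "b")))
  })
  for (nm in c("tconv_res", "tconv_img")) {
    if (is.null(out[[nm]])) next
    parts <- lapply(structs, function(s) s[[nm]])
    out[[nm]] <- list(w = do.call(f, lapply(parts, `[[`, "w")),
                      b = do.call(f, lapply(parts, `[[`, "b")))
  }
  out
}

zero_like <- function(weights) map_weights(function(w) w * 0, weights)

grad_norm <- function(grads) {
  sq <- 0
  for (layer in c(grads$convs, list(grads$tconv_res, grads$tconv_img))) {
    if (is.null(layer)) next
    sq <- sq + sum(layer$w^2) + sum(layer$b^2)
  }
  sqrt(sq)
}

clip_gradients <- function(grads, max_norm) {
  if (!is.finite(max_norm)) return(grads)
  gn <- grad_norm(grads)
  if (gn <= max_norm) return(grads)
  map_weights(function(g) g * (max_norm / gn), grads)
}

# One SGD step with classical momentum and L2 weight decay:
#   v <- momentum * v - lr * (g + wd * w);  w <- w + v
sgd_step <- function(weights, grads, velocity, lr, momentum, wd) {
  velocity <- map_weights(function(v, w, g) momentum * v - lr * (g + wd * w),
                          velocity, weights, grads)
  weights <- map_weights(`+`, weights, velocity)
  list(weights = weights, velocity = velocity)
}

# --- training loop ------------------------------------------------------

#' Train the super-resolution network
#'
#' Each epoch performs `steps_per_epoch` SGD steps; each step samples
#' `batch_size` HR patches (with their co-located LR patches) from
#' randomly chosen training images, runs the network on the LR patches,
#' and descends the combined Charbonnier + GDL loss with momentum and L2
#' weight decay at the scheduled learning rate. Fully reproducible given
#' `cfg$seed` and `cfg$network$init_seed`.
#'
#' @param dataset Non-empty list of HR slices (numeric matrices in
#'   `[0, 1]`, at least `patch_hr` on each side).
#' @param cfg A [train_config()].
#' @param val_dataset Optional list of HR slices for validation PSNR.
#' @param val_every Record validation PSNR every this many epochs
#'   (default 10; also recorded at the final epoch).
#' @param verbose Print one log line per epoch.
#' @return List with `model` (the trained `model_state`) and `history`
#'   (data frame: epoch, lr, loss, val_psnr).
#' @export
train_network <- function(dataset, cfg = train_config(),
                          val_dataset = NULL, val_every = 10L,
                          verbose = FALSE) {
  if (!length(dataset)) stop("dataset is empty", call. = FALSE)
  scale <- cfg$network$scale
  pairs <- lapply(dataset, make_pair, scale = scale)
  small <- vapply(pairs, function(p)
    nrow(p$hr) < cfg$patch_hr || ncol(p$hr) < cfg$patch_hr, TRUE)
  if (all(small))
    stop("no training image is large enough for patch_hr", call. = FALSE)
  pairs <- pairs[!small]
  model <- build_network(cfg$network)
  velocity <- zero_like(model$weights)
  rng <- local_rng(cfg$seed)
  history <- data.frame(epoch = integer(), lr = numeric(),
                        loss = numeric(), val_psnr = numeric())
  val_psnr <- function() {
    if (is.null(val_dataset)) return(NA_real_)
    mean(vapply(val_dataset, function(hr) {
      p <- make_pair(hr, scale = scale)
      psnr(predict_slice(model, p$lr), p$hr)
    }, 0))
  }
  for (epoch in seq_len(cfg$epochs) - 1L) {
    lr_now <- lr_schedule(epoch, cfg)
    epoch_loss <- 0
    for (step in seq_len(cfg$steps_per_epoch)) {
      img_idx <- rng$sample_int(length(pairs), cfg$batch_size,
                                replace = TRUE)
      batch_seed <- derive_seed(cfg$seed, epoch * 7919 + step)
      hr_patches <- vector("list", cfg$batch_size)
      lr_patches <- vector("list", cfg$batch_size)
      for (k in seq_len(cfg$batch_size)) {
        pb <- sample_patches(pairs[[img_idx[k]]], cfg$patch_hr, 1L,
                             seed = derive_seed(batch_seed, k))
        hr_patches[[k]] <- pb$hr_patches[[1]]
        lr_patches[[k]] <- pb$lr_patches[[1]]
      }
      xb <- as_input_batch(lr_patches)
      fwd <- net_forward_batch(model, xb, cache = TRUE)
      pred <- batch_to_list(fwd$out)
      lg <- combined_loss(pred, hr_patches, cfg$loss, grad = TRUE)
      grads <- net_backward_batch(model, fwd, as_input_batch(lg$grad)$mat)
      grads <- clip_gradients(grads, cfg$clip_grad_norm)
      upd <- sgd_step(model$weights, grads, velocity, lr_now,
                      cfg$momentum, cfg$weight_decay)
      model$weights <- upd$weights
      velocity <- upd$velocity
      epoch_loss <- epoch_loss + lg$value
    }
    epoch_loss <- epoch_loss / cfg$steps_per_epoch
    vp <- if (!is.null(val_dataset) &&
              (epoch %% val_every == 0L || epoch == cfg$epochs - 1L))
      val_psnr() else NA_real_
    history <- rbind(history,
                     data.frame(epoch = epoch, lr = lr_now,
                                loss = epoch_loss, val_psnr = vp))
    if (verbose)
      message(sprintf("epoch %3d  lr %.3g  loss %.5f  val PSNR %s",
                      epoch, lr_now, epoch_loss,
                      if (is.na(vp)) "-" else sprintf("%.2f dB", vp)))
  }
  list(model = model, history = history)
}

#' Reference desk-scale smoke experiment configuration
#'
#' The package's canonical single-CPU experiment: 20 phantoms of 128x128
#' for training, 5 held-out phantoms for testing, 30 epochs of four
#' batches of eight 64x64 HR patches (120 SGD steps), the default
#' 13-conv/64-channel network, and a learning rate of 3e-3 suited to
#' training from random initialization under gradient clipping. Used by
#' the training demonstrations and the acceptance run.
#'
#' @param seed Integer seed; controls initialization, patch sampling and
#'   the phantom draws.
#' @param epochs Training epochs (default 30).
#' @return List with `phantom` (a [phantom_spec()]), `train` (a
#'   [train_config()]), `n_train`, `n_test`, and `test_seed` (a seed for
#'   the held-out phantoms, derived disjointly from `seed`).
#' @export
smoke_config <- function(seed = 0L, epochs = 30L) {
  list(phantom = phantom_spec(128, 128),
       n_train = 20L, n_test = 5L,
       test_seed = derive_seed(seed, 424243L),
       train = train_config(initial_lr = 3e-3, epochs = epochs,
                            batch_size = 8L, patch_hr = 64L,
                            steps_per_epoch = 4L, seed = seed,
                            network = network_config(init_seed = seed)))
}

#' Run an ablation comparison
#'
#' Trains one model per variant with identical seeds and data, then
#' scores per-subject PSNR on the test slices, yielding a
#' variant-by-subject table (the with/without-GDL and with/without
#' image-branch comparisons).
#'
#' @param dataset Training slices (list of matrices).
#' @param variants Named list; each element is a list of [train_config()]
#'   field overrides (possibly nested, e.g.
#'   `list(loss = list(gdl_weight = 0))`), applied on top of `cfg`.
#' @param cfg Baseline [train_config()].
#' @param test_dataset HR test slices (the "subjects").
#' @return An object of class `ablation_report`: matrix `psnr`
#'   (variant x subject) plus per-variant means.
#' @export
run_ablation <- function(dataset, variants, cfg, test_dataset) {
  if (length(variants) < 2L) stop("need >= 2 variants", call. = FALSE)
  if (is.null(names(variants)) || any(!nzchar(names(variants))))
    stop("variants must be named", call. = FALSE)
  apply_delta <- function(base, delta) {
    for (nm in names(delta)) {
      if (is.list(delta[[nm]]) && !is.null(base[[nm]]) &&
          is.list(base[[nm]])) {
        base[[nm]] <- apply_delta(base[[nm]], delta[[nm]])
      } else base[[nm]] <- delta[[nm]]
    }
    base
  }
  psnr_tab <- matrix(NA_real_, length(variants), length(test_dataset),
                     dimnames = list(names(variants),
                                     sprintf("subject%02d",
                                             seq_along(test_dataset))))
  for (v in seq_along(variants)) {
    vcfg <- apply_delta(cfg, variants[[v]])
    class(vcfg) <- "train_config"
    class(vcfg$network) <- "network_config"
    class(vcfg$loss) <- "loss_config"
    fit <- train_network(dataset, vcfg)
    for (s in seq_along(test_dataset)) {
      p <- make_pair(test_dataset[[s]], scale = vcfg$network$scale)
      psnr_tab[v, s] <- psnr(predict_slice(fit$model, p$lr), p$hr)
    }
  }
  structure(list(psnr = psnr_tab, mean = rowMeans(psnr_tab)),
            class = "ablation_report")
}

#' @export
print.ablation_report <- function(x, ...) {
  cat("ablation report (PSNR, dB):\n")
  print(round(cbind(x$psnr, mean = x$mean), 2))
  invisible(x)
}
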