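test_that("default config gives the canonical layer census", {
  model <- build_network(network_config())
  census <- layer_census(model)
  expect_equal(census[["conv"]], 13)
  expect_equal(census[["transposed_conv"]], 2)
  no_branch <- build_network(network_config(use_image_branch = FALSE))
  expect_equal(layer_census(no_branch)[["transposed_conv"]], 1)
  expect_equal(layer_census(no_branch)[["conv"]], 13)
})

test_that("parameter count equals the closed-form layer-wise sum", {
  model <- build_network(network_config())
  # 3x3 convs: 1->64, then 12 of 64->64; tconvs 4x4: 64->1 and 1->1
  expected <- (3 * 3 * 1 * 64 + 64) +
    12 * (3 * 3 * 64 * 64 + 64) +
    (4 * 4 * 64 * 1 + 1) +
    (4 * 4 * 1 * 1 + 1)
  expect_equal(model$n_parameters, expected)
  small <- build_network(network_config(n_feature_convs = 3, channels = 8))
  expect_equal(small$n_parameters,
               (9 * 1 * 8 + 8) + 2 * (9 * 8 * 8 + 8) +
                 (16 * 8 + 1) + (16 + 1))
})

test_that("forward output is the exact sum of the two branches", {
  model <- build_network(network_config(n_feature_convs = 4, channels = 8,
                                        init_seed = 3))
  lr <- rand_img(16, 16, 1)
  parts <- net_forward(model, lr, components = TRUE)
  expect_identical(parts$out, parts$residual + parts$image)
  # rearranged form only to rounding (floating addition is not invertible)
  expect_equal(parts$out - parts$image, parts$residual, tolerance = 1e-12)
})

test_that("zero weights produce the all-zero output", {
  model <- build_network(network_config(n_feature_convs = 3, channels = 4))
  model$weights$convs <- lapply(model$weights$convs, function(l)
    list(w = l$w * 0, b = l$b * 0))
  model$weights$tconv_res <- list(w = model$weights$tconv_res$w * 0, b = 0)
  model$weights$tconv_img <- list(w = model$weights$tconv_img$w * 0, b = 0)
  out <- net_forward(model, rand_img(12, 12, 2))
  expect_identical(out, matrix(0, 24, 24))
})

test_that("the x2 shape law holds across input sizes", {
  model <- build_network(network_config(n_feature_convs = 2, channels = 4))
  for (n in c(32, 48, 77, 128)) {
    out <- net_forward(model, rand_img(n, n, n))
    expect_equal(dim(out), c(2 * n, 2 * n))
  }
  out <- net_forward(model, rand_img(40, 64, 9))
  expect_equal(dim(out), c(80, 128))
})

test_that("the transposed convolution matches a brute-force scatter", {
  # direct accumulation of x[i] * w[k] at output 2*i + k - 1 (0-based),
  # on a replicate-padded input with a 2-pixel output crop
  bf_tconv <- function(x, w, b) {
    H <- nrow(x); W <- ncol(x)
    xp <- x[c(1, 1:H, H), c(1, 1:W, W)]
    out <- matrix(0, 2 * (H + 2), 2 * (W + 2))
    for (i in seq_len(H + 2)) for (j in seq_len(W + 2)) {
      for (a in 1:4) for (bb in 1:4) {
        o1 <- 2 * (i - 1) + a - 1
        o2 <- 2 * (j - 1) + bb - 1
        if (o1 >= 1 && o1 <= 2 * (H + 2) && o2 >= 1 && o2 <= 2 * (W + 2))
          out[o1, o2] <- out[o1, o2] + xp[i, j] * w[a, bb]
      }
    }
    out[3:(2 * H + 2), 3:(2 * W + 2)] + b
  }
  set.seed(21)
  x <- matrix(rnorm(7 * 6), 7, 6)
  w <- array(rnorm(16), c(4, 4, 1, 1))
  xb <- mrisr:::as_input_batch(x)
  got <- matrix(mrisr:::tconv_forward(xb$mat, w, 0.2, 7, 6, 1)$out, 14, 12)
  # engine arithmetic is float32
  expect_equal(got, bf_tconv(x, w[, , 1, 1], 0.2), tolerance = 1e-5)
})

test_that("the zero-padded convolution matches a brute-force loop", {
  set.seed(41)
  x <- matrix(rnorm(9 * 8), 9, 8)
  w <- array(rnorm(9), c(3, 3, 1, 1))
  b <- 0.1
  xb <- mrisr:::as_input_batch(x)
  got <- matrix(mrisr:::conv_forward(xb$mat, w, b, 9, 8, 1)$out, 9, 8)
  ref <- matrix(b, 9, 8)
  for (i in 1:9) for (j in 1:8) for (a in 1:3) for (bb in 1:3) {
    si <- i + a - 2; sj <- j + bb - 2
    if (si >= 1 && si <= 9 && sj >= 1 && sj <= 8)
      ref[i, j] <- ref[i, j] + x[si, sj] * w[a, bb, 1, 1]
  }
  expect_equal(got, ref, tolerance = 1e-6)
})

test_that("network weight gradients agree with finite differences", {
  set.seed(17)
  model <- build_network(network_config(n_feature_convs = 3, channels = 4,
                                        init_seed = 2))
  lrs <- list(matrix(runif(64), 8, 8))
  hrs <- list(upsample_bicubic(lrs[[1]], 2) +
                0.05 * matrix(rnorm(256), 16, 16))
  xb <- mrisr:::as_input_batch(lrs)
  fwd <- mrisr:::net_forward_batch(model, xb, cache = TRUE)
  lg <- combined_loss(mrisr:::batch_to_list(fwd$out), hrs,
                      loss_config(), grad = TRUE)
  grads <- mrisr:::net_backward_batch(model, fwd,
                                      mrisr:::as_input_batch(lg$grad)$mat)
  loss_at <- function() {
    f <- mrisr:::net_forward_batch(model, xb)
    combined_loss(mrisr:::batch_to_list(f$out), hrs)
  }
  eps <- 1e-3
  probes <- list(list(c("convs", 1), 2), list(c("convs", 3), 5),
                 list("tconv_res", 5), list("tconv_img", 9))
  for (pr in probes) {
    path <- pr[[1]]; idx <- pr[[2]]
    get_w <- function() if (length(path) == 2)
      model$weights[[path[1]]][[as.integer(path[2])]]$w[idx]
    else model$weights[[path[1]]]$w[idx]
    set_w <- function(v) if (length(path) == 2)
      model$weights[[path[1]]][[as.integer(path[2])]]$w[idx] <<- v
    else model$weights[[path[1]]]$w[idx] <<- v
    w0 <- get_w()
    set_w(w0 + eps); f1 <- loss_at()
    set_w(w0 - eps); f2 <- loss_at()
    set_w(w0)
    fd <- (f1 - f2) / (2 * eps)
    ana <- if (length(path) == 2)
      grads$convs[[as.integer(path[2])]]$w[idx]
    else grads[[path[1]]]$w[idx]
    # the float32 forward puts ~1e-3 absolute noise on fd at this eps;
    # the check guards sign/scale/indexing, not ulp-level agreement
    expect_lt(abs(fd - ana) / max(abs(fd), 0.1), 0.03)
  }
})

test_that("prediction clips, is deterministic and finite when untrained", {
  model <- build_network(network_config(n_feature_convs = 3, channels = 4,
                                        init_seed = 5))
  lr <- rand_img(64, 64, 6)
  out1 <- predict_slice(model, lr)
  out2 <- predict_slice(model, lr)
  expect_identical(out1, out2)
  expect_true(all(is.finite(out1)))
  expect_gte(min(out1), 0)
  expect_lte(max(out1), 1)
  # force a raw value above 1 and check the clip
  model$weights$tconv_img$b <- 5
  expect_equal(max(predict_slice(model, lr)), 1)
})

test_that("interior output shifts by 2 when the input shifts by 1", {
  model <- build_network(network_config(n_feature_convs = 3, channels = 4,
                                        init_seed = 8))
  set.seed(31)
  base <- matrix(runif(48 * 48), 48, 48)
  shifted <- base[c(2:48, 48), ]        # shift up by one row
  out_a <- net_forward(model, base)
  out_b <- net_forward(model, shifted)
  # receptive field radius: 3 convs of 3x3 => 3 at LR, x2 at output, plus
  # the tconv support; compare deep interior rows only
  m <- 20
  interior <- (2 * m + 1):(96 - 2 * m)
  expect_equal(out_b[interior, 20:76], out_a[interior + 2, 20:76],
               tolerance = 1e-5)
})

test_that("invalid geometries are rejected", {
  expect_error(network_config(transpose_kernel = 5), "divisible")
  expect_error(network_config(scale = 4), "scale")
  expect_error(network_config(conv_kernel = 4), "odd")
})
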