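test_that("learning-rate schedule halves at the period boundaries", {
  cfg <- train_config(initial_lr = 1e-5, lr_halving_period = 50)
  expect_equal(lr_schedule(0, cfg), 1e-5)
  expect_equal(lr_schedule(49, cfg), 1e-5)
  expect_equal(lr_schedule(50, cfg), 5e-6)
  expect_equal(lr_schedule(100, cfg), 2.5e-6)
  # non-increasing over epochs
  expect_true(all(diff(lr_schedule(0:300, cfg)) <= 0))
})

test_that("the 7:1:1:1 split reproduces the published partition sizes", {
  items <- as.list(seq_len(1921))
  sp <- split_dataset(items, c(7, 1, 1, 1), seed = 0)
  expect_equal(lengths(sp)[["train"]], 1345)
  expect_equal(lengths(sp)[["tune_weights"]], 192)
  expect_equal(lengths(sp)[["tune_hyper"]], 192)
  expect_equal(lengths(sp)[["test"]], 192)
  sp10 <- split_dataset(as.list(1:10), c(7, 1, 1, 1), seed = 1)
  expect_equal(unname(lengths(sp10)), c(7, 1, 1, 1))
})

test_that("the split is a disjoint cover with seed-dependent membership", {
  items <- as.list(1:37)
  sp <- split_dataset(items, seed = 3)
  all_items <- unlist(sp)
  expect_setequal(all_items, 1:37)
  expect_equal(length(all_items), 37)  # disjoint: no duplicates
  sp2 <- split_dataset(items, seed = 3)
  expect_identical(sp, sp2)
  sp3 <- split_dataset(items, seed = 4)
  expect_false(identical(sp, sp3))
  expect_equal(lengths(sp3), lengths(sp))  # sizes depend only on n
})

test_that("weight decay shrinks parameters under zero loss gradient", {
  model <- build_network(network_config(n_feature_convs = 2, channels = 4,
                                        init_seed = 1))
  zero_g <- mrisr:::zero_like(model$weights)
  v <- mrisr:::zero_like(model$weights)
  norm_of <- function(w) sqrt(sum(unlist(lapply(
    c(w$convs, list(w$tconv_res, w$tconv_img)),
    function(l) sum(l$w^2)))))
  n0 <- norm_of(model$weights)
  upd <- mrisr:::sgd_step(model$weights, zero_g, v, lr = 0.5,
                          momentum = 0, wd = 0.1)
  n1 <- norm_of(upd$weights)
  upd2 <- mrisr:::sgd_step(upd$weights, zero_g, upd$velocity, lr = 0.5,
                           momentum = 0, wd = 0.1)
  expect_lt(n1, n0)
  expect_lt(norm_of(upd2$weights), n1)
})

test_that("short training runs are reproducible and book-kept", {
  imgs <- generate_dataset(4, phantom_spec(64, 64), seed = 2)
  cfg <- train_config(initial_lr = 5e-3, epochs = 3, batch_size = 2,
                      patch_hr = 32, seed = 9,
                      network = network_config(n_feature_convs = 3,
                                               channels = 8,
                                               init_seed = 9))
  fit1 <- train_network(imgs, cfg)
  fit2 <- train_network(imgs, cfg)
  expect_equal(nrow(fit1$history), 3)
  expect_identical(fit1$history$loss, fit2$history$loss)
  expect_identical(fit1$model$weights, fit2$model$weights)
  expect_true(all(is.finite(fit1$history$loss)))
})

test_that("ablation rows are per-variant and deterministic", {
  imgs <- generate_dataset(4, phantom_spec(64, 64), seed = 5)
  test_imgs <- generate_dataset(2, phantom_spec(64, 64), seed = 99)
  cfg <- train_config(initial_lr = 5e-3, epochs = 2, batch_size = 2,
                      patch_hr = 32, seed = 1,
                      network = network_config(n_feature_convs = 2,
                                               channels = 4,
                                               init_seed = 1))
  rep <- run_ablation(imgs,
                      list(baseline = list(),
                           same_as_baseline = list(),
                           without_gdl = list(loss = list(gdl_weight = 0))),
                      cfg, test_imgs)
  expect_equal(dim(rep$psnr), c(3, 2))
  expect_identical(rep$psnr["baseline", ], rep$psnr["same_as_baseline", ])
  expect_error(run_ablation(imgs, list(a = list()), cfg, test_imgs),
               ">= 2 variants")
})

test_that("degenerate training inputs are rejected", {
  expect_error(train_network(list(), train_config()), "empty")
  small <- list(matrix(0.5, 16, 16))
  expect_error(train_network(small, train_config(patch_hr = 64)),
               "large enough")
  expect_error(train_config(momentum = 1), "momentum")
  expect_error(train_config(patch_hr = 63), "even")
})
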