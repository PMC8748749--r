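test_that("NIfTI round trip preserves phantom slices", {
  slices <- generate_dataset(10, phantom_spec(64, 64), seed = 1)
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_slices_nifti(slices, path)
  back <- load_volume_slices(path, axis = 3)
  expect_length(back, 10)
  expect_true(all(vapply(back, function(s) all(dim(s) == c(64, 64)), TRUE)))
  for (k in c(1, 5, 10))
    expect_equal(back[[k]], slices[[k]], tolerance = 1e-6)
  expect_true(all(vapply(back, function(s) min(s) >= 0 && max(s) <= 1,
                         TRUE)))
})

test_that("slicing respects the chosen axis and blank-slice dropping", {
  arr <- array(runif(24 * 20 * 6), c(24, 20, 6))
  arr[, , 4] <- 0.5  # constant slice
  path <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  s3 <- load_volume_slices(path, axis = 3)
  expect_length(s3, 6)
  expect_equal(dim(s3[[1]]), c(24, 20))
  s1 <- load_volume_slices(path, axis = 1)
  expect_length(s1, 24)
  expect_equal(dim(s1[[1]]), c(20, 6))
  dropped <- load_volume_slices(path, axis = 3, drop_blank = TRUE)
  expect_length(dropped, 5)
  expect_error(load_volume_slices("no/such/file.nii"), "no such file")
  expect_error(load_volume_slices(withr::local_tempfile(fileext = ".txt",
                                                        lines = "x")),
               "unsupported format")
})

test_that("the identity oracle method scores perfectly", {
  slices <- generate_dataset(3, phantom_spec(64, 64), seed = 7)
  # degradation happens inside the harness, so wrap upsampling that
  # returns the exact HR: cheat by closing over the slices
  k <- 0
  oracle <- function(lr, scale) {
    k <<- k + 1
    make_pair(slices[[k]], scale)$hr
  }
  report <- evaluate_methods(slices, list(oracle = oracle), scale = 2)
  expect_true(all(report$per_slice$psnr == Inf))
  expect_true(all(abs(report$per_slice$ssim - 1) < 1e-12))
})

test_that("report structure and the bicubic cross-check agree", {
  slices <- generate_dataset(4, phantom_spec(64, 64), seed = 3)
  methods <- list(bicubic = sr_method("bicubic"),
                  nearest = sr_method("nearest"))
  report <- evaluate_methods(slices, methods, scale = 2)
  expect_equal(nrow(report$summary), 2 * 2)  # methods x metrics
  expect_setequal(unique(report$summary$method), names(methods))
  direct <- mean(sapply(slices, function(hr) {
    p <- make_pair(hr, 2)
    psnr(upsample_bicubic(p$lr, 2), p$hr)
  }))
  got <- report$summary[report$summary$method == "bicubic" &
                        report$summary$metric == "psnr", "mean"]
  expect_equal(got, direct, tolerance = 1e-10)
})

test_that("a failing method yields NA cells but the report survives", {
  slices <- generate_dataset(2, phantom_spec(64, 64), seed = 4)
  methods <- list(bicubic = sr_method("bicubic"),
                  broken = function(lr, scale) stop("boom"))
  expect_warning(evaluate_methods(slices[1], methods), "boom")
  report <- suppressWarnings(evaluate_methods(slices, methods))
  expect_true(all(is.na(
    report$per_slice$psnr[report$per_slice$method == "broken"])))
  expect_true(all(is.finite(
    report$per_slice$psnr[report$per_slice$method == "bicubic"])))
})

test_that("error maps are exact absolute differences", {
  hr <- generate_phantom(phantom_spec(64, 64), seed = 2)
  sr <- clip01_test <- pmin(pmax(hr + 0.05 * rand_img(64, 64, 5) - 0.025,
                                 0), 1)
  em <- error_map(sr, hr)
  expect_identical(em, abs(sr - hr))
  expect_true(all(em >= 0))
  expect_equal(which.max(em), which.max(abs(sr - hr)))
  expect_identical(error_map(hr, hr), matrix(0, 64, 64))
  expect_error(error_map(hr[1:10, ], hr), "shape")
})

test_that("CSV reports round-trip to the same numbers", {
  slices <- generate_dataset(3, phantom_spec(64, 64), seed = 8)
  report <- evaluate_methods(slices, list(bicubic = sr_method("bicubic")))
  path <- withr::local_tempfile(fileext = ".csv")
  write_report_csv(report, path)
  back <- read.csv(path)
  expect_equal(back$mean, report$summary$mean, tolerance = 1e-12)
  expect_equal(back$sd, report$summary$sd, tolerance = 1e-12)
})

test_that("per-subject aggregation averages slices before the summary", {
  slices <- generate_dataset(6, phantom_spec(64, 64), seed = 9)
  subjects <- c(1, 1, 1, 2, 2, 2)
  report <- evaluate_methods(slices, list(bicubic = sr_method("bicubic")),
                             subjects = subjects)
  expect_equal(nrow(report$per_subject), 2)
  manual <- tapply(report$per_slice$psnr, report$per_slice$subject, mean)
  expect_equal(sort(report$per_subject$psnr), sort(as.vector(manual)))
  expect_equal(report$summary$n[1], 2)
})
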