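# Method comparison harness: degrade, reconstruct, score, aggregate.

#' Extract normalized 2D slices from a volume or image directory
#'
#' Reads a NIfTI volume (`.nii` / `.nii.gz`) or a directory of PNG
#' slices and returns ordered 2D slices along the chosen axis.
#' Intensities are min-max normalized to `[0, 1]` per volume; volumes
#' whose values already lie in `[0, 1]` are treated as normalized and
#' passed through unchanged.
#'
#' @param path NIfTI file or directory of PNG files.
#' @param axis Slicing axis for volumes, 1-3 (default 3, the last axis).
#' @param drop_blank Drop zero-variance slices (default `FALSE`).
#' @return List of numeric matrices in `[0, 1]`.
#' @export
load_volume_slices <- function(path, axis = 3L, drop_blank = FALSE) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (!length(files))
      stop(sprintf("no PNG slices found in directory '%s'", path),
           call. = FALSE)
    slices <- lapply(files, read_slice_png)
  } else {
    if (!file.exists(path))
      stop(sprintf("cannot read '%s': no such file", path), call. = FALSE)
    if (!grepl("\\.nii(\\.gz)?$", path))
      stop(sprintf("unsupported format for '%s' (expected NIfTI or a PNG directory)",
                   path), call. = FALSE)
    vol <- RNifti::readNifti(path)
    arr <- as.array(vol)
    if (length(dim(arr)) == 2L) arr <- array(arr, c(dim(arr), 1L))
    if (length(dim(arr)) != 3L)
      stop("only 2D/3D NIfTI volumes are supported", call. = FALSE)
    axis <- as.integer(axis)
    if (axis < 1L || axis > 3L) stop("axis must be 1, 2 or 3", call. = FALSE)
    # per-volume min-max normalization; volumes already in [0, 1] are
    # taken as normalized and passed through (so phantom exports
    # round-trip unchanged)
    if (min(arr) < 0 || max(arr) > 1) arr <- normalize_minmax(arr)
    n <- dim(arr)[axis]
    slices <- lapply(seq_len(n), function(i)
      switch(axis, arr[i, , ], arr[, i, ], arr[, , i]))
  }
  slices <- lapply(slices, clip01)
  if (drop_blank)
    slices <- Filter(function(s) stats::sd(s) > 0, slices)
  slices
}

#' Pixelwise absolute error map
#'
#' @param sr,hr Equal-shape numeric matrices.
#' @return `abs(sr - hr)`, suitable for color-mapped export.
#' @export
error_map <- function(sr, hr) {
  check_image(sr, "sr"); check_image(hr, "hr"); check_same_shape(sr, hr)
  abs(sr - hr)
}

#' Compare super-resolution methods on a test set
#'
#' Self-supervised protocol: each HR slice is degraded with [make_pair()],
#' every method reconstructs from the LR image, and the result is scored
#' against the original with PSNR and SSIM. Slices sharing a subject id
#' are averaged per subject before the mean/SD/CI summary, so the spread
#' reflects between-subject variability.
#'
#' @param hr_slices List of HR slices in `[0, 1]`.
#' @param methods Named list of functions `f(lr, scale)`, e.g. from
#'   [sr_method()] / [model_method()].
#' @param scale Integer scale factor (default 2).
#' @param subjects Optional subject id per slice (default: one subject
#'   per slice).
#' @param confidence CI level (default 0.95).
#' @return An object of class `eval_report`: `per_slice` and
#'   `per_subject` data frames and a `summary` data frame with one row
#'   per method and metric (`mean`, `sd`, `ci_low`, `ci_high`, `n`).
#'   Method failures are recorded as `NA` cells with a message; the
#'   report is still produced.
#' @export
evaluate_methods <- function(hr_slices, methods, scale = 2L,
                             subjects = NULL, confidence = 0.95) {
  if (!length(hr_slices)) stop("need at least one slice", call. = FALSE)
  if (!length(methods) || is.null(names(methods)))
    stop("methods must be a non-empty named list", call. = FALSE)
  if (is.null(subjects)) subjects <- seq_along(hr_slices)
  stopifnot(length(subjects) == length(hr_slices))
  rows <- list()
  for (i in seq_along(hr_slices)) {
    pair <- make_pair(hr_slices[[i]], scale = scale)
    for (m in names(methods)) {
      res <- tryCatch({
        sr <- methods[[m]](pair$lr, scale)
        check_same_shape(sr, pair$hr)
        c(psnr = psnr(sr, pair$hr), ssim = ssim(sr, pair$hr))
      }, error = function(e) {
        warning(sprintf("method '%s' failed on slice %d: %s",
                        m, i, conditionMessage(e)), call. = FALSE)
        c(psnr = NA_real_, ssim = NA_real_)
      })
      rows[[length(rows) + 1L]] <-
        data.frame(slice = i, subject = subjects[i], method = m,
                   psnr = res["psnr"], ssim = res["ssim"],
                   row.names = NULL)
    }
  }
  per_slice <- do.call(rbind, rows)
  per_subject <- stats::aggregate(cbind(psnr, ssim) ~ subject + method,
                                  data = per_slice, FUN = mean,
                                  na.action = stats::na.pass)
  summ <- list()
  for (m in names(methods)) {
    for (metric in c("psnr", "ssim")) {
      vals <- per_subject[per_subject$method == m, metric]
      vals <- vals[is.finite(vals)]
      st <- if (length(vals) >= 2L) summarize_metric(vals, confidence)
      else list(mean = if (length(vals)) vals else NA_real_,
                sd = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                n = length(vals))
      summ[[length(summ) + 1L]] <-
        data.frame(method = m, metric = metric, mean = st$mean,
                   sd = st$sd, ci_low = st$ci_low, ci_high = st$ci_high,
                   n = st$n)
    }
  }
  structure(list(per_slice = per_slice, per_subject = per_subject,
                 summary = do.call(rbind, summ), confidence = confidence),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(format_report(x), sep = "\n")
  invisible(x)
}

#' Format an evaluation report as an aligned text table
#'
#' @param report An `eval_report`.
#' @return Character vector of table lines.
#' @export
format_report <- function(report) {
  s <- report$summary
  lines <- sprintf("%-14s %-5s %9s %8s %22s",
                   "method", "metric", "mean", "SD",
                   sprintf("%g%% CI", 100 * report$confidence))
  for (i in seq_len(nrow(s))) {
    lines <- c(lines, sprintf("%-14s %-5s %9.4f %8.4f   [%8.4f, %8.4f]",
                              s$method[i], s$metric[i], s$mean[i], s$sd[i],
                              s$ci_low[i], s$ci_high[i]))
  }
  lines
}

#' Write an evaluation report to CSV
#'
#' Writes the summary table (and optionally the per-subject table) so it
#' re-parses to the same numbers.
#'
#' @param report An `eval_report`.
#' @param path Output CSV path for the summary.
#' @param per_subject_path Optional CSV path for the subject-level table.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path, per_subject_path = NULL) {
  utils::write.csv(report$summary, path, row.names = FALSE)
  if (!is.null(per_subject_path))
    utils::write.csv(report$per_subject, per_subject_path,
                     row.names = FALSE)
  invisible(path)
}
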