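# Slice and checkpoint I/O: 16-bit PNG, single-slice NIfTI, YAML configs.

#' Write a slice as an 8-bit grayscale PNG
#'
#' For quick visual export; use [write_slice_tiff()] (16-bit) or
#' [write_slices_nifti()] (float) when quantization matters.
#'
#' @param img Numeric matrix in `[0, 1]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_slice_png <- function(img, path) {
  check_image(img)
  if (min(img) < 0 || max(img) > 1)
    stop("image must be in [0, 1] for PNG export", call. = FALSE)
  png::writePNG(img, path, dpi = NULL)
  invisible(path)
}

#' Write a slice as a 16-bit grayscale TIFF
#'
#' @param img Numeric matrix in `[0, 1]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_slice_tiff <- function(img, path) {
  check_image(img)
  if (min(img) < 0 || max(img) > 1)
    stop("image must be in [0, 1] for TIFF export", call. = FALSE)
  tiff::writeTIFF(img, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a grayscale TIFF slice
#'
#' @param path TIFF file path.
#' @return Numeric matrix in `[0, 1]`.
#' @export
read_slice_tiff <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cannot read '%s': no such TIFF file", path),
         call. = FALSE)
  a <- tiff::readTIFF(path)
  if (length(dim(a)) == 3L) a <- apply(a[, , seq_len(min(3L, dim(a)[3])),
                                         drop = FALSE], c(1, 2), mean)
  a
}

#' Read a grayscale PNG slice
#'
#' Multi-channel images are averaged to one channel.
#'
#' @param path PNG file path.
#' @return Numeric matrix in `[0, 1]`.
#' @export
read_slice_png <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cannot read '%s': no such PNG file", path), call. = FALSE)
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- apply(a[, , seq_len(min(3L, dim(a)[3])),
                                         drop = FALSE], c(1, 2), mean)
  a
}

#' Write slices as a single NIfTI volume
#'
#' @param slices A matrix (one slice) or list of equally sized matrices,
#'   stacked along the third axis.
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_slices_nifti <- function(slices, path) {
  if (is.matrix(slices)) slices <- list(slices)
  d <- dim(slices[[1]])
  arr <- array(0, c(d, length(slices)))
  for (k in seq_along(slices)) arr[, , k] <- slices[[k]]
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  invisible(path)
}

#' Save a model checkpoint
#'
#' Single-file checkpoint holding the network configuration and all
#' weights; the config additionally round-trips through YAML via
#' [config_to_yaml()].
#'
#' @param model A `model_state`.
#' @param path Output path (`.rds`).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "model_state"))
  saveRDS(list(format = "mrisr-checkpoint-1",
               config = unclass(model$config),
               weights = model$weights), path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Checkpoint path written by [save_checkpoint()].
#' @return A `model_state`.
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "mrisr-checkpoint-1"))
    stop("not a recognized checkpoint file", call. = FALSE)
  config <- do.call(network_config, x$config)
  model <- structure(list(config = config, weights = x$weights),
                     class = "model_state")
  model$n_parameters <- count_parameters(model)
  model
}

#' Serialize a configuration to YAML
#'
#' Works for `network_config`, `loss_config` and `train_config` (nested
#' configs are inlined).
#'
#' @param cfg A configuration object.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
config_to_yaml <- function(cfg, path) {
  strip <- function(x) {
    x <- unclass(x)
    lapply(x, function(v) if (is.list(v)) strip(v) else v)
  }
  yaml::write_yaml(strip(cfg), path)
  invisible(path)
}

#' Read a training configuration from YAML
#'
#' Missing fields fall back to the [train_config()] defaults; nested
#' `loss` and `network` blocks are promoted to their config classes.
#'
#' @param path YAML path.
#' @return A `train_config`.
#' @export
train_config_from_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  keep <- function(args, fn) args[intersect(names(args), names(formals(fn)))]
  if (!is.null(x$loss)) x$loss <- do.call(loss_config,
                                          keep(x$loss, loss_config))
  if (!is.null(x$network)) x$network <- do.call(network_config,
                                                keep(x$network,
                                                     network_config))
  do.call(train_config, keep(x, train_config))
}
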