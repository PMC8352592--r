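#' Write / read a FRAP curve as CSV
#'
#' Curves are exchanged as comma-separated text with a header and columns
#' `time_s`, `roi`, `whole`, `background`, `is_pre` (0/1 flag marking the
#' pre-bleach frames).
#'
#' @param curve A [frap_curve()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  check_that(inherits(curve, "frap_curve"), "curve", "must be a frap_curve")
  df <- as.data.frame(curve)
  df$is_pre <- as.integer(seq_len(nrow(df)) <= attr(curve, "n_pre"))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curve_csv
#' @param n_pre Pre-bleach frame count, required only when the file lacks an
#'   `is_pre` column and `bleach_detect = "annotated"`.
#' @param bleach_detect For unannotated files: `"annotated"` requires
#'   `n_pre`; `"min"` falls back to locating the bleach at the
#'   minimum-intensity frame of the ROI channel.
#' @export
read_curve_csv <- function(path, n_pre = NULL,
                           bleach_detect = c("annotated", "min")) {
  bleach_detect <- match.arg(bleach_detect)
  df <- read.csv(path)
  check_that(all(c("time_s", "roi", "whole", "background") %in% names(df)),
             "path", "CSV must have time_s, roi, whole, background columns")
  if ("is_pre" %in% names(df)) {
    n_pre <- sum(df$is_pre > 0)
  } else if (is.null(n_pre)) {
    check_that(bleach_detect == "min", "n_pre",
               "required when the CSV has no is_pre column")
    n_pre <- which.min(df$roi) - 1L
    check_that(n_pre >= 1, "path", "cannot locate a bleach frame")
  }
  frap_curve(df$time_s, df$roi, df$whole, df$background, n_pre = n_pre)
}

#' Write / read an image stack as multi-page TIFF
#'
#' Stacks are stored as 8-bit grayscale multi-page TIFF, one page per
#' z-slice.
#'
#' @param stack Numeric array `y` x `x` (x `z`) with values in \[0, 255\].
#' @param path File path.
#' @return `path` invisibly (write) or the numeric array on the 0-255 scale
#'   (read).
#' @export
write_stack_tiff <- function(stack, path) {
  check_that(is.numeric(stack), "stack", "must be numeric")
  check_that(all(stack >= 0 & stack <= 255), "stack",
             "values must lie in [0, 255]")
  if (length(dim(stack)) == 2) stack <- array(stack, dim = c(dim(stack), 1))
  pages <- lapply(seq_len(dim(stack)[3]),
                  function(z) stack[, , z] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (z in seq_along(pages)) {
    pg <- pages[[z]]
    if (length(dim(pg)) == 3) pg <- pg[, , 1]
    arr[, , z] <- pg
  }
  round(arr * 255)
}

#' Write a phantom with its ground-truth sidecar
#'
#' Stores the rendered stack as multi-page TIFF and the ground truth (class
#' volume fractions, voxel size, seed, intensities) as a JSON sidecar named
#' `<path>.json`.
#'
#' @param phantom Output of [render_nucleus_phantom()].
#' @param path TIFF file path.
#' @return `path`, invisibly.
#' @export
write_phantom_tiff <- function(phantom, path) {
  check_that(is.list(phantom) && !is.null(phantom$image), "phantom",
             "must be a rendered phantom")
  write_stack_tiff(phantom$image, path)
  sidecar <- list(
    ground_truth_fractions = as.list(phantom$ground_truth),
    target_fractions = as.list(phantom$spec$class_fractions),
    class_intensity = as.list(phantom$spec$class_intensity),
    voxel_size_um = as.list(phantom$spec$voxel_size),
    shape = as.integer(phantom$spec$shape),
    psf_sigma = phantom$spec$psf_sigma,
    seed = phantom$spec$seed)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
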