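#' Manders colocalization coefficients
#'
#' Thresholded Manders coefficients between two channels of identical
#' geometry:
#' \deqn{M_1 = \frac{\sum_i a_i \, [b_i > \tau_b]}{\sum_i a_i}, \qquad
#'       M_2 = \frac{\sum_i b_i \, [a_i > \tau_a]}{\sum_i b_i}}
#' i.e. the fraction of each channel's intensity lying in voxels where the
#' other channel exceeds its threshold.  Both coefficients are invariant
#' under uniform rescaling of the measured channel.
#'
#' @param channel_a,channel_b Non-negative numeric arrays of identical shape.
#' @param threshold Either `"otsu"` (default; automatic threshold per
#'   channel) or a numeric vector `c(tau_a, tau_b)` of fixed thresholds.
#' @param mask Optional logical array restricting the analysis.
#' @return A `coloc_result` list: `M1`, `M2`, `tau_a`, `tau_b`.
#' @export
manders_coefficients <- function(channel_a, channel_b, threshold = "otsu",
                                 mask = NULL) {
  check_that(is.numeric(channel_a) && is.numeric(channel_b), "channel_a",
             "channels must be numeric")
  check_that(identical(dim(channel_a) %||% length(channel_a),
                       dim(channel_b) %||% length(channel_b)),
             "channel_b", "geometry must match channel_a")
  check_that(all(channel_a >= 0) && all(channel_b >= 0), "channel_a",
             "intensities must be non-negative")
  a <- as.numeric(channel_a)
  b <- as.numeric(channel_b)
  if (!is.null(mask)) {
    check_that(is.logical(mask) &&
                 length(mask) == length(a), "mask", "must match the channels")
    a <- a[as.logical(mask)]
    b <- b[as.logical(mask)]
  }
  if (identical(threshold, "otsu")) {
    tau_a <- otsu_threshold(a)
    tau_b <- otsu_threshold(b)
  } else {
    check_that(is.numeric(threshold) && length(threshold) == 2, "threshold",
               'must be "otsu" or c(tau_a, tau_b)')
    tau_a <- threshold[1]
    tau_b <- threshold[2]
  }
  sum_a <- sum(a)
  sum_b <- sum(b)
  check_that(sum_a > 0 && sum_b > 0, "channel_a",
             "channels must carry nonzero total intensity")
  structure(list(M1 = sum(a[b > tau_b]) / sum_a,
                 M2 = sum(b[a > tau_a]) / sum_b,
                 tau_a = tau_a, tau_b = tau_b),
            class = "coloc_result")
}

# Otsu threshold on arbitrary-range data, via EBImage on a [0, 1] rescale.
otsu_threshold <- function(x) {
  rng <- range(x)
  if (rng[2] <= rng[1]) return(rng[1])
  u <- (x - rng[1]) / (rng[2] - rng[1])
  tau01 <- EBImage::otsu(EBImage::Image(matrix(u, nrow = 1)), levels = 256)
  rng[1] + tau01 * (rng[2] - rng[1])
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> M1 = %.4f (tau_b %.4g), M2 = %.4f (tau_a %.4g)\n",
              x$M1, x$tau_b, x$M2, x$tau_a))
  invisible(x)
}

#' Render an 8-bit image through a fixed false-color lookup table
#'
#' Deterministic mapping of gray values 0..255 onto a 256-entry color table
#' (full-scale heat map display).  The table is bijective, so the original
#' gray values can be recovered exactly with [heatmap_invert()].
#'
#' @param image Numeric array with values in \[0, 255\] (rounded to
#'   integers).
#' @param lut Character vector of 256 distinct colors; default is the
#'   inferno palette.
#' @return Character array of hex colors, same shape as `image`, with the
#'   LUT attached as attribute `lut`.
#' @export
heatmap_render <- function(image, lut = heatmap_lut()) {
  check_that(is.numeric(image), "image", "must be numeric")
  v <- round(image)
  check_that(all(v >= 0 & v <= 255), "image", "values must lie in [0, 255]")
  check_that(length(lut) == 256 && !anyDuplicated(lut), "lut",
             "must be 256 distinct colors")
  out <- array(lut[v + 1L], dim = dim(image) %||% length(image))
  attr(out, "lut") <- lut
  out
}

#' Invert a false-color rendering back to gray values
#'
#' @param colors Output of [heatmap_render()] (or any array of LUT colors).
#' @param lut The lookup table used for rendering; defaults to the one
#'   attached to `colors`.
#' @return Integer array of gray values 0..255.
#' @export
heatmap_invert <- function(colors, lut = attr(colors, "lut")) {
  check_that(!is.null(lut), "lut", "no lookup table supplied or attached")
  idx <- match(as.character(colors), lut)
  check_that(!anyNA(idx), "colors", "contains colors outside the LUT")
  array(idx - 1L, dim = dim(colors) %||% length(colors))
}

#' @rdname heatmap_render
#' @export
heatmap_lut <- function() {
  lut <- hcl.colors(256, "Inferno")
  stopifnot(!anyDuplicated(lut))
  lut
}
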