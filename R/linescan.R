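#' Intensity profile along a line, as percent of the image maximum
#'
#' Samples each channel along the segment from `from` to `to` by bilinear
#' interpolation at sub-pixel spacing, and scales each channel so that its
#' image-wide maximum is 100 percent — the convention used for band/interband
#' line scans across a nucleus.
#'
#' @param channels A single numeric matrix or a named list of matrices
#'   (same dimensions), one per channel.
#' @param from,to Segment endpoints as `c(row, col)` in pixel coordinates
#'   (1-based, may be fractional); both must lie inside the image.
#' @param spacing Sample spacing along the segment, pixels.
#' @return A data frame with `distance` (pixels from `from`) and one percent
#'   column per channel.
#' @export
line_scan_profile <- function(channels, from, to, spacing = 0.5) {
  if (is.matrix(channels)) channels <- list(intensity = channels)
  check_that(is.list(channels) && length(channels) >= 1, "channels",
             "must be a matrix or list of matrices")
  dims <- dim(channels[[1]])
  for (ch in channels)
    check_that(is.matrix(ch) && identical(dim(ch), dims), "channels",
               "all channels must be matrices of identical dimensions")
  check_that(length(from) == 2 && length(to) == 2, "from",
             "endpoints must be (row, col) pairs")
  inside <- function(p) p[1] >= 1 && p[1] <= dims[1] &&
    p[2] >= 1 && p[2] <= dims[2]
  check_that(inside(from) && inside(to), "from",
             "endpoints must lie inside the image")
  check_that(spacing > 0, "spacing", "must be > 0")

  len <- sqrt(sum((to - from)^2))
  n <- max(2L, ceiling(len / spacing) + 1L)
  tt <- seq(0, 1, length.out = n)
  rows <- from[1] + tt * (to[1] - from[1])
  cols <- from[2] + tt * (to[2] - from[2])

  out <- data.frame(distance = tt * len)
  for (nm in names(channels)) {
    v <- bilinear_sample(channels[[nm]], rows, cols)
    mx <- max(channels[[nm]])
    check_that(mx > 0, "channels", "channel maximum must be > 0")
    out[[nm]] <- 100 * v / mx
  }
  out
}

# Bilinear interpolation of matrix `m` at fractional (row, col) positions.
bilinear_sample <- function(m, rows, cols) {
  r0 <- pmin(pmax(floor(rows), 1), nrow(m) - 1L)
  c0 <- pmin(pmax(floor(cols), 1), ncol(m) - 1L)
  fr <- rows - r0
  fc <- cols - c0
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 1L, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1L)] * (1 - fr) * fc +
    m[cbind(r0 + 1L, c0 + 1L)] * fr * fc
}
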