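#' Construct a raw FRAP/FLIP time-series curve
#'
#' Bundles the per-frame mean ROI intensity, whole-nucleus intensity and
#' background intensity with the number of pre-bleach frames.
#'
#' @param time Frame times in seconds, strictly increasing.
#' @param roi Mean intensity of the bleached region per frame.
#' @param whole Mean intensity of the whole nucleus per frame.
#' @param background Background intensity per frame (scalar recycled).
#' @param n_pre Number of pre-bleach frames (>= 1 and < number of frames).
#' @return A `frap_curve` data frame.
#' @export
frap_curve <- function(time, roi, whole = rep(1, length(time)),
                       background = 0, n_pre) {
  n <- length(time)
  check_that(n >= 3, "time", "need at least 3 frames")
  check_that(all(diff(time) > 0), "time", "must be strictly increasing")
  check_that(length(roi) == n, "roi", "length must match time")
  check_that(length(whole) == n, "whole", "length must match time")
  if (length(background) == 1) background <- rep(background, n)
  check_that(length(background) == n, "background", "length must match time")
  check_that(n_pre >= 1 && n_pre < n, "n_pre", "must be >= 1 and < n frames")
  new_frap_curve(time, roi, whole, background, n_pre)
}

#' Subtract background fluorescence from a curve
#'
#' Subtracts the background channel from the ROI and whole-nucleus channels,
#' flooring at zero.  Frames hitting the floor are recorded in the
#' `floored_frames` attribute (and raise a warning) rather than silently
#' clipping.
#'
#' @param curve A [frap_curve()].
#' @return A background-corrected `frap_curve` with `background` set to 0.
#' @export
background_correct <- function(curve) {
  check_that(inherits(curve, "frap_curve"), "curve", "must be a frap_curve")
  roi <- curve$roi - curve$background
  whole <- curve$whole - curve$background
  floored <- which(roi < 0 | whole < 0)
  if (length(floored) > 0) {
    warning(sprintf("background correction floored %d frame(s) at 0",
                    length(floored)), call. = FALSE)
    roi <- pmax(roi, 0)
    whole <- pmax(whole, 0)
  }
  out <- new_frap_curve(curve$time_s, roi, whole, numeric(nrow(curve)),
                        attr(curve, "n_pre"))
  attr(out, "floored_frames") <- floored
  out
}

#' Full-scale normalization of a FRAP curve
#'
#' Double normalization of the background-corrected ROI signal against the
#' whole-nucleus channel (correcting for acquisition photobleaching),
#' followed by full-scale rescaling so that the pre-bleach mean maps to 1 and
#' the first post-bleach frame to exactly 0:
#' \deqn{I_{dn}(t) = \frac{roi(t)/\overline{roi_{pre}}}{whole(t)/\overline{whole_{pre}}},
#'   \qquad F(t) = \frac{I_{dn}(t) - I_{dn}(t_0)}{1 - I_{dn}(t_0)}}
#' where \eqn{t_0} is the first post-bleach frame.
#'
#' @param curve A background-corrected [frap_curve()].
#' @return A `normalized_curve` data frame with columns `time` (seconds from
#'   bleach; pre-bleach frames have negative time) and `value`, and
#'   attributes `n_pre` and `bleach_depth_observed` (\eqn{1 - I_{dn}(t_0)}).
#' @section Errors: if no bleach is detectable (\eqn{I_{dn}(t_0) \ge 1}) an
#'   error of class `chromodyn_analysis_error` is signalled.
#' @export
full_scale_normalize <- function(curve) {
  check_that(inherits(curve, "frap_curve"), "curve", "must be a frap_curve")
  n_pre <- attr(curve, "n_pre")
  pre <- seq_len(n_pre)
  roi_pre <- mean(curve$roi[pre])
  whole_pre <- mean(curve$whole[pre])
  check_that(roi_pre > 0, "roi", "pre-bleach ROI mean must be > 0")
  check_that(all(curve$whole > 0), "whole", "whole-nucleus channel must be > 0")
  i_dn <- (curve$roi / roi_pre) / (curve$whole / whole_pre)
  t0 <- n_pre + 1L
  if (i_dn[t0] >= 1)
    abort_analysis("no bleach detected: first post-bleach frame is not below the pre-bleach level")
  value <- (i_dn - i_dn[t0]) / (1 - i_dn[t0])
  tau <- curve$time_s - curve$time_s[t0]
  structure(data.frame(time = tau, value = value),
            n_pre = n_pre,
            bleach_depth_observed = 1 - i_dn[t0],
            class = c("normalized_curve", "data.frame"))
}

#' @export
print.normalized_curve <- function(x, ...) {
  cat(sprintf(
    "<normalized_curve> %d frames (%d pre-bleach), observed bleach depth %.3f\n",
    nrow(x), attr(x, "n_pre"), attr(x, "bleach_depth_observed")))
  invisible(x)
}

# Post-bleach portion (tau >= 0) as a plain data frame.
post_bleach <- function(nc) {
  check_that(inherits(nc, "normalized_curve"), "curve",
             "must be a normalized_curve")
  idx <- seq.int(attr(nc, "n_pre") + 1L, nrow(nc))
  data.frame(time = nc$time[idx], value = nc$value[idx])
}

#' Mean normalized recovery around a fixed time point
#'
#' Reads percent recovery at a fixed time (e.g. recovery within 50 min of
#' photobleaching) as the mean of the normalized curve over a window
#' centered at `t`.
#'
#' @param curve A `normalized_curve`.
#' @param t Time since bleach, seconds; must lie within the sampled range.
#' @param window Full window width in seconds (0 = nearest sample only).
#' @return Recovery as a fraction of the pre-bleach level.
#' @export
percent_recovery_at <- function(curve, t, window = 0) {
  pb <- post_bleach(curve)
  check_that(t >= min(pb$time) && t <= max(pb$time), "t",
             "must lie within the sampled post-bleach range")
  check_that(window >= 0, "window", "must be >= 0")
  if (window == 0) {
    pb$value[which.min(abs(pb$time - t))]
  } else {
    sel <- abs(pb$time - t) <= window / 2
    mean(pb$value[sel])
  }
}
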