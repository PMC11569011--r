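# Savitzky-Golay smoothing of the raw acceleration channels and gravity-
# magnitude confidence flagging.  Inclination from gravity projection is only
# meaningful while the accelerometer measures ~1 g, so samples with a vector
# magnitude far from 1 g (dynamic phases, impacts) are flagged, not dropped.

#' Savitzky-Golay smoothing configuration
#'
#' @param polynomial_order order of the local polynomial fit (default 3).
#' @param window_s window length in seconds (default 1.0); the window in
#'   samples is rounded to the nearest odd count and must exceed the order.
#' @param sample_rate sampling rate in Hz.
#' @return Object of class \code{smoothing_config} with the resolved odd
#'   window length in samples (\code{window_n}).
#' @export
smoothing_config <- function(polynomial_order = 3, window_s = 1.0,
                             sample_rate = 128) {
  if (polynomial_order < 1) stop_fmt("smoothing_config: order must be >= 1")
  if (window_s <= 0 || sample_rate <= 0)
    stop_fmt("smoothing_config: window_s and sample_rate must be > 0")
  n <- round(window_s * sample_rate)
  if (n %% 2 == 0) n <- n + 1
  if (n <= polynomial_order)
    stop_fmt("smoothing_config: window (%d samples) must exceed order %d",
             n, polynomial_order)
  structure(list(polynomial_order = polynomial_order, window_s = window_s,
                 sample_rate = sample_rate, window_n = n),
            class = "smoothing_config")
}

#' Savitzky-Golay filter one channel
#'
#' Least-squares local polynomial smoothing (order 3 by default); the filter
#' reproduces polynomials up to the configured order exactly, so slow posture
#' changes pass undistorted while sample noise is attenuated.  Edges are
#' handled by evaluating the polynomial fit of the first/last full window at
#' the edge positions (no zero padding), so the output has the same length.
#'
#' @param channel numeric series (acceleration in g, or any signal).
#' @param cfg a \code{\link{smoothing_config}}.
#' @return Smoothed series of the same length.
#' @export
savitzky_golay <- function(channel, cfg = smoothing_config()) {
  stopifnot(inherits(cfg, "smoothing_config"))
  if (length(channel) < cfg$window_n)
    stop_fmt("savitzky_golay: series (%d) shorter than window (%d samples)",
             length(channel), cfg$window_n)
  as.numeric(signal::sgolayfilt(channel, p = cfg$polynomial_order,
                                n = cfg$window_n))
}

#' Smooth all channels of a recording
#'
#' @param rec an \code{\link{accel_recording}}.
#' @param cfg a \code{\link{smoothing_config}}; its \code{sample_rate} is
#'   replaced by the recording's.
#' @return An \code{\link{accel_recording}} with smoothed channels.
#' @export
smooth_recording <- function(rec, cfg = smoothing_config()) {
  stopifnot(inherits(rec, "accel_recording"))
  cfg <- smoothing_config(cfg$polynomial_order, cfg$window_s, rec$sample_rate)
  ch <- as.data.frame(lapply(rec$channels, savitzky_golay, cfg = cfg))
  accel_recording(ch, rec$sample_rate, rec$start_time, rec$sensors)
}

#' Flag low-confidence samples by gravity magnitude
#'
#' A sample is low-confidence when the acceleration vector magnitude falls
#' outside the closed interval \code{[lo, hi]} g — e.g. free-fall-like or
#' impact phases, where the gravity direction cannot be read off the
#' accelerometer.
#'
#' @param rec an \code{\link{accel_recording}}.
#' @param lo,hi magnitude bounds in g (defaults 0.5 and 1.5); \code{lo < hi}.
#' @return Logical data frame, one column per sensor; \code{TRUE} marks a
#'   flagged (low-confidence) sample.
#' @export
flag_low_confidence <- function(rec, lo = 0.5, hi = 1.5) {
  stopifnot(inherits(rec, "accel_recording"))
  if (!(lo < hi)) stop_fmt("flag_low_confidence: need lo < hi")
  out <- lapply(rec$sensors, function(s) {
    m <- sqrt(rec$channels[[paste0(s, "_ax")]]^2 +
              rec$channels[[paste0(s, "_ay")]]^2 +
              rec$channels[[paste0(s, "_az")]]^2)
    m < lo | m > hi
  })
  as.data.frame(setNames(out, rec$sensors))
}
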