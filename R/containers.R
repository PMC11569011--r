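#' @importFrom stats approx rnorm rpois runif setNames
#' @importFrom utils read.csv read.delim write.table packageVersion
NULL

SENSORS <- c("C7", "L5", "TH", "SH")
MARKERS <- c("C7", "L5", "IC", "LM")
ACTIVITY_LABELS <- c("standing_upright", "standing_forward_lean",
                     "walking", "parkinsonian_gait", "other")

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

#' Synchronized four-sensor tri-axial acceleration recording
#'
#' Container for the 12 raw acceleration channels of the four body-worn
#' sensors (C7, L5, thigh TH, shank SH), sampled at a common fixed rate.
#' Channels are in units of g; at upright stance the longitudinal channel of
#' every sensor reads \code{a_x = -1} g (gravity along the segment axis).
#'
#' @param channels data frame (or coercible) with one column per channel,
#'   named \code{<sensor>_a<axis>} e.g. \code{C7_ax}; all columns equal length
#'   and free of non-finite values.
#' @param sample_rate sampling rate in Hz (default 128).
#' @param start_time time of the first sample in seconds (default 0).
#' @param sensors sensors that must be present; defaults to all four.
#'   A perpendicular-only recording may carry just \code{c("C7","L5")}.
#' @return An object of class \code{accel_recording}: a list with elements
#'   \code{channels}, \code{sample_rate}, \code{start_time}, \code{sensors},
#'   \code{n_samples}, \code{time_s}.
#' @export
accel_recording <- function(channels, sample_rate = 128, start_time = 0,
                            sensors = SENSORS) {
  channels <- as.data.frame(channels)
  sensors <- match.arg(sensors, SENSORS, several.ok = TRUE)
  wanted <- as.vector(t(outer(sensors, c("ax", "ay", "az"), paste, sep = "_")))
  missing <- setdiff(wanted, names(channels))
  if (length(missing))
    stop_fmt("accel_recording: missing channel column(s): %s",
             paste(missing, collapse = ", "))
  channels <- channels[wanted]  # canonical order, never silently reordered
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0)
    stop_fmt("accel_recording: sample_rate must be a single positive number")
  n <- nrow(channels)
  if (n < 1) stop_fmt("accel_recording: no samples")
  bad <- !vapply(channels, function(x) all(is.finite(x)), logical(1))
  if (any(bad))
    stop_fmt("accel_recording: non-finite values (gaps) in channel(s): %s",
             paste(names(channels)[bad], collapse = ", "))
  structure(list(
    channels = channels,
    sample_rate = sample_rate,
    start_time = start_time,
    sensors = sensors,
    n_samples = n,
    time_s = start_time + (seq_len(n) - 1) / sample_rate
  ), class = "accel_recording")
}

#' @export
print.accel_recording <- function(x, ...) {
  cat(sprintf("<accel_recording> %d sensors (%s), %d samples @ %g Hz (%.2f s)\n",
              length(x$sensors), paste(x$sensors, collapse = ", "),
              x$n_samples, x$sample_rate, x$n_samples / x$sample_rate))
  invisible(x)
}

#' Optical marker trajectory for the four reference markers
#'
#' Time-indexed 3D positions (meters, z vertical up) of the C7, L5, iliac
#' crest (IC) and lateral malleolus (LM) reflective markers.
#'
#' @param coords data frame with columns \code{<marker>_<x|y|z>} for all four
#'   markers, finite values.
#' @param sample_rate sampling rate in Hz.
#' @param start_time time of first frame, seconds.
#' @return Object of class \code{marker_trajectory}.
#' @export
marker_trajectory <- function(coords, sample_rate, start_time = 0) {
  coords <- as.data.frame(coords)
  wanted <- as.vector(t(outer(MARKERS, c("x", "y", "z"), paste, sep = "_")))
  missing <- setdiff(wanted, names(coords))
  if (length(missing))
    stop_fmt("marker_trajectory: missing coordinate column(s): %s",
             paste(missing, collapse = ", "))
  coords <- coords[wanted]
  if (sample_rate <= 0) stop_fmt("marker_trajectory: sample_rate must be > 0")
  for (nm in wanted) {
    bad <- which(!is.finite(coords[[nm]]))
    if (length(bad))
      stop_fmt("marker_trajectory: non-finite %s at frame(s) %s",
               nm, paste(utils::head(bad, 5), collapse = ", "))
  }
  n <- nrow(coords)
  structure(list(
    coords = coords, sample_rate = sample_rate, start_time = start_time,
    n_frames = n, time_s = start_time + (seq_len(n) - 1) / sample_rate
  ), class = "marker_trajectory")
}

#' @export
print.marker_trajectory <- function(x, ...) {
  cat(sprintf("<marker_trajectory> %d frames @ %g Hz (%.2f s), markers %s\n",
              x$n_frames, x$sample_rate, x$n_frames / x$sample_rate,
              paste(MARKERS, collapse = ", ")))
  invisible(x)
}

#' Labeled activity segments
#'
#' Ordered, non-overlapping time intervals labeling the recorded activities.
#'
#' @param label character vector of labels from the closed set
#'   \code{standing_upright, standing_forward_lean, walking,
#'   parkinsonian_gait, other}.
#' @param t_start,t_end interval bounds in seconds, \code{t_start < t_end}.
#' @return Object of class \code{activity_segments} (a data frame).
#' @export
activity_segments <- function(label, t_start, t_end) {
  label <- as.character(label)
  bad <- setdiff(label, ACTIVITY_LABELS)
  if (length(bad))
    stop_fmt("activity_segments: unknown label(s): %s (allowed: %s)",
             paste(unique(bad), collapse = ", "),
             paste(ACTIVITY_LABELS, collapse = ", "))
  if (length(label) != length(t_start) || length(label) != length(t_end))
    stop_fmt("activity_segments: label/t_start/t_end lengths differ")
  if (any(!(t_start < t_end)))
    stop_fmt("activity_segments: every t_start must be < t_end")
  o <- order(t_start)
  label <- label[o]; t_start <- t_start[o]; t_end <- t_end[o]
  if (length(t_start) > 1 && any(t_start[-1] < t_end[-length(t_end)] - 1e-12))
    stop_fmt("activity_segments: segments overlap")
  structure(data.frame(label = label, t_start = t_start, t_end = t_end,
                       stringsAsFactors = FALSE),
            class = c("activity_segments", "data.frame"))
}

#' Segment lengths of the leg
#'
#' Thigh (\code{u}) and shank (\code{l}) lengths in meters, measured on the
#' subject at sensor placement; inputs to the two-pendulum leg model.
#'
#' @param u_m thigh length in meters, in (0, 1).
#' @param l_m shank length in meters, in (0, 1).
#' @return Object of class \code{anthropometry}.
#' @export
anthropometry <- function(u_m, l_m) {
  if (!is.finite(u_m) || u_m <= 0 || u_m >= 1)
    stop_fmt("anthropometry: thigh length u_m must be in (0, 1) m")
  if (!is.finite(l_m) || l_m <= 0 || l_m >= 1)
    stop_fmt("anthropometry: shank length l_m must be in (0, 1) m")
  structure(list(u_m = u_m, l_m = l_m), class = "anthropometry")
}

#' @export
print.anthropometry <- function(x, ...) {
  cat(sprintf("<anthropometry> thigh u = %.3f m, shank l = %.3f m\n",
              x$u_m, x$l_m))
  invisible(x)
}

#' Labeled angle time series
#'
#' A time-indexed sequence of angles in degrees with a validity mask and a
#' semantic label (e.g. \code{"ca_mal"} or \code{"phi_per_ref"}).
#'
#' @param time_s sample times, seconds.
#' @param angle angles, degrees.
#' @param valid logical validity mask (recycled); invalid samples are ignored
#'   by window averaging and evaluation.
#' @param label semantic label.
#' @return Object of class \code{angle_series} (a data frame with columns
#'   \code{time_s}, \code{angle}, \code{valid}).
#' @export
angle_series <- function(time_s, angle, valid = TRUE, label = "angle") {
  if (length(time_s) != length(angle))
    stop_fmt("angle_series: time_s and angle lengths differ")
  valid <- rep_len(as.logical(valid), length(angle))
  structure(data.frame(time_s = time_s, angle = angle, valid = valid),
            label = label, class = c("angle_series", "data.frame"))
}

#' @export
print.angle_series <- function(x, ...) {
  rng <- range(x$angle[x$valid], na.rm = TRUE)
  cat(sprintf("<angle_series '%s'> %d samples, %d valid, range [%.2f, %.2f] deg\n",
              attr(x, "label"), nrow(x), sum(x$valid), rng[1], rng[2]))
  invisible(x)
}
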