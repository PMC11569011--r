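# File formats.  All plain text:
#   IMU CSV:     time_s,C7_ax,...,SH_az  (12 acceleration columns, units g)
#   marker TSV:  time_s<TAB>C7_x ... LM_z (meters, z up)
#   segments:    label<TAB>t_start<TAB>t_end
# Numbers are written with 10 decimals so round-trips hold to 1e-9.

fmt_num <- function(x) formatC(x, digits = 10, format = "f")

check_time_column <- function(time_s, path) {
  if (any(!is.finite(time_s)))
    stop_fmt("%s: non-finite time values", path)
  dt <- diff(time_s)
  if (length(dt) && any(dt <= 0))
    stop_fmt("%s: time column is not strictly increasing", path)
  if (length(dt) > 1 && (max(dt) - min(dt)) > 1e-6 * stats::median(dt) + 1e-9)
    stop_fmt("%s: time column is not uniformly sampled", path)
}

#' Read an IMU recording from CSV
#'
#' Expects the wide dialect \code{time_s,C7_ax,...,SH_az}: one row per
#' sample, accelerations in g, all requested sensors present.  The sample
#' rate is inferred from the time column.
#'
#' @param path file path.
#' @param sensors sensors that must be present (default all four; use
#'   \code{c("C7","L5")} for a perpendicular-only recording).
#' @return An \code{\link{accel_recording}}.
#' @export
read_accel_csv <- function(path, sensors = SENSORS) {
  if (!file.exists(path)) stop_fmt("read_accel_csv: no such file: %s", path)
  d <- read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(d))
    stop_fmt("%s: missing time_s column", path)
  check_time_column(d$time_s, path)
  rate <- if (nrow(d) > 1) 1 / stats::median(diff(d$time_s)) else 128
  accel_recording(d[setdiff(names(d), "time_s")], sample_rate = rate,
                  start_time = d$time_s[1], sensors = sensors)
}

#' Write an IMU recording to CSV
#'
#' @param rec an \code{\link{accel_recording}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_accel_csv <- function(rec, path) {
  stopifnot(inherits(rec, "accel_recording"))
  d <- cbind(time_s = fmt_num(rec$time_s),
             as.data.frame(lapply(rec$channels, fmt_num)))
  write.table(d, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a marker trajectory from TSV
#'
#' Expects the dialect \code{time_s<TAB>C7_x ... LM_z}: 12 coordinate columns
#' in meters, z vertical up.  NaN coordinates are an error naming the frame.
#'
#' @param path file path.
#' @return A \code{\link{marker_trajectory}}.
#' @export
read_markers_tsv <- function(path) {
  if (!file.exists(path)) stop_fmt("read_markers_tsv: no such file: %s", path)
  d <- read.delim(path, check.names = FALSE)
  if (!"time_s" %in% names(d))
    stop_fmt("%s: missing time_s column", path)
  check_time_column(d$time_s, path)
  rate <- if (nrow(d) > 1) 1 / stats::median(diff(d$time_s)) else 100
  marker_trajectory(d[setdiff(names(d), "time_s")], sample_rate = rate,
                    start_time = d$time_s[1])
}

#' Write a marker trajectory to TSV
#'
#' @param traj a \code{\link{marker_trajectory}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_markers_tsv <- function(traj, path) {
  stopifnot(inherits(traj, "marker_trajectory"))
  d <- cbind(time_s = fmt_num(traj$time_s),
             as.data.frame(lapply(traj$coords, fmt_num)))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read activity segment annotations
#'
#' Plain text, one segment per line: \code{label<TAB>t_start<TAB>t_end}.
#'
#' @param path file path.
#' @return An \code{\link{activity_segments}}.
#' @export
read_segments_tsv <- function(path) {
  if (!file.exists(path)) stop_fmt("read_segments_tsv: no such file: %s", path)
  d <- read.delim(path, header = FALSE,
                  col.names = c("label", "t_start", "t_end"))
  activity_segments(d$label, d$t_start, d$t_end)
}

#' Write activity segment annotations
#'
#' @param seg an \code{\link{activity_segments}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_segments_tsv <- function(seg, path) {
  stopifnot(inherits(seg, "activity_segments"))
  write.table(data.frame(seg$label, fmt_num(seg$t_start), fmt_num(seg$t_end)),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Resample a marker trajectory to a target rate
#'
#' Linear interpolation on each coordinate; used to compare the optical
#' reference sample-wise with the 128 Hz IMU streams.  Duration is preserved
#' to within one sample period.
#'
#' @param traj a \code{\link{marker_trajectory}}.
#' @param target_rate new sampling rate in Hz, > 0.
#' @return A \code{\link{marker_trajectory}} at \code{target_rate}.
#' @export
resample_markers <- function(traj, target_rate) {
  stopifnot(inherits(traj, "marker_trajectory"))
  if (target_rate <= 0) stop_fmt("resample_markers: target_rate must be > 0")
  if (traj$n_frames < 2)
    stop_fmt("resample_markers: need at least 2 frames")
  t_old <- traj$time_s
  t_new <- seq(t_old[1], t_old[length(t_old)], by = 1 / target_rate)
  coords <- as.data.frame(lapply(traj$coords, function(col)
    approx(t_old, col, xout = t_new)$y))
  marker_trajectory(coords, sample_rate = target_rate, start_time = t_new[1])
}

RUN_CONFIG_KEYS <- c("sample_rate", "u_m", "l_m", "marker_time_offset_s",
                     "sg_window_s", "sg_order", "calibration")
CALIBRATION_KEYS <- c("method", "window", "photo_ca_per", "photo_ca_mal")

#' Read and validate a run configuration file
#'
#' YAML file with keys \code{sample_rate}, \code{u_m}, \code{l_m},
#' \code{marker_time_offset_s}, \code{sg_window_s}, \code{sg_order} and an
#' optional \code{calibration} block (\code{method: zero|patient_specific},
#' \code{window: [t0, t1]}, \code{photo_ca_per}, \code{photo_ca_mal}).
#' Unknown keys are rejected before any computation.
#'
#' @param path path to the YAML file.
#' @return A named list with validated entries and defaults filled in
#'   (\code{sample_rate} 128 Hz, \code{sg_window_s} 1.0 s, \code{sg_order} 3,
#'   \code{marker_time_offset_s} 0).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_fmt("read_run_config: no such file: %s", path)
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), RUN_CONFIG_KEYS)
  if (length(unknown))
    stop_fmt("config: unknown key(s): %s", paste(unknown, collapse = ", "))
  defaults <- list(sample_rate = 128, sg_window_s = 1.0, sg_order = 3,
                   marker_time_offset_s = 0)
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  if (cfg$sample_rate <= 0) stop_fmt("config: sample_rate must be > 0")
  if (!is.null(cfg$calibration)) {
    unknown <- setdiff(names(cfg$calibration), CALIBRATION_KEYS)
    if (length(unknown))
      stop_fmt("config: unknown calibration key(s): %s",
               paste(unknown, collapse = ", "))
    if (!is.null(cfg$calibration$method) &&
        !cfg$calibration$method %in% c("zero", "patient_specific"))
      stop_fmt("config: calibration method must be zero or patient_specific")
  }
  cfg
}
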