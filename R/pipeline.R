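# High-level pipeline entry points, also driven by the exec/camptokin CLI:
#   ca_synth    — generate a synthetic recording set from a posture script
#   ca_process  — raw channels -> smoothed -> inclinations -> CA series
#   ca_evaluate — CA series vs marker reference: per-activity RMSE, MAD
#   ca_calibrate — compute a calibration state from a recording
# Every run can write a provenance JSON (inputs, seed, calibration, version)
# for auditability.

write_provenance <- function(path, ...) {
  info <- list(tool = "camptokin",
               version = as.character(packageVersion("camptokin")),
               created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
               ...)
  jsonlite::write_json(info, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Generate a synthetic recording set
#'
#' Runs the forward-kinematics generator for a posture script and (if
#' \code{out_dir} is given) writes \code{imu.csv}, \code{markers.tsv},
#' \code{segments.tsv}, \code{truth.tsv} and \code{provenance.json}.
#'
#' @param script a \code{\link{posture_script}} (default
#'   \code{\link{default_posture_script}()}).
#' @param seed integer seed driving all generator randomness.
#' @param anthro an \code{\link{anthropometry}}.
#' @param dims a \code{\link{body_dimensions}}.
#' @param noise a \code{\link{noise_model}}; its seed is overridden by
#'   \code{seed} when that is non-NULL.
#' @param rate IMU sampling rate in Hz.
#' @param marker_rate marker sampling rate in Hz (default: \code{rate}).
#' @param out_dir output directory, or NULL to skip writing.
#' @return Invisibly, a list with \code{truth}, \code{accel},
#'   \code{markers}, \code{segments}.
#' @export
ca_synth <- function(script = default_posture_script(), seed = NULL,
                     anthro = anthropometry(0.45, 0.45),
                     dims = body_dimensions(), noise = noise_model(),
                     rate = 128, marker_rate = NULL, out_dir = NULL) {
  if (!is.null(seed)) noise$seed <- as.integer(seed)
  truth <- generate_truth(script, rate = rate, anthro = anthro)
  accel <- project_accelerometers(truth, noise)
  markers <- project_markers(truth, anthro, dims, noise, rate = marker_rate)
  segments <- script_segments(script)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_accel_csv(accel, file.path(out_dir, "imu.csv"))
    write_markers_tsv(markers, file.path(out_dir, "markers.tsv"))
    write_segments_tsv(segments, file.path(out_dir, "segments.tsv"))
    write_truth_tsv(truth, file.path(out_dir, "truth.tsv"))
    write_provenance(file.path(out_dir, "provenance.json"),
                     stage = "synth", seed = noise$seed,
                     noise = unclass(noise)[names(unclass(noise)) != "seed"],
                     anthropometry = unclass(anthro),
                     body_dimensions = unclass(dims),
                     n_samples = nrow(truth), sample_rate = rate)
  }
  invisible(list(truth = truth, accel = accel, markers = markers,
                 segments = segments))
}

resolve_calibration <- function(incl, series, cal_cfg, window_s = 1.0) {
  # returns list(incl=..., recompute=logical, cal=state or NULL)
  if (is.null(cal_cfg)) return(list(cal = NULL))
  if (inherits(cal_cfg, "calibration_state")) return(list(cal = cal_cfg))
  method <- cal_cfg$method
  window <- if (!is.null(cal_cfg$window)) as.numeric(cal_cfg$window)
            else c(0, 60)
  if (identical(method, "zero")) {
    list(cal = zero_calibrate(incl, window))
  } else if (identical(method, "patient_specific")) {
    if (is.null(cal_cfg$photo_ca_per) || is.null(cal_cfg$photo_ca_mal))
      stop_fmt("calibration: patient_specific needs photo_ca_per and photo_ca_mal")
    idx <- window_index(series$time_s, window) & series$valid
    if (!any(idx))
      stop_fmt("calibration: no valid samples in window [%g, %g] s",
               window[1], window[2])
    list(cal = patient_specific_calibrate(
      measured_ca_per = mean(series$ca_per[idx]),
      measured_ca_mal = mean(series$ca_mal[idx]),
      photo_ca_per = cal_cfg$photo_ca_per,
      photo_ca_mal = cal_cfg$photo_ca_mal))
  } else stop_fmt("calibration: unknown method '%s'", method)
}

#' Process a recording into camptocormia angle series
#'
#' The full measurement chain: Savitzky-Golay smoothing of the raw channels,
#' sensor inclinations from gravity projection, the perpendicular spine
#' model, the two-pendulum leg model and the malleolus composition, with
#' optional calibration.  Writes per-sample and windowed series plus a
#' provenance JSON when \code{out_dir} is given.
#'
#' @param accel an \code{\link{accel_recording}} or path to an IMU CSV.
#' @param anthro an \code{\link{anthropometry}}; required unless
#'   \code{perpendicular_only}.
#' @param calibration either a \code{\link{calibration_state}}, or a config
#'   list \code{list(method = "zero"|"patient_specific", window = c(t0,t1),
#'   photo_ca_per =, photo_ca_mal =)}, or NULL for none.  Zero calibration
#'   is applied to the inclinations (which are then re-run through the
#'   models); patient-specific offsets are applied to the CA series.
#' @param smoothing apply the Savitzky-Golay filter (TRUE) or pass raw
#'   channels through (FALSE).
#' @param sg_window_s,sg_order smoothing window (s) and polynomial order.
#' @param perpendicular_only compute only the two-sensor perpendicular CA.
#' @param flip optional per-sensor sign flips, see
#'   \code{\link{compute_inclinations}}.
#' @param window_s averaging window for the windowed output series.
#' @param out_dir output directory, or NULL to skip writing.
#' @return A list with \code{series} (\code{camptocormia_series}),
#'   \code{inclinations}, \code{calibration} (state or NULL), and
#'   \code{windows} (data frame of 1-s window means).
#' @export
ca_process <- function(accel, anthro = NULL, calibration = NULL,
                       smoothing = TRUE, sg_window_s = 1.0, sg_order = 3,
                       perpendicular_only = FALSE, flip = NULL,
                       window_s = 1.0, out_dir = NULL) {
  if (is.character(accel))
    accel <- read_accel_csv(accel, sensors = if (perpendicular_only)
      c("C7", "L5") else SENSORS)
  stopifnot(inherits(accel, "accel_recording"))
  if (!perpendicular_only && is.null(anthro))
    stop_fmt("ca_process: anthropometry is required for the malleolus method (or set perpendicular_only = TRUE)")
  rec <- if (smoothing)
    smooth_recording(accel, smoothing_config(sg_order, sg_window_s,
                                             accel$sample_rate))
  else accel
  incl <- compute_inclinations(rec, flip = flip)
  series <- compute_camptocormia(incl, anthro, perpendicular_only)
  cal <- NULL
  res <- resolve_calibration(incl, series, calibration)
  if (!is.null(res$cal)) {
    cal <- res$cal
    if (cal$method == "zero") {
      incl <- apply_calibration(incl, cal)
      series <- compute_camptocormia(incl, anthro, perpendicular_only)
      series$calibration$applied <- "zero"
      series$calibration$state <- cal
    } else {
      series <- apply_calibration(series, cal)
    }
  }
  wa_per <- window_average(angle_series(series$time_s, series$ca_per,
                                        series$valid), window_s)
  win <- data.frame(time_s = wa_per$time_s, ca_per = wa_per$angle)
  if (!perpendicular_only) {
    win$phi_leg <- window_average(angle_series(series$time_s, series$phi_leg,
                                               series$valid), window_s)$angle
    win$ca_mal <- window_average(angle_series(series$time_s, series$ca_mal,
                                              series$valid), window_s)$angle
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    samp <- data.frame(time_s = fmt_num(series$time_s),
                       ca_per = fmt_num(series$ca_per),
                       phi_leg = fmt_num(series$phi_leg),
                       ca_mal = fmt_num(series$ca_mal),
                       valid = series$valid)
    write.table(samp, file.path(out_dir, "ca_samples.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    winf <- win; winf[] <- lapply(winf, fmt_num)
    write.table(winf, file.path(out_dir, "ca_windows.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_provenance(file.path(out_dir, "provenance.json"),
                     stage = "process",
                     smoothing = if (smoothing)
                       list(order = sg_order, window_s = sg_window_s)
                     else "none",
                     calibration = if (!is.null(cal))
                       list(method = cal$method,
                            offsets = list(leg = cal$offset_leg,
                                           per = cal$offset_per,
                                           mal = cal$offset_mal),
                            zero_refs = as.list(cal$zero_refs),
                            provenance = cal$provenance)
                     else "none",
                     perpendicular_only = perpendicular_only,
                     n_samples = length(series$time_s),
                     sample_rate = series$sample_rate)
  }
  list(series = series, inclinations = incl, calibration = cal,
       windows = win)
}

#' Evaluate CA series against a marker-based reference
#'
#' Resamples the marker trajectory to the IMU rate, reconstructs the
#' reference angles, aligns the streams, and reports per-activity RMSE for
#' the perpendicular and (if present) malleolus methods plus the
#' MAD-by-angle histogram of the perpendicular CA.
#'
#' @param series a \code{camptocormia_series} from \code{\link{ca_process}}.
#' @param markers a \code{\link{marker_trajectory}} or path to a TSV.
#' @param segments an \code{\link{activity_segments}} or path to a TSV.
#' @param marker_time_offset_s manual clock alignment added to marker times.
#' @param window_s comparison window in seconds (default 1.0).
#' @param sample_wise compare raw samples instead of window averages.
#' @param out_dir output directory, or NULL to skip writing.
#' @return A list with \code{per} and (possibly NULL) \code{mal}
#'   \code{evaluation_report}s, \code{mad} (\code{mad_histogram} of the
#'   perpendicular CA) and \code{reference} (the reconstructed angles).
#' @export
ca_evaluate <- function(series, markers, segments,
                        marker_time_offset_s = 0, window_s = 1.0,
                        sample_wise = FALSE, out_dir = NULL) {
  stopifnot(inherits(series, "camptocormia_series"))
  if (is.character(markers)) markers <- read_markers_tsv(markers)
  if (is.character(segments)) segments <- read_segments_tsv(segments)
  if (marker_time_offset_s != 0)
    markers$time_s <- markers$time_s + marker_time_offset_s
  markers <- resample_markers(markers, series$sample_rate)
  ref <- compute_reference_angles(markers)
  # align on the common time span
  n <- min(length(series$time_s), nrow(ref))
  if (n < 2 || abs(series$time_s[1] - ref$time_s[1]) > 0.5 / series$sample_rate)
    stop_fmt("ca_evaluate: streams do not overlap (IMU starts %g s, reference %g s)",
             series$time_s[1], ref$time_s[1])
  est_per <- angle_series(series$time_s[1:n], series$ca_per[1:n],
                          series$valid[1:n], "ca_per")
  ref_per <- angle_series(ref$time_s[1:n], ref$phi_per_ref[1:n],
                          label = "phi_per_ref")
  rep_per <- rmse_by_activity(est_per, ref_per, segments, window_s,
                              sample_wise)
  mad <- mad_histogram(est_per, ref_per)
  rep_mal <- NULL
  if (any(is.finite(series$ca_mal))) {
    est_mal <- angle_series(series$time_s[1:n], series$ca_mal[1:n],
                            series$valid[1:n], "ca_mal")
    ref_mal <- angle_series(ref$time_s[1:n], ref$ca_ref_l5[1:n],
                            label = "ca_ref_l5")
    rep_mal <- rmse_by_activity(est_mal, ref_mal, segments, window_s,
                                sample_wise)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_evaluation_report(rep_per,
                            file.path(out_dir, "rmse_perpendicular.tsv"),
                            file.path(out_dir, "report_perpendicular.txt"),
                            mad = mad)
    if (!is.null(rep_mal))
      write_evaluation_report(rep_mal,
                              file.path(out_dir, "rmse_malleolus.tsv"),
                              file.path(out_dir, "report_malleolus.txt"))
    write_reference_tsv(ref, file.path(out_dir, "reference_angles.tsv"))
    write_provenance(file.path(out_dir, "provenance.json"),
                     stage = "evaluate", window_s = window_s,
                     sample_wise = sample_wise,
                     marker_time_offset_s = marker_time_offset_s,
                     n_compared = n)
  }
  list(per = rep_per, mal = rep_mal, mad = mad, reference = ref)
}

#' Compute a calibration state from a recording
#'
#' Convenience wrapper used by the CLI \code{calibrate} subcommand: smooths
#' the recording, computes inclinations and (for patient-specific
#' calibration) the CA series, then derives the requested calibration.
#'
#' @param accel an \code{\link{accel_recording}} or path to an IMU CSV.
#' @param method \code{"zero"} or \code{"patient_specific"}.
#' @param window calibration window \code{c(t0, t1)} in seconds (upright
#'   standing for zero; standing forward lean for patient-specific).
#' @param photo_ca_per,photo_ca_mal photo-derived CA values in degrees
#'   (patient-specific only).
#' @param anthro an \code{\link{anthropometry}} (patient-specific only).
#' @param out optional path for a JSON dump of the state.
#' @return A \code{\link{calibration_state}}.
#' @export
ca_calibrate <- function(accel, method = c("zero", "patient_specific"),
                         window = c(0, 60), photo_ca_per = NULL,
                         photo_ca_mal = NULL, anthro = NULL, out = NULL) {
  method <- match.arg(method)
  if (is.character(accel)) accel <- read_accel_csv(accel)
  rec <- smooth_recording(accel,
                          smoothing_config(sample_rate = accel$sample_rate))
  incl <- compute_inclinations(rec)
  cal <- if (method == "zero") {
    zero_calibrate(incl, window)
  } else {
    series <- compute_camptocormia(incl, anthro)
    resolve_calibration(incl, series,
                        list(method = "patient_specific", window = window,
                             photo_ca_per = photo_ca_per,
                             photo_ca_mal = photo_ca_mal))$cal
  }
  if (!is.null(out))
    write_provenance(out, stage = "calibrate", method = cal$method,
                     zero_refs = as.list(cal$zero_refs),
                     offsets = list(leg = cal$offset_leg,
                                    per = cal$offset_per,
                                    mal = cal$offset_mal),
                     provenance = cal$provenance)
  cal
}
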