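# Calibration.  Two procedures:
#   zero calibration — per-channel mean inclination over an upright-standing
#     window (default first 60 s) is subtracted from the inclinations;
#   patient-specific calibration — the difference between a photo-derived CA
#     (external tool) and the IMU CA averaged over a standing-forward-lean
#     window is added to the subsequent CA series.
# offset_leg is the approximately constant gap between leg angles referenced
# at L5 vs at the iliac crest (L5 lies posterior/superior to the hip axis).

#' Calibration state
#'
#' @param zero_refs named numeric vector of per-channel zero reference
#'   angles in degrees (names among \code{phi_c7, phi_l5, phi_th, phi_sh}).
#' @param offset_leg,offset_per,offset_mal scalar offsets in degrees.
#' @param method one of \code{"zero"}, \code{"patient_specific"},
#'   \code{"none"}.
#' @param provenance free-form list recording how the state was obtained
#'   (window used, photo angles used).
#' @return Object of class \code{calibration_state}.
#' @export
calibration_state <- function(zero_refs = numeric(0), offset_leg = 0,
                              offset_per = 0, offset_mal = 0,
                              method = c("none", "zero", "patient_specific"),
                              provenance = list()) {
  method <- match.arg(method)
  vals <- c(zero_refs, offset_leg, offset_per, offset_mal)
  if (any(!is.finite(vals)))
    stop_fmt("calibration_state: offsets and zero references must be finite")
  if (offset_leg != 0 && offset_mal != 0)
    stop_fmt("calibration_state: enabling both offset_leg and offset_mal on the same stream double-corrects the leg contribution; choose one")
  structure(list(zero_refs = zero_refs, offset_leg = offset_leg,
                 offset_per = offset_per, offset_mal = offset_mal,
                 method = method, provenance = provenance),
            class = "calibration_state")
}

#' @export
print.calibration_state <- function(x, ...) {
  cat(sprintf("<calibration_state> method: %s\n", x$method))
  if (length(x$zero_refs))
    cat("  zero refs [deg]:",
        paste(sprintf("%s=%.3f", names(x$zero_refs), x$zero_refs),
              collapse = ", "), "\n")
  cat(sprintf("  offsets [deg]: leg=%.3f per=%.3f mal=%.3f\n",
              x$offset_leg, x$offset_per, x$offset_mal))
  invisible(x)
}

window_index <- function(time_s, window) {
  time_s >= window[1] & time_s <= window[2]
}

#' Zero calibration from an upright-standing window
#'
#' The subject stands still and upright for 60 s at the start of the
#' recording; the per-channel mean inclination over that window becomes the
#' zero reference angle subtracted from all subsequent samples.
#'
#' @param incl an \code{\link{compute_inclinations}} result.
#' @param window \code{c(t0, t1)} in seconds, default the first 60 s.
#' @return A \code{\link{calibration_state}} with \code{method = "zero"}.
#' @export
zero_calibrate <- function(incl, window = c(0, 60)) {
  stopifnot(inherits(incl, "inclination_set"))
  if (diff(window) < 5)
    stop_fmt("zero_calibrate: calibration window must be at least 5 s")
  if (window[1] < incl$time_s[1] - 1e-9 ||
      window[2] > incl$time_s[length(incl$time_s)] + 1e-9)
    stop_fmt("zero_calibrate: window [%g, %g] s not covered by the recording",
             window[1], window[2])
  idx <- window_index(incl$time_s, window)
  refs <- vapply(names(incl$angles), function(nm) {
    ok <- idx & incl$valid[[nm]]
    if (sum(ok) < 0.5 * sum(idx))
      stop_fmt("zero_calibrate: more than half of the %s samples in the window are low-confidence", nm)
    mean(incl$angles[[nm]][ok])
  }, numeric(1))
  calibration_state(zero_refs = refs, method = "zero",
                    provenance = list(window = window))
}

#' Patient-specific calibration from a forward-lean photograph
#'
#' A still photograph in the standing-forward-lean posture is measured
#' externally (two numbers: CA by the perpendicular and malleolus methods);
#' the offsets are the photo angles minus the IMU angles averaged over the
#' same posture window, and are added to the subsequent CA series.
#'
#' @param measured_ca_per,measured_ca_mal IMU CA values (degrees) averaged
#'   over the annotated forward-lean calibration window.
#' @param photo_ca_per,photo_ca_mal photo-derived CA values in degrees.
#' @return A \code{\link{calibration_state}} with
#'   \code{method = "patient_specific"}.
#' @export
patient_specific_calibrate <- function(measured_ca_per, measured_ca_mal,
                                       photo_ca_per, photo_ca_mal) {
  vals <- c(measured_ca_per, measured_ca_mal, photo_ca_per, photo_ca_mal)
  if (any(!is.finite(vals)))
    stop_fmt("patient_specific_calibrate: all four angles must be finite")
  calibration_state(
    offset_per = photo_ca_per - measured_ca_per,
    offset_mal = photo_ca_mal - measured_ca_mal,
    method = "patient_specific",
    provenance = list(photo_ca_per = photo_ca_per,
                      photo_ca_mal = photo_ca_mal,
                      measured_ca_per = measured_ca_per,
                      measured_ca_mal = measured_ca_mal))
}

#' Estimate the L5-vs-IC leg reference offset
#'
#' Mean difference between the leg reference angle measured from L5 and from
#' the iliac crest over a window (typically standing still with forward
#' lean).  The offset is approximately constant because L5 sits at a fixed
#' position posterior/superior to the hip rotation axis; determined once, it
#' can be added to the recorded leg angle.
#'
#' @param ref_l5,ref_ic \code{\link{angle_series}} of the leg reference
#'   angle using the L5-LM and IC-LM frames.
#' @param window \code{c(t0, t1)} in seconds.
#' @return Offset in degrees (scalar).
#' @export
estimate_offset_leg <- function(ref_l5, ref_ic, window) {
  stopifnot(inherits(ref_l5, "angle_series"), inherits(ref_ic, "angle_series"))
  if (nrow(ref_l5) != nrow(ref_ic))
    stop_fmt("estimate_offset_leg: series lengths differ")
  idx <- window_index(ref_l5$time_s, window) & ref_l5$valid & ref_ic$valid
  if (!any(idx))
    stop_fmt("estimate_offset_leg: no valid samples in window [%g, %g] s",
             window[1], window[2])
  mean(ref_l5$angle[idx] - ref_ic$angle[idx])
}

#' Apply a calibration state
#'
#' For an inclination set, subtracts the per-channel zero references.  For a
#' camptocormia series, adds \code{offset_per} to \code{ca_per},
#' \code{offset_mal} to \code{ca_mal}, and \code{offset_leg} to both
#' \code{phi_leg} and \code{ca_mal} (moving the leg angle into the L5
#' reference frame).  Application is recorded in the object's provenance;
#' applying the same calibration method twice is an error.
#'
#' @param x an \code{inclination_set} or \code{camptocormia_series}.
#' @param cal a \code{\link{calibration_state}}.
#' @return The shifted object, same class as \code{x}.
#' @export
apply_calibration <- function(x, cal) {
  stopifnot(inherits(cal, "calibration_state"))
  UseMethod("apply_calibration")
}

#' @export
apply_calibration.inclination_set <- function(x, cal) {
  if (!is.null(attr(x, "calibrated")))
    stop_fmt("apply_calibration: this inclination_set is already calibrated")
  for (nm in names(cal$zero_refs)) {
    if (is.null(x$angles[[nm]]))
      stop_fmt("apply_calibration: channel %s not present", nm)
    x$angles[[nm]] <- x$angles[[nm]] - cal$zero_refs[[nm]]
  }
  attr(x, "calibrated") <- cal$method
  x
}

#' @export
apply_calibration.camptocormia_series <- function(x, cal) {
  if (cal$method %in% x$calibration$applied)
    stop_fmt("apply_calibration: '%s' calibration already applied to this series",
             cal$method)
  x$ca_per <- x$ca_per + cal$offset_per
  x$ca_mal <- x$ca_mal + cal$offset_mal + cal$offset_leg
  x$phi_leg <- x$phi_leg + cal$offset_leg
  x$calibration$applied <- c(x$calibration$applied, cal$method)
  x$calibration$state <- cal
  x
}
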