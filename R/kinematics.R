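# Core angle math.  All angles in degrees; gravity is the absolute
# inclination reference.  Axis convention (matched by the synthetic
# generator; per-sensor flips for real hardware are applied upstream):
#   trunk sensors (C7, L5): +x cranial along the segment, upright reads
#     a_x = -1 g; forward lean moves gravity onto a_z.
#   leg sensors (TH, SH): anterior tilt drives a_y negative.

RAD2DEG <- 180 / pi
DEG2RAD <- pi / 180

# spine-chain model coefficients (trunk inclinations -> CA_per, deg)
CA_PER_INTERCEPT <- 0.3856
CA_PER_COEF_L5 <- 0.4542
CA_PER_COEF_C7 <- 0.5458

check_nonzero <- function(mag, what, zero = c("error", "na")) {
  zero <- match.arg(zero)
  bad <- mag == 0
  if (any(bad)) {
    if (zero == "error")
      stop_fmt("%s: zero-magnitude acceleration vector at sample(s) %s",
               what, paste(utils::head(which(bad), 5), collapse = ", "))
  }
  bad
}

#' Trunk sensor inclination from gravity projection
#'
#' Inclination of a trunk sensor's longitudinal axis against the vertical,
#' computed from the projection of gravity onto the sensor axes:
#' \code{-atan(sqrt(a_y^2 + a_z^2) / a_x)}, realized with the two-argument
#' arctangent so that a horizontal sensor (\code{a_x = 0}) cleanly yields 90
#' degrees.  Returns 0 for upright stance (\code{a_x = -1} g) and values in
#' [0, 180).
#'
#' @param a_x,a_y,a_z acceleration components in g (vectors).
#' @param zero \code{"error"} to fail on a zero-magnitude vector,
#'   \code{"na"} to return NA for that sample.
#' @return Inclination in degrees.
#' @export
trunk_inclination <- function(a_x, a_y, a_z, zero = c("error", "na")) {
  r <- sqrt(a_y^2 + a_z^2)
  bad <- check_nonzero(r^2 + a_x^2, "trunk_inclination", zero)
  phi <- unname(atan2(r, -a_x) * RAD2DEG)
  phi[bad] <- NA_real_
  phi
}

#' Leg sensor inclination from gravity projection
#'
#' Signed inclination of a leg segment against the vertical:
#' \code{-atan(a_y / sqrt(a_x^2 + a_z^2))}, positive when the segment's
#' distal end is anterior (anterior tilt drives \code{a_y} negative under
#' the mounting convention).  Values in [-90, 90]; 0 for a vertical segment.
#'
#' @inheritParams trunk_inclination
#' @return Signed inclination in degrees.
#' @export
leg_inclination <- function(a_x, a_y, a_z, zero = c("error", "na")) {
  r <- sqrt(a_x^2 + a_z^2)
  bad <- check_nonzero(r^2 + a_y^2, "leg_inclination", zero)
  phi <- unname(atan2(-a_y, r) * RAD2DEG)
  phi[bad] <- NA_real_
  phi
}

#' Perpendicular-method camptocormia angle
#'
#' Affine spine-chain model mapping the two trunk sensor inclinations to the
#' angle of the L5-C7 line against the vertical:
#' \deqn{CA_{per} = 0.3856 + 0.4542\,\phi_{L5} + 0.5458\,\phi_{C7}.}
#' The coefficients come from a flexible-chain model of the spine with fixed
#' vertebral heights and mobility; they sum to one, so a rigid trunk tilted
#' by \eqn{\alpha} maps to \eqn{\alpha} plus the small intercept.
#'
#' @param phi_l5,phi_c7 L5 and C7 inclinations in degrees.
#' @return CA (perpendicular method) in degrees.
#' @export
ca_perpendicular <- function(phi_l5, phi_c7) {
  CA_PER_INTERCEPT + CA_PER_COEF_L5 * phi_l5 + CA_PER_COEF_C7 * phi_c7
}

#' Knee angle from thigh and shank inclinations
#'
#' Interior knee angle of the two-pendulum leg model,
#' \eqn{\theta = 180 - \phi_{TH} - \phi_{SH}} (degrees); 180 for a straight
#' vertical leg.  Values outside (0, 180] are physically invalid and flagged
#' by \code{\link{leg_angle}}.
#'
#' @param phi_th,phi_sh thigh and shank inclinations in degrees.
#' @return Knee angle in degrees.
#' @export
knee_angle <- function(phi_th, phi_sh) 180 - phi_th - phi_sh

#' Leg angle from the planar two-pendulum model
#'
#' Treats thigh and shank as coupled pendula in the sagittal plane.  With
#' segment lengths \code{u}, \code{l} and inclinations \eqn{\phi_{TH}},
#' \eqn{\phi_{SH}}, the vertical drops are \eqn{Z_u = u\cos\phi_{TH}},
#' \eqn{Z_l = l\cos\phi_{SH}}; the hip-ankle distance follows the cosine law
#' \eqn{H = \sqrt{u^2 + l^2 - 2ul\cos\theta}} with knee angle
#' \eqn{\theta = 180 - \phi_{TH} - \phi_{SH}}, and the leg angle magnitude is
#' \eqn{\arccos((Z_u + Z_l)/H)}.  The sign is that of the ankle's anterior
#' offset \eqn{u\sin\phi_{TH} - l\sin\phi_{SH}}: positive when the foot is
#' in front of the frontal plane.  Because \eqn{H^2} equals the sum of
#' squares of the anterior offset and \eqn{Z_u + Z_l}, the arccos expression
#' equals the two-argument arctangent of those two legs; the implementation
#' switches to that form where arccos is ill-conditioned (argument within
#' 1e-7 of one, i.e. near-zero leg angles), so collinear postures evaluate
#' exactly.
#'
#' Samples with \eqn{\theta} outside \eqn{(0, 180 + tol]}, a degenerate
#' \eqn{H = 0}, or an arccos argument beyond 1 + 1e-9 are flagged invalid
#' (with a warning for the latter) rather than silently clamped.  The
#' hyperextension tolerance (default 0.5 degrees) keeps straight-leg
#' postures from flickering invalid: mild genu recurvatum is physiologic
#' and the formulas remain well-defined just past 180.
#'
#' @param phi_th,phi_sh thigh and shank inclinations in degrees (vectors).
#' @param anthro an \code{\link{anthropometry}}.
#' @param hyperextension_tol degrees of knee hyperextension past 180 still
#'   treated as valid.
#' @return A data frame with columns \code{phi_leg} (signed degrees),
#'   \code{theta}, \code{h}, \code{z_u}, \code{z_l}, \code{valid}.
#' @export
leg_angle <- function(phi_th, phi_sh, anthro, hyperextension_tol = 0.5) {
  stopifnot(inherits(anthro, "anthropometry"))
  u <- anthro$u_m; l <- anthro$l_m
  theta <- knee_angle(phi_th, phi_sh)
  z_u <- u * cos(phi_th * DEG2RAD)
  z_l <- l * cos(phi_sh * DEG2RAD)
  h <- sqrt(pmax(u^2 + l^2 - 2 * u * l * cos(theta * DEG2RAD), 0))
  x_ant <- u * sin(phi_th * DEG2RAD) - l * sin(phi_sh * DEG2RAD)
  valid <- theta > 0 & theta <= 180 + hyperextension_tol
  if (any(h == 0 & valid))
    stop_fmt("leg_angle: degenerate geometry (H = 0) at sample(s) %s",
             paste(utils::head(which(h == 0 & valid), 5), collapse = ", "))
  arg <- (z_u + z_l) / h
  over <- valid & abs(arg) > 1 + 1e-9
  if (any(over)) {
    warning(sprintf(
      "leg_angle: numerically inconsistent arccos argument at %d sample(s); flagged invalid",
      sum(over)), call. = FALSE)
    valid <- valid & !over
  }
  mag <- acos(pmin(pmax(arg, -1), 1)) * RAD2DEG
  near1 <- is.finite(arg) & abs(arg) > 1 - 1e-7
  if (any(near1))
    mag[near1] <- abs(atan2(x_ant, z_u + z_l)[near1]) * RAD2DEG
  phi_leg <- ifelse(x_ant < 0, -mag, mag)
  phi_leg[!valid] <- NA_real_
  data.frame(phi_leg = phi_leg, theta = theta, h = h,
             z_u = z_u, z_l = z_l, valid = valid)
}

#' Malleolus-method camptocormia angle
#'
#' Composition of the trunk and leg contributions:
#' \eqn{CA_{mal} = CA_{per} + \Phi_{leg}} (exact sum, degrees).
#'
#' @param ca_per perpendicular-method CA in degrees.
#' @param phi_leg signed leg angle in degrees.
#' @return Malleolus-method CA in degrees.
#' @export
ca_malleolus <- function(ca_per, phi_leg) ca_per + phi_leg

#' Classify samples against the camptocormia cutoff
#'
#' The clinical consensus defines camptocormia as forward flexion exceeding
#' 30 degrees under the malleolus method; the comparison is strict, so a
#' sample at exactly the threshold is not flagged.
#'
#' @param ca_mal malleolus-method CA series in degrees.
#' @param threshold cutoff in degrees (default 30), >= 0.
#' @return Logical vector, \code{TRUE} where \code{ca_mal > threshold}.
#' @export
classify_camptocormia <- function(ca_mal, threshold = 30) {
  if (threshold < 0) stop_fmt("classify_camptocormia: threshold must be >= 0")
  ca_mal > threshold
}

#' Sensor inclinations for a whole recording
#'
#' Applies \code{\link{trunk_inclination}} to the C7 and L5 channels and
#' \code{\link{leg_inclination}} to the TH and SH channels, carrying the
#' low-confidence mask from \code{\link{flag_low_confidence}}.
#'
#' @param rec an \code{\link{accel_recording}} (usually smoothed).
#' @param conf_lo,conf_hi gravity-magnitude confidence bounds in g.
#' @param flip optional named numeric vector of per-sensor sign flips
#'   (values +1/-1, names among C7, L5, TH, SH) applied to all three axes of
#'   that sensor before the inclination formulas — the \code{axis_convention}
#'   switch for hardware mounted opposite to the package convention.
#' @return Object of class \code{inclination_set}: list with \code{time_s},
#'   \code{angles} (data frame \code{phi_c7, phi_l5, phi_th, phi_sh} as
#'   available), \code{valid} (logical data frame), \code{sample_rate}.
#' @export
compute_inclinations <- function(rec, conf_lo = 0.5, conf_hi = 1.5,
                                 flip = NULL) {
  stopifnot(inherits(rec, "accel_recording"))
  mask <- flag_low_confidence(rec, conf_lo, conf_hi)
  get3 <- function(s) {
    f <- if (!is.null(flip) && s %in% names(flip)) flip[[s]] else 1
    lapply(c("ax", "ay", "az"),
           function(a) f * rec$channels[[paste(s, a, sep = "_")]])
  }
  angles <- list(); valid <- list()
  for (s in rec$sensors) {
    ch <- get3(s)
    phi <- if (s %in% c("C7", "L5"))
      trunk_inclination(ch[[1]], ch[[2]], ch[[3]], zero = "na")
    else
      leg_inclination(ch[[1]], ch[[2]], ch[[3]], zero = "na")
    nm <- paste0("phi_", tolower(s))
    angles[[nm]] <- phi
    valid[[nm]] <- !mask[[s]] & is.finite(phi)
  }
  structure(list(time_s = rec$time_s,
                 angles = as.data.frame(angles),
                 valid = as.data.frame(valid),
                 sample_rate = rec$sample_rate),
            class = "inclination_set")
}

#' @export
print.inclination_set <- function(x, ...) {
  cat(sprintf("<inclination_set> %d samples @ %g Hz, channels: %s\n",
              length(x$time_s), x$sample_rate,
              paste(names(x$angles), collapse = ", ")))
  invisible(x)
}

#' Camptocormia angle series from sensor inclinations
#'
#' Evaluates the perpendicular spine model and (unless
#' \code{perpendicular_only}) the two-pendulum leg model and the malleolus
#' composition for every sample.  The identity
#' \code{ca_mal = ca_per + phi_leg} holds exactly at every sample; samples
#' that are low-confidence on any used channel, or physically invalid in the
#' leg model, are masked.
#'
#' @param incl an \code{\link{compute_inclinations}} result.
#' @param anthro an \code{\link{anthropometry}}; required unless
#'   \code{perpendicular_only}.
#' @param perpendicular_only compute only \code{ca_per} (two-sensor mode).
#' @return Object of class \code{camptocormia_series}: list with
#'   \code{time_s}, \code{ca_per}, \code{phi_leg}, \code{ca_mal},
#'   \code{theta}, \code{valid}, \code{sample_rate}, \code{calibration}.
#' @export
compute_camptocormia <- function(incl, anthro = NULL,
                                 perpendicular_only = FALSE) {
  stopifnot(inherits(incl, "inclination_set"))
  a <- incl$angles
  if (is.null(a$phi_c7) || is.null(a$phi_l5))
    stop_fmt("compute_camptocormia: C7 and L5 inclinations are required")
  ca_per <- ca_perpendicular(a$phi_l5, a$phi_c7)
  valid <- incl$valid$phi_c7 & incl$valid$phi_l5
  if (perpendicular_only) {
    phi_leg <- theta <- rep(NA_real_, length(ca_per))
    ca_mal <- rep(NA_real_, length(ca_per))
  } else {
    if (is.null(a$phi_th) || is.null(a$phi_sh))
      stop_fmt("compute_camptocormia: TH and SH inclinations required for the malleolus method (or set perpendicular_only = TRUE)")
    if (is.null(anthro))
      stop_fmt("compute_camptocormia: anthropometry required for the malleolus method")
    leg <- leg_angle(a$phi_th, a$phi_sh, anthro)
    phi_leg <- leg$phi_leg
    theta <- leg$theta
    ca_mal <- ca_malleolus(ca_per, phi_leg)
    valid <- valid & incl$valid$phi_th & incl$valid$phi_sh & leg$valid
  }
  structure(list(time_s = incl$time_s, ca_per = ca_per, phi_leg = phi_leg,
                 ca_mal = ca_mal, theta = theta, valid = valid,
                 sample_rate = incl$sample_rate,
                 calibration = list(applied = character(0))),
            class = "camptocormia_series")
}

#' @export
print.camptocormia_series <- function(x, ...) {
  cat(sprintf("<camptocormia_series> %d samples @ %g Hz, %d valid\n",
              length(x$time_s), x$sample_rate, sum(x$valid)))
  ok <- x$valid
  if (any(ok)) {
    cat(sprintf("  ca_per:  mean %6.2f deg, range [%.2f, %.2f]\n",
                mean(x$ca_per[ok]), min(x$ca_per[ok]), max(x$ca_per[ok])))
    if (any(is.finite(x$ca_mal[ok])))
      cat(sprintf("  ca_mal:  mean %6.2f deg, range [%.2f, %.2f]\n",
                  mean(x$ca_mal[ok], na.rm = TRUE),
                  min(x$ca_mal[ok], na.rm = TRUE),
                  max(x$ca_mal[ok], na.rm = TRUE)))
  }
  if (length(x$calibration$applied))
    cat("  calibration applied:",
        paste(x$calibration$applied, collapse = ", "), "\n")
  invisible(x)
}

#' Plot a camptocormia series
#'
#' Base-graphics time plot of \code{ca_per} and (if present) \code{ca_mal},
#' with the 30-degree malleolus cutoff drawn as a dashed line.
#'
#' @param x a \code{camptocormia_series}.
#' @param threshold cutoff line in degrees (default 30).
#' @param ... passed to \code{plot}.
#' @return \code{x}, invisibly.
#' @export
plot.camptocormia_series <- function(x, threshold = 30, ...) {
  ok <- x$valid
  has_mal <- any(is.finite(x$ca_mal[ok]))
  ylim <- range(c(x$ca_per[ok], if (has_mal) x$ca_mal[ok], threshold),
                na.rm = TRUE)
  graphics::plot(x$time_s[ok], x$ca_per[ok], type = "l", col = "steelblue",
                 xlab = "time [s]", ylab = "angle [deg]", ylim = ylim, ...)
  if (has_mal)
    graphics::lines(x$time_s[ok], x$ca_mal[ok], col = "firebrick")
  graphics::abline(h = threshold, lty = 2, col = "grey40")
  graphics::legend("topleft", bty = "n", lty = 1,
                   col = c("steelblue", if (has_mal) "firebrick"),
                   legend = c("CA perpendicular", if (has_mal) "CA malleolus"))
  invisible(x)
}
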