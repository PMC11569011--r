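# Forward-kinematics generator: from a prescribed posture script it derives
# ground-truth angle trajectories, then projects them into (a) the 12
# accelerometer channels under the package's axis conventions and (b) the
# four optical marker trajectories — the synthetic test bed for the whole
# pipeline.  Adjacent activity blocks are blended with a quintic smoothstep
# so the truth is twice continuously differentiable, which keeps it inside
# the passband of the order-3 Savitzky-Golay filter.

#' Trajectory primitives for posture scripts
#'
#' A trajectory describes one angle over a block's local time \code{t}
#' (seconds from block start): a constant, a linear ramp over the block
#' duration, or a sinusoid \code{mean + amplitude * sin(2*pi*freq*t +
#' phase)}.  Trajectories are analytic so they can be extrapolated slightly
#' across block boundaries during blending.
#'
#' @param value,from,to,mean,amplitude angles in degrees.
#' @param freq_hz frequency in Hz; \code{phase} in radians.
#' @return A trajectory specification list.
#' @export
traj_constant <- function(value) list(type = "constant", value = value)

#' @rdname traj_constant
#' @export
traj_ramp <- function(from, to) list(type = "ramp", from = from, to = to)

#' @rdname traj_constant
#' @export
traj_sine <- function(mean, amplitude, freq_hz, phase = 0)
  list(type = "sine", mean = mean, amplitude = amplitude,
       freq_hz = freq_hz, phase = phase)

traj_eval <- function(spec, t, duration) {
  switch(spec$type,
    constant = rep_len(spec$value, length(t)),
    ramp = spec$from + (spec$to - spec$from) * t / duration,
    sine = spec$mean + spec$amplitude *
      sin(2 * pi * spec$freq_hz * t + spec$phase),
    stop_fmt("unknown trajectory type: %s", spec$type))
}

#' One activity block of a posture script
#'
#' @param label activity label (closed set of
#'   \code{\link{activity_segments}}).
#' @param duration_s block duration in seconds, > 0.
#' @param trunk trajectory of the true perpendicular CA in degrees.
#' @param leg trajectory of the leg base tilt in degrees (straight leg:
#'   thigh at the tilt, shank at its negative).
#' @param gait_amp_deg,gait_freq_hz amplitude and frequency of a sinusoidal
#'   whole-leg swing added to the base tilt (antiphase thigh/shank
#'   components, so the leg stays straight while swinging).
#' @param knee_amp_deg peak knee-flexion oscillation in degrees, added on
#'   the shank at the gait frequency (knee angle dips to 180 minus this).
#' @return A posture block list.
#' @export
posture_block <- function(label, duration_s,
                          trunk = traj_constant(0),
                          leg = traj_constant(0),
                          gait_amp_deg = 0, gait_freq_hz = 0,
                          knee_amp_deg = 0) {
  if (!label %in% ACTIVITY_LABELS)
    stop_fmt("posture_block: unknown label '%s'", label)
  if (duration_s <= 0) stop_fmt("posture_block: duration must be > 0")
  list(label = label, duration_s = duration_s, trunk = trunk, leg = leg,
       gait_amp_deg = gait_amp_deg, gait_freq_hz = gait_freq_hz,
       knee_amp_deg = knee_amp_deg)
}

#' Posture script: an ordered sequence of activity blocks
#'
#' @param blocks list of \code{\link{posture_block}}s.
#' @param transition_s length of the smoothstep blend across each block
#'   boundary in seconds (default 4); must not exceed the shortest block.
#' @return Object of class \code{posture_script}.
#' @export
posture_script <- function(blocks, transition_s = 4) {
  if (!length(blocks)) stop_fmt("posture_script: no blocks")
  durs <- vapply(blocks, `[[`, numeric(1), "duration_s")
  if (transition_s < 0 || (length(blocks) > 1 && transition_s > min(durs)))
    stop_fmt("posture_script: transition (%g s) exceeds the shortest block (%g s)",
             transition_s, min(durs))
  structure(list(blocks = blocks, transition_s = transition_s,
                 duration_s = sum(durs)), class = "posture_script")
}

#' @export
print.posture_script <- function(x, ...) {
  cat(sprintf("<posture_script> %d blocks, %.0f s total (%.1f s transitions)\n",
              length(x$blocks), x$duration_s, x$transition_s))
  for (b in x$blocks)
    cat(sprintf("  %-22s %5.1f s\n", b$label, b$duration_s))
  invisible(x)
}

#' Posture script mirroring the study's activity sequence
#'
#' Four blocks of 60, 50, 25 and 80 s: standing still upright, standing
#' still with forward lean, walking, and mimicked parkinsonian gait.  Angle
#' magnitudes are chosen as typical for a camptocormia assessment (near-zero
#' upright posture, ~30 degree forward lean straddling the clinical cutoff,
#' mildly stooped gait); the dynamic blocks carry slow leg swing and knee
#' oscillation so the truth stays within the smoothing filter's passband.
#'
#' @param transition_s blend length across block boundaries, seconds.
#' @return A \code{\link{posture_script}}.
#' @export
default_posture_script <- function(transition_s = 4) {
  posture_script(list(
    posture_block("standing_upright", 60,
                  trunk = traj_constant(2), leg = traj_constant(0)),
    posture_block("standing_forward_lean", 50,
                  trunk = traj_sine(30, 4, 0.05), leg = traj_constant(5)),
    posture_block("walking", 25,
                  trunk = traj_constant(10), leg = traj_constant(2),
                  gait_amp_deg = 8, gait_freq_hz = 0.12, knee_amp_deg = 5),
    posture_block("parkinsonian_gait", 80,
                  trunk = traj_sine(35, 5, 0.08), leg = traj_constant(4),
                  gait_amp_deg = 6, gait_freq_hz = 0.1, knee_amp_deg = 4)
  ), transition_s = transition_s)
}

#' Accelerometer and marker noise model
#'
#' @param accel_sigma_g white-noise standard deviation on every
#'   acceleration channel, in g.
#' @param burst_amplitude_g,burst_rate_hz motion-artifact bursts: short
#'   (~0.05 s) noise bursts of the given amplitude at the given mean rate.
#' @param marker_sigma_m white jitter on every marker coordinate, meters.
#' @param seed integer seed; all randomness of the generator flows from it
#'   (marker jitter uses \code{seed + 1} so the two streams are
#'   independent).  \code{NULL} leaves the RNG state untouched.
#' @return Object of class \code{noise_model}.
#' @export
noise_model <- function(accel_sigma_g = 0, burst_amplitude_g = 0,
                        burst_rate_hz = 0, marker_sigma_m = 0, seed = NULL) {
  if (accel_sigma_g < 0 || marker_sigma_m < 0 || burst_rate_hz < 0)
    stop_fmt("noise_model: noise parameters must be >= 0")
  structure(list(accel_sigma_g = accel_sigma_g,
                 burst_amplitude_g = burst_amplitude_g,
                 burst_rate_hz = burst_rate_hz,
                 marker_sigma_m = marker_sigma_m, seed = seed),
            class = "noise_model")
}

smoothstep5 <- function(s) {
  s <- pmin(pmax(s, 0), 1)
  s^3 * (10 - 15 * s + 6 * s^2)
}

# evaluate one quantity over the whole script with boundary blending
script_eval <- function(script, t, what) {
  blocks <- script$blocks
  starts <- cumsum(c(0, vapply(blocks, `[[`, numeric(1), "duration_s")))
  f <- function(i, t) {
    b <- blocks[[i]]
    tl <- t - starts[i]
    switch(what,
      trunk = traj_eval(b$trunk, tl, b$duration_s),
      th = traj_eval(b$leg, tl, b$duration_s) +
        b$gait_amp_deg * sin(2 * pi * b$gait_freq_hz * tl),
      sh = -traj_eval(b$leg, tl, b$duration_s) -
        b$gait_amp_deg * sin(2 * pi * b$gait_freq_hz * tl) +
        b$knee_amp_deg * (1 - cos(2 * pi * b$gait_freq_hz * tl)) / 2)
  }
  i_of <- findInterval(t, starts, rightmost.closed = FALSE)
  i_of <- pmin(pmax(i_of, 1), length(blocks))
  out <- numeric(length(t))
  for (i in seq_along(blocks)) {
    sel <- i_of == i
    if (any(sel)) out[sel] <- f(i, t[sel])
  }
  tau <- script$transition_s
  if (tau > 0 && length(blocks) > 1) {
    for (i in seq_len(length(blocks) - 1)) {
      b <- starts[i + 1]
      sel <- t >= b - tau / 2 & t < b + tau / 2
      if (!any(sel)) next
      w <- smoothstep5((t[sel] - b) / tau + 0.5)
      out[sel] <- (1 - w) * f(i, t[sel]) + w * f(i + 1, t[sel])
    }
  }
  out
}

script_labels <- function(script, t) {
  blocks <- script$blocks
  starts <- cumsum(c(0, vapply(blocks, `[[`, numeric(1), "duration_s")))
  i_of <- pmin(pmax(findInterval(t, starts), 1), length(blocks))
  vapply(blocks, `[[`, character(1), "label")[i_of]
}

#' Activity segments implied by a posture script
#'
#' @param script a \code{\link{posture_script}}.
#' @return An \code{\link{activity_segments}} with one segment per block.
#' @export
script_segments <- function(script) {
  stopifnot(inherits(script, "posture_script"))
  durs <- vapply(script$blocks, `[[`, numeric(1), "duration_s")
  starts <- cumsum(c(0, durs))
  activity_segments(vapply(script$blocks, `[[`, character(1), "label"),
                    starts[-length(starts)], starts[-1])
}

#' Ground-truth angle series for a posture script
#'
#' Derives, sample by sample, the true perpendicular CA, the four sensor
#' inclinations consistent with it, and the true leg and malleolus angles.
#' The trunk inclinations are chosen to satisfy the spine-chain model
#' exactly: with a spine distribution ratio \eqn{\rho = \phi_{C7}/\phi_{L5}}
#' (default 1, equal angles — any pair satisfying the model is valid truth),
#' \eqn{\phi_{L5} = (CA_{per} - 0.3856)/(0.4542 + 0.5458\rho)}.  Leg truths
#' follow the two-pendulum geometry exactly, so running the kinematics
#' module on the generated inclinations reproduces the truth to numerical
#' precision.
#'
#' @param script a \code{\link{posture_script}}.
#' @param rate sampling rate in Hz (default 128).
#' @param anthro an \code{\link{anthropometry}} (default 0.45 m segments),
#'   needed to resolve the leg angle when the knee flexes.
#' @param spine_ratio \eqn{\phi_{C7}/\phi_{L5}} distribution ratio.
#' @return Object of class \code{posture_truth}: a data frame with columns
#'   \code{time_s, label, phi_c7, phi_l5, phi_th, phi_sh, ca_per_true,
#'   phi_leg_true, ca_mal_true, theta_true}; sample rate in attribute
#'   \code{sample_rate}.
#' @export
generate_truth <- function(script, rate = 128,
                           anthro = anthropometry(0.45, 0.45),
                           spine_ratio = 1) {
  stopifnot(inherits(script, "posture_script"))
  if (rate <= 0) stop_fmt("generate_truth: rate must be > 0")
  t <- seq(0, script$duration_s - 1 / rate, by = 1 / rate)
  label <- script_labels(script, t)
  ca_per <- script_eval(script, t, "trunk")
  phi_th <- script_eval(script, t, "th")
  phi_sh <- script_eval(script, t, "sh")
  bad <- abs(ca_per) > 80
  if (any(bad))
    stop_fmt("generate_truth: trunk angle beyond 80 deg in block '%s'",
             label[which(bad)[1]])
  bad <- abs(phi_th) > 60 | abs(phi_sh) > 60
  if (any(bad))
    stop_fmt("generate_truth: leg angle beyond 60 deg in block '%s'",
             label[which(bad)[1]])
  phi_l5 <- (ca_per - CA_PER_INTERCEPT) /
    (CA_PER_COEF_L5 + CA_PER_COEF_C7 * spine_ratio)
  phi_c7 <- spine_ratio * phi_l5
  leg <- leg_angle(phi_th, phi_sh, anthro)
  if (!all(leg$valid))
    stop_fmt("generate_truth: infeasible leg geometry in block '%s'",
             label[which(!leg$valid)[1]])
  structure(data.frame(time_s = t, label = label,
                       phi_c7 = phi_c7, phi_l5 = phi_l5,
                       phi_th = phi_th, phi_sh = phi_sh,
                       ca_per_true = ca_per,
                       phi_leg_true = leg$phi_leg,
                       ca_mal_true = ca_per + leg$phi_leg,
                       theta_true = leg$theta,
                       stringsAsFactors = FALSE),
            sample_rate = rate,
            class = c("posture_truth", "data.frame"))
}

#' Project ground-truth angles into accelerometer channels
#'
#' For each sensor the unit gravity vector is rotated by the segment's
#' inclination and expressed in the sensor frame: trunk sensors read
#' \code{(-cos phi, 0, sin phi)} g, leg sensors \code{(-cos phi, -sin phi,
#' 0)} g, matching the conventions of \code{\link{trunk_inclination}} and
#' \code{\link{leg_inclination}} so a noise-free round trip through the
#' kinematics module reproduces the truth.  White noise and optional
#' motion-artifact bursts are then added.
#'
#' @param truth a \code{\link{generate_truth}} result.
#' @param noise a \code{\link{noise_model}}.
#' @return An \code{\link{accel_recording}}.
#' @export
project_accelerometers <- function(truth, noise = noise_model()) {
  stopifnot(inherits(truth, "posture_truth"), inherits(noise, "noise_model"))
  rate <- attr(truth, "sample_rate")
  n <- nrow(truth)
  if (!is.null(noise$seed)) set.seed(as.integer(noise$seed))
  ch <- list()
  for (s in SENSORS) {
    phi <- truth[[paste0("phi_", tolower(s))]] * DEG2RAD
    if (s %in% c("C7", "L5")) {
      ax <- -cos(phi); ay <- rep(0, n); az <- sin(phi)
    } else {
      ax <- -cos(phi); ay <- -sin(phi); az <- rep(0, n)
    }
    if (noise$accel_sigma_g > 0) {
      ax <- ax + rnorm(n, 0, noise$accel_sigma_g)
      ay <- ay + rnorm(n, 0, noise$accel_sigma_g)
      az <- az + rnorm(n, 0, noise$accel_sigma_g)
    }
    ch[[paste0(s, "_ax")]] <- ax
    ch[[paste0(s, "_ay")]] <- ay
    ch[[paste0(s, "_az")]] <- az
  }
  if (noise$burst_rate_hz > 0 && noise$burst_amplitude_g > 0) {
    n_burst <- rpois(1, noise$burst_rate_hz * n / rate)
    width <- max(1, round(0.05 * rate))
    for (k in seq_len(n_burst)) {
      at <- sample.int(n, 1)
      idx <- at:min(n, at + width - 1)
      sensor <- sample(SENSORS, 1)
      for (a in c("ax", "ay", "az")) {
        nm <- paste(sensor, a, sep = "_")
        ch[[nm]][idx] <- ch[[nm]][idx] +
          noise$burst_amplitude_g * rnorm(length(idx))
      }
    }
  }
  accel_recording(as.data.frame(ch), sample_rate = rate)
}

#' Body dimensions for the synthetic marker generator
#'
#' @param trunk_length_m L5-to-C7 distance along the spine line, meters.
#' @param ankle_height_m height of the LM marker above ground, meters.
#' @param l5_gap_deg constructed leg-frame gap between the L5-LM and IC-LM
#'   reference lines in degrees: the synthetic L5 marker is placed by
#'   rotating the hip (IC) position about LM by exactly this angle, so the
#'   gap is constant by construction (0 makes L5 and IC coincide on the leg
#'   line, the degenerate no-offset case).
#' @return A list of class \code{body_dimensions}.
#' @export
body_dimensions <- function(trunk_length_m = 0.45, ankle_height_m = 0.08,
                            l5_gap_deg = 0) {
  if (trunk_length_m <= 0 || ankle_height_m < 0)
    stop_fmt("body_dimensions: lengths must be positive")
  structure(list(trunk_length_m = trunk_length_m,
                 ankle_height_m = ankle_height_m,
                 l5_gap_deg = l5_gap_deg), class = "body_dimensions")
}

#' Project ground-truth angles into optical marker trajectories
#'
#' Builds the leg chain from the fixed ankle (LM) upward with the true
#' thigh/shank inclinations, places IC at the hip joint, derives L5 by an
#' exact rotation of the hip position about LM (see
#' \code{\link{body_dimensions}}), and places C7 up the spine line tilted by
#' the true perpendicular CA.  On noise-free output the reconstructed trunk
#' reference equals the true CA and the IC-frame leg reference equals the
#' absolute true leg angle.
#'
#' @param truth a \code{\link{generate_truth}} result.
#' @param anthro the \code{\link{anthropometry}} used for the truth.
#' @param dims a \code{\link{body_dimensions}}.
#' @param noise a \code{\link{noise_model}} (marker jitter; uses
#'   \code{seed + 1}).
#' @param rate marker sampling rate in Hz (default: the truth's rate).
#' @return A \code{\link{marker_trajectory}}.
#' @export
project_markers <- function(truth, anthro = anthropometry(0.45, 0.45),
                            dims = body_dimensions(),
                            noise = noise_model(), rate = NULL) {
  stopifnot(inherits(truth, "posture_truth"), inherits(dims, "body_dimensions"))
  truth_rate <- attr(truth, "sample_rate")
  if (is.null(rate)) rate <- truth_rate
  if (rate != truth_rate) {
    keep <- seq(1, nrow(truth), by = truth_rate / rate)
    truth <- truth[round(keep), ]
  }
  u <- anthro$u_m; l <- anthro$l_m
  th <- truth$phi_th * DEG2RAD; sh <- truth$phi_sh * DEG2RAD
  ca <- truth$ca_per_true * DEG2RAD
  n <- nrow(truth)
  lm <- cbind(x = rep(0, n), y = rep(0, n), z = rep(dims$ankle_height_m, n))
  knee <- lm + cbind(l * sin(sh), 0, l * cos(sh))
  hip <- knee + cbind(-u * sin(th), 0, u * cos(th))
  ic <- hip
  # The hip sits at x = -(u+l)sin(phi_leg) relative to the ankle, so the
  # LM->IC line has signed tilt -phi_leg.  Rotating that line about LM by
  # -gap makes the LM->L5 tilt -(phi_leg + gap): for anterior postures the
  # unsigned L5-frame leg reference exceeds the IC-frame one by exactly gap.
  g <- -dims$l5_gap_deg * DEG2RAD
  d <- ic - lm
  l5 <- lm + cbind(d[, 1] * cos(g) + d[, 3] * sin(g), d[, 2],
                   d[, 3] * cos(g) - d[, 1] * sin(g))
  c7 <- l5 + cbind(dims$trunk_length_m * sin(ca), 0,
                   dims$trunk_length_m * cos(ca))
  coords <- data.frame(
    C7_x = c7[, 1], C7_y = c7[, 2], C7_z = c7[, 3],
    L5_x = l5[, 1], L5_y = l5[, 2], L5_z = l5[, 3],
    IC_x = ic[, 1], IC_y = ic[, 2], IC_z = ic[, 3],
    LM_x = lm[, 1], LM_y = lm[, 2], LM_z = lm[, 3])
  if (noise$marker_sigma_m > 0) {
    if (!is.null(noise$seed)) set.seed(as.integer(noise$seed) + 1L)
    coords[] <- lapply(coords, function(col)
      col + rnorm(n, 0, noise$marker_sigma_m))
  }
  marker_trajectory(coords, sample_rate = rate, start_time = truth$time_s[1])
}

#' Write a ground-truth series to TSV
#'
#' @param truth a \code{\link{generate_truth}} result.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  stopifnot(inherits(truth, "posture_truth"))
  d <- truth
  num <- vapply(d, is.numeric, logical(1))
  d[num] <- lapply(d[num], fmt_num)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
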