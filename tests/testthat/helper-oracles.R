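# Independent oracles and fixture builders used across the suite.

# Brute-force 2D forward kinematics for the leg: explicit hip/knee/ankle
# coordinates (x anterior, z up, hip at origin), then the signed angle of
# the hip->ankle vector against the vertical.  Independent of leg_angle().
leg_oracle <- function(phi_th, phi_sh, u, l) {
  th <- phi_th * pi / 180
  sh <- phi_sh * pi / 180
  knee_x <- u * sin(th); knee_z <- -u * cos(th)
  ankle_x <- knee_x - l * sin(sh); ankle_z <- knee_z - l * cos(sh)
  phi_leg <- atan2(ankle_x, -ankle_z) * 180 / pi
  h <- sqrt(ankle_x^2 + ankle_z^2)
  # interior knee angle between knee->hip and knee->ankle
  v1 <- c(-knee_x, -knee_z)
  v2 <- c(ankle_x - knee_x, ankle_z - knee_z)
  ct <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  theta <- acos(pmin(pmax(ct, -1), 1)) * 180 / pi
  list(phi_leg = phi_leg, h = h, theta = theta)
}

# Gravity vector seen by a trunk sensor tilted alpha degrees forward
# (geometric oracle: rotate the unit gravity vector about y and project).
trunk_gravity <- function(alpha_deg) {
  a <- alpha_deg * pi / 180
  c(ax = -cos(a), ay = 0, az = sin(a))
}

leg_gravity <- function(alpha_deg) {
  a <- alpha_deg * pi / 180
  c(ax = -cos(a), ay = -sin(a), az = 0)
}

# A minimal constant-posture recording for io/calibration tests.
make_constant_recording <- function(n = 256, rate = 128, trunk_deg = 0,
                                    th_deg = 0, sh_deg = 0) {
  tg <- trunk_gravity(trunk_deg)
  thg <- leg_gravity(th_deg)
  shg <- leg_gravity(sh_deg)
  ch <- data.frame(
    C7_ax = rep(tg["ax"], n), C7_ay = rep(tg["ay"], n), C7_az = rep(tg["az"], n),
    L5_ax = rep(tg["ax"], n), L5_ay = rep(tg["ay"], n), L5_az = rep(tg["az"], n),
    TH_ax = rep(thg["ax"], n), TH_ay = rep(thg["ay"], n), TH_az = rep(thg["az"], n),
    SH_ax = rep(shg["ax"], n), SH_ay = rep(shg["ay"], n), SH_az = rep(shg["az"], n))
  accel_recording(ch, sample_rate = rate)
}

# Static four-marker pose for reference tests.
make_static_markers <- function(n = 100, rate = 100,
                                c7 = c(0, 0, 1.4), l5 = c(0, 0, 1.0),
                                ic = c(0.05, 0, 1.0), lm = c(0, 0, 0.1)) {
  one <- c(c7, l5, ic, lm)
  coords <- as.data.frame(matrix(rep(one, each = n), nrow = n))
  names(coords) <- as.vector(t(outer(c("C7", "L5", "IC", "LM"),
                                     c("x", "y", "z"), paste, sep = "_")))
  marker_trajectory(coords, sample_rate = rate)
}

# Short two-block script used where the full default script is overkill.
short_script <- function(transition_s = 2) {
  posture_script(list(
    posture_block("standing_upright", 10, trunk = traj_constant(3)),
    posture_block("standing_forward_lean", 10, trunk = traj_constant(25),
                  leg = traj_constant(5))
  ), transition_s = transition_s)
}
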