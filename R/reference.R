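# Reference angles from optical motion-capture markers.  Segment directions
# are taken from displacement vectors between markers (C7 - L5, top - LM);
# angles against the vertical z axis.  The trunk reference is signed-free in
# [0, 180); the leg references take the absolute value, so they are unsigned
# in [0, 90) while the IMU leg angle is signed — near-zero leg angles
# therefore fold onto the positive side in the reference.

vec_angle_to_vertical <- function(dx, dy, dz) {
  atan2(sqrt(dx^2 + dy^2), dz) * RAD2DEG
}

#' Trunk reference angle from the C7 and L5 markers
#'
#' Angle of the L5-to-C7 displacement against the vertical:
#' \code{atan(sqrt(dx^2 + dy^2) / dz)} on \code{C7 - L5}, quadrant-safe,
#' in [0, 180).
#'
#' @param c7,l5 numeric matrices (or vectors) of x, y, z positions in meters,
#'   one row per frame.
#' @return Angle in degrees per frame.
#' @export
ref_trunk_angle <- function(c7, l5) {
  c7 <- rbind(c7); l5 <- rbind(l5)
  d <- c7 - l5
  if (any(rowSums(d^2) == 0))
    stop_fmt("ref_trunk_angle: coincident C7 and L5 markers")
  unname(vec_angle_to_vertical(d[, 1], d[, 2], d[, 3]))
}

#' Leg reference angle from a top marker and the lateral malleolus
#'
#' Absolute angle of the LM-to-top displacement against the vertical, in
#' [0, 90).  \code{top} is the L5 marker (L5-LM frame) or the iliac crest
#' marker (IC-LM frame); it must lie above LM in every frame.
#'
#' @param top,lm numeric matrices (or vectors) of x, y, z positions in
#'   meters, one row per frame.
#' @return Angle in degrees per frame (non-negative).
#' @export
ref_leg_angle <- function(top, lm) {
  top <- rbind(top); lm <- rbind(lm)
  d <- top - lm
  if (any(d[, 3] <= 0))
    stop_fmt("ref_leg_angle: top marker at or below LM in frame(s) %s",
             paste(utils::head(which(d[, 3] <= 0), 5), collapse = ", "))
  unname(abs(vec_angle_to_vertical(d[, 1], d[, 2], d[, 3])))
}

#' Malleolus-method reference angle (L5 frame)
#'
#' Exact sum of the trunk reference and the L5-frame leg reference.
#'
#' @param phi_per_ref trunk reference angle, degrees.
#' @param phi_leg_ref_l5 L5-frame leg reference angle, degrees.
#' @return Reference CA in degrees.
#' @export
ref_ca_l5 <- function(phi_per_ref, phi_leg_ref_l5) phi_per_ref + phi_leg_ref_l5

#' Reference angles for a whole marker trajectory
#'
#' Computes the trunk reference, both leg references (L5-LM and IC-LM
#' frames) and the malleolus-method reference CA for every frame.
#'
#' @param traj a \code{\link{marker_trajectory}} (resample first with
#'   \code{\link{resample_markers}} for sample-wise IMU comparison).
#' @return Object of class \code{reference_angles}: a data frame with
#'   columns \code{time_s}, \code{phi_per_ref}, \code{phi_leg_ref_l5},
#'   \code{phi_leg_ref_ic}, \code{ca_ref_l5}.
#' @export
compute_reference_angles <- function(traj) {
  stopifnot(inherits(traj, "marker_trajectory"))
  m <- function(name) as.matrix(traj$coords[paste(name, c("x", "y", "z"),
                                                  sep = "_")])
  phi_per <- ref_trunk_angle(m("C7"), m("L5"))
  phi_l5 <- ref_leg_angle(m("L5"), m("LM"))
  phi_ic <- ref_leg_angle(m("IC"), m("LM"))
  structure(data.frame(time_s = traj$time_s,
                       phi_per_ref = phi_per,
                       phi_leg_ref_l5 = phi_l5,
                       phi_leg_ref_ic = phi_ic,
                       ca_ref_l5 = ref_ca_l5(phi_per, phi_l5)),
            class = c("reference_angles", "data.frame"))
}

#' Write reference angles to TSV
#'
#' Columns \code{time_s, phi_per_ref, phi_leg_ref_l5, phi_leg_ref_ic,
#' ca_ref_l5}.
#'
#' @param ref a \code{\link{compute_reference_angles}} result.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_reference_tsv <- function(ref, path) {
  stopifnot(inherits(ref, "reference_angles"))
  d <- as.data.frame(lapply(ref, fmt_num))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
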