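# Orientation frame: right-handed, X = subject's right, Y = up,
# Z = posterior. Decomposition is intrinsic yaw(Y) -> pitch(X) -> roll(Z),
# which places each anatomical movement on a single Euler axis and moves
# gimbal lock to |flexion-extension| = 90 deg, outside cervical range.
# The clinical sign map (flexion +, extension -; left lateral +, right -;
# right rotation +, left -) is applied after Euler extraction:
#   flexion_extension = -pitch, lateral_flexion = +roll, rotation = -yaw.

GIMBAL_WARN_DEG <- 85

#' Orientation relative to a neutral calibration
#'
#' Re-zeroes a measured head orientation against the calibrated neutral:
#' returns `inverse(q_ref) * q`, the rotation that carries the neutral
#' head pose onto the measured one. Identity when `q` equals the
#' reference.
#'
#' @param q Measured orientation (`quat` or length-4 numeric, `w,x,y,z`).
#' @param calib A [neutral_calibration()] object (or a bare quaternion
#'   used as the reference).
#' @return The relative orientation as a canonical-hemisphere `quat`.
#' @export
relative_orientation <- function(q, calib) {
  q_ref <- if (inherits(calib, "neutral_calibration")) calib$q_ref else quat(calib)
  q <- quat(q)
  quat_canonical(quat_multiply(quat_conjugate(q_ref), q))
}

# intrinsic Y-X-Z Euler extraction from a rotation matrix; returns
# c(yaw, pitch, roll) in radians
euler_yxz <- function(m) {
  sp <- -m[2, 3]
  sp <- max(-1, min(1, sp))
  pitch <- asin(sp)
  if (abs(sp) > 1 - 1e-12) {
    # gimbal-locked: yaw/roll degenerate, put everything in yaw
    yaw <- atan2(-m[3, 1], m[1, 1])
    roll <- 0
  } else {
    yaw <- atan2(m[1, 3], m[3, 3])
    roll <- atan2(m[2, 1], m[2, 2])
  }
  c(yaw = yaw, pitch = pitch, roll = roll)
}

#' Decompose a relative orientation into anatomical angles
#'
#' Factors the neutral-relative head orientation into the three signed
#' cervical angles via an intrinsic yaw-pitch-roll Euler decomposition
#' followed by the clinical sign map. Exact inverse of
#' [compose_from_angles()] away from gimbal lock.
#'
#' @param q_rel Relative (neutral-calibrated) unit quaternion.
#' @param warn_gimbal Warn when `|flexion_extension|` exceeds 85 degrees
#'   (approaching the decomposition's gimbal lock, and outside
#'   physiological cervical range). Default `TRUE`.
#' @return An [anatomical_angles()] triple in degrees.
#' @examples
#' decompose_angles(quat_identity())          # all zero
#' q <- compose_from_angles(anatomical_angles(34, 0, 0))
#' decompose_angles(q)                        # 34 deg flexion
#' @export
decompose_angles <- function(q_rel, warn_gimbal = TRUE) {
  q_rel <- quat(q_rel)
  e <- euler_yxz(quat_to_matrix(q_rel))
  a <- anatomical_angles(
    flexion_extension = -e[["pitch"]] * 180 / pi,
    lateral_flexion = e[["roll"]] * 180 / pi,
    rotation = -e[["yaw"]] * 180 / pi)
  if (warn_gimbal && abs(a[["flexion_extension"]]) > GIMBAL_WARN_DEG) {
    warning(sprintf(
      "flexion-extension %.1f deg is beyond %d deg: near gimbal lock and outside cervical range",
      a[["flexion_extension"]], GIMBAL_WARN_DEG), call. = FALSE)
  }
  a
}

#' Compose a relative orientation from anatomical angles
#'
#' Inverse of [decompose_angles()]: builds the unit quaternion whose
#' decomposition returns the given signed angle triple (within 1e-9
#' degrees for `|flexion_extension| < 85` degrees).
#'
#' @param a An [anatomical_angles()] triple, or a length-3 numeric
#'   `c(flexion_extension, lateral_flexion, rotation)` in degrees.
#' @return A unit `quat`.
#' @export
compose_from_angles <- function(a) {
  a <- as.numeric(a)
  stopifnot(length(a) == 3L, all(is.finite(a)))
  yaw <- -a[3]; pitch <- -a[1]; roll <- a[2]
  q <- quat_multiply(
    quat_multiply(quat_from_axis_angle(c(0, 1, 0), yaw),
                  quat_from_axis_angle(c(1, 0, 0), pitch)),
    quat_from_axis_angle(c(0, 0, 1), roll))
  quat_canonical(q)
}

#' Neutral (starting-position) calibration
#'
#' Wraps the reference head orientation against which all angles are
#' measured, mirroring the examination step in which the user sets up the
#' initial head position before the protocol starts.
#'
#' @param q_ref Reference unit quaternion.
#' @return An object of class `"neutral_calibration"`.
#' @export
neutral_calibration <- function(q_ref) {
  structure(list(q_ref = quat_canonical(quat(q_ref))), class = "neutral_calibration")
}

#' @export
print.neutral_calibration <- function(x, ...) {
  cat("<neutral_calibration>\n")
  print(x$q_ref)
  invisible(x)
}

#' Estimate the neutral orientation from a still window
#'
#' Averages the head orientation over the initial still window of a
#' session (hemisphere-aligned component mean, renormalized). The window
#' must be still: the calibration drift rate — the geodesic angle between
#' the mean orientations of the first and last thirds of the window,
#' divided by the time between them — must stay below `max_speed_dps`.
#' Per-sample speeds are not used because sensor noise dominates them at
#' 60 Hz; the drift rate isolates actual head motion.
#'
#' @param stream A [pose_stream()].
#' @param window_s Length of the calibration window in seconds (default 1).
#' @param max_speed_dps Maximum tolerated drift rate in deg/s (default 10).
#' @return A [neutral_calibration()].
#' @export
estimate_neutral <- function(stream, window_s = 1, max_speed_dps = 10) {
  stopifnot(inherits(stream, "pose_stream"))
  t0 <- stream$t[1]
  idx <- which(stream$t <= t0 + window_s)
  if (stream$t[length(stream$t)] - t0 < window_s - 1e-9) {
    stop("stream shorter than the calibration window", call. = FALSE)
  }
  if (length(idx) < 3L) stop("too few samples in the calibration window", call. = FALSE)
  Q <- qm_align(stream$q[idx, , drop = FALSE], stream$q[idx[1], ])

  third <- max(1L, floor(length(idx) / 3))
  head_idx <- seq_len(third)
  tail_idx <- seq.int(length(idx) - third + 1L, length(idx))
  mean_q <- function(rows) quat_unit(colMeans(Q[rows, , drop = FALSE]))
  gap_s <- mean(stream$t[idx][tail_idx]) - mean(stream$t[idx][head_idx])
  drift_dps <- quat_angle_deg(mean_q(head_idx), mean_q(tail_idx)) / gap_s
  if (drift_dps > max_speed_dps) {
    stop(sprintf(
      "calibration instability: drift %.1f deg/s over window %.2f-%.2f s (limit %g deg/s)",
      drift_dps, t0, t0 + window_s, max_speed_dps), call. = FALSE)
  }
  neutral_calibration(quat_unit(colMeans(Q)))
}

#' Anatomical angle time series of a pose stream
#'
#' Applies [relative_orientation()] and [decompose_angles()] to every
#' sample: the per-frame signed cervical angles of the whole session,
#' measured against the calibrated neutral.
#'
#' @param stream A [pose_stream()].
#' @param calib A [neutral_calibration()]; defaults to
#'   [estimate_neutral()] on the stream's first second.
#' @return An [angle_series()] aligned with the stream's timestamps. If
#'   any sample approaches gimbal lock a single warning lists the sample
#'   indices.
#' @export
angles_timeseries <- function(stream, calib = estimate_neutral(stream)) {
  stopifnot(inherits(stream, "pose_stream"))
  q_ref <- if (inherits(calib, "neutral_calibration")) calib$q_ref else quat(calib)
  Qrel <- qm_multiply(as.numeric(quat_conjugate(q_ref)), stream$q)

  # vectorised intrinsic Y-X-Z extraction + sign map (see euler_yxz)
  w <- Qrel[, 1]; x <- Qrel[, 2]; y <- Qrel[, 3]; z <- Qrel[, 4]
  m23 <- 2 * (y * z - w * x)
  m13 <- 2 * (x * z + w * y)
  m33 <- 1 - 2 * (x^2 + y^2)
  m21 <- 2 * (x * y + w * z)
  m22 <- 1 - 2 * (x^2 + z^2)
  sp <- pmax(-1, pmin(1, -m23))
  pitch <- asin(sp)
  yaw <- atan2(m13, m33)
  roll <- atan2(m21, m22)

  fe <- -pitch * 180 / pi
  gimbal <- which(abs(fe) > GIMBAL_WARN_DEG)
  if (length(gimbal) > 0) {
    warning(sprintf(
      "%d samples beyond %d deg flexion-extension (near gimbal lock): indices %s",
      length(gimbal), GIMBAL_WARN_DEG,
      paste(utils::head(gimbal, 10), collapse = ", ")), call. = FALSE)
  }
  angle_series(stream$t,
               flexion_extension = fe,
               lateral_flexion = roll * 180 / pi,
               rotation = -yaw * 180 / pi)
}
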