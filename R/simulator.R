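# Synthetic session generator: six-movement examination protocols with
# optional cross-plane couplings and angle-space Gaussian noise, and the
# noise-free skull-rig single-plane validation trials, both with
# ground-truth annotations (episode windows, true signed peaks, true
# couplings, whole-degree goniometer twin readings).

MOVEMENT_LABELS <- c("flexion", "extension", "left_lateral", "right_lateral",
                     "left_rotation", "right_rotation")

# channel and conventional sign of each movement direction
MOVEMENT_CHANNEL <- c(
  flexion = "flexion_extension", extension = "flexion_extension",
  left_lateral = "lateral_flexion", right_lateral = "lateral_flexion",
  left_rotation = "rotation", right_rotation = "rotation")

MOVEMENT_SIGN <- c(
  flexion = +1, extension = -1,
  left_lateral = +1, right_lateral = -1,
  left_rotation = -1, right_rotation = +1)

#' Specification of one protocol movement
#'
#' @param label One of `"flexion"`, `"extension"`, `"left_lateral"`,
#'   `"right_lateral"`, `"left_rotation"`, `"right_rotation"`.
#' @param peak_deg Unsigned peak excursion in degrees; the signed peak
#'   follows the movement's clinical sign convention.
#' @param rise_s Rise time (and, mirrored, return time) in seconds.
#' @param hold_s Hold time at peak in seconds.
#' @param coupling Named numeric vector of cross-plane co-movement
#'   ratios. Names are movement directions (e.g. `"left_rotation"`) with
#'   non-negative ratios applied with that direction's sign, or raw
#'   channel names (e.g. `"rotation"`) with signed ratios applied to the
#'   primary signed profile. `|ratio| < 1`.
#' @return A `movement_spec` list.
#' @export
movement_spec <- function(label, peak_deg, rise_s = 1.5, hold_s = 0.5,
                          coupling = NULL) {
  label <- match.arg(label, MOVEMENT_LABELS)
  stopifnot(peak_deg >= 0, rise_s > 0, hold_s >= 0)
  if (!is.null(coupling)) {
    stopifnot(is.numeric(coupling), !is.null(names(coupling)),
              all(abs(coupling) < 1))
    bad <- setdiff(names(coupling), c(MOVEMENT_LABELS, ANGLE_CHANNELS))
    if (length(bad)) stop("unknown coupling target: ", paste(bad, collapse = ", "),
                          call. = FALSE)
    if (any(names(coupling) %in% MOVEMENT_LABELS & coupling < 0)) {
      stop("direction-named couplings must be non-negative (the direction carries the sign)",
           call. = FALSE)
    }
  }
  structure(list(label = label, peak_deg = peak_deg, rise_s = rise_s,
                 hold_s = hold_s, coupling = coupling),
            class = "movement_spec")
}

default_movements <- function() {
  # mid-range healthy adult cervical values; fixtures, not normative claims
  peaks <- c(flexion = 50, extension = 60, left_lateral = 40, right_lateral = 40,
             left_rotation = 70, right_rotation = 70)
  lapply(MOVEMENT_LABELS, function(l) movement_spec(l, peaks[[l]]))
}

#' Examination-protocol configuration
#'
#' Defaults reproduce the six-movement examination in its fixed order —
#' flexion, extension, left side bend, right side bend, left rotation,
#' right rotation — at 60 Hz with mid-range healthy peak angles.
#'
#' @param movements Ordered list of [movement_spec()]s (default: the six
#'   protocol movements in protocol order).
#' @param rest_s Rest between movements in seconds.
#' @param lead_in_s Initial neutral hold used for calibration, seconds.
#' @param noise_sd_deg Per-channel Gaussian angle noise SD in degrees.
#' @param rate_hz Sampling rate (default 60).
#' @param seed Integer seed; the simulated stream is deterministic given
#'   the seed.
#' @return A `protocol_config` list.
#' @export
protocol_config <- function(movements = default_movements(), rest_s = 1,
                            lead_in_s = 1.5, noise_sd_deg = 0.5,
                            rate_hz = 60, seed = 1L) {
  stopifnot(rate_hz > 0, rest_s >= 0, lead_in_s > 0, noise_sd_deg >= 0)
  labs <- vapply(movements, `[[`, "", "label")
  if (anyDuplicated(labs)) stop("duplicate movement labels", call. = FALSE)
  # a non-protocol order is allowed here; validate_protocol_order flags it
  structure(list(movements = movements, rest_s = rest_s, lead_in_s = lead_in_s,
                 noise_sd_deg = noise_sd_deg, rate_hz = rate_hz,
                 seed = as.integer(seed)),
            class = "protocol_config")
}

#' Minimum-jerk rise profile
#'
#' The standard smooth model of voluntary point-to-point movement: the
#' quintic `peak * (10 tau^3 - 15 tau^4 + 6 tau^5)` with `tau = t /
#' rise_s`, which starts and ends with zero velocity and acceleration.
#' Values are clamped to 0 before the rise and to `peak` after it.
#'
#' @param t Time in seconds (vectorized), `t >= 0`.
#' @param rise_s Rise duration in seconds.
#' @param peak Target amplitude in degrees (signed).
#' @return Profile value(s) in degrees.
#' @examples
#' minimum_jerk_profile(0.75, 1.5, 45)  # half way: 22.5
#' @export
minimum_jerk_profile <- function(t, rise_s, peak) {
  stopifnot(rise_s > 0)
  tau <- pmax(0, pmin(1, t / rise_s))
  peak * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
}

# signed out-and-back profile of one movement evaluated on local time
# u in [0, rise + hold + rise]
episode_profile <- function(u, rise_s, hold_s, peak_signed) {
  up <- minimum_jerk_profile(u, rise_s, peak_signed)
  ret <- minimum_jerk_profile(2 * rise_s + hold_s - u, rise_s, peak_signed)
  ifelse(u <= rise_s + hold_s, up, ret)
}

# build t grid + per-channel angle matrix from a schedule of episodes
schedule_to_angles <- function(schedule, total_s, rate_hz) {
  n <- round(rate_hz * total_s)
  t <- seq(0, by = 1 / rate_hz, length.out = n)
  ang <- matrix(0, n, 3, dimnames = list(NULL, ANGLE_CHANNELS))
  for (ep in schedule) {
    sel <- t >= ep$start_s & t <= ep$end_s
    u <- t[sel] - ep$start_s
    prof <- episode_profile(u, ep$rise_s, ep$hold_s, ep$peak_signed)
    ang[sel, ep$channel] <- ang[sel, ep$channel] + prof
    for (k in seq_along(ep$coupling)) {
      tgt <- names(ep$coupling)[k]
      if (tgt %in% MOVEMENT_LABELS) {
        ch <- MOVEMENT_CHANNEL[[tgt]]
        cprof <- abs(prof) * ep$coupling[[k]] * MOVEMENT_SIGN[[tgt]]
      } else {
        ch <- tgt
        cprof <- prof * ep$coupling[[k]]
      }
      ang[sel, ch] <- ang[sel, ch] + cprof
    }
  }
  list(t = t, angles = ang)
}

angles_to_stream <- function(t, ang, rate_hz) {
  rad <- pi / 180
  yaw <- -ang[, "rotation"] * rad
  pitch <- -ang[, "flexion_extension"] * rad
  roll <- ang[, "lateral_flexion"] * rad
  qy <- cbind(cos(yaw / 2), 0, sin(yaw / 2), 0)
  qx <- cbind(cos(pitch / 2), sin(pitch / 2), 0, 0)
  qz <- cbind(cos(roll / 2), 0, 0, sin(roll / 2))
  Q <- qm_multiply(qm_multiply(qy, qx), qz)
  pose_stream(t, Q, rate_hz = rate_hz)
}

signed_coupling_truth <- function(coupling) {
  if (is.null(coupling)) return(NULL)
  out <- numeric(0)
  for (k in seq_along(coupling)) {
    tgt <- names(coupling)[k]
    if (tgt %in% MOVEMENT_LABELS) {
      out[MOVEMENT_CHANNEL[[tgt]]] <- coupling[[k]] * MOVEMENT_SIGN[[tgt]]
    } else {
      out[tgt] <- coupling[[k]]
    }
  }
  out
}

#' Simulate a full examination session
#'
#' Generates a pose stream for the six-movement protocol: a neutral
#' lead-in for calibration, then each movement rising to its signed peak
#' along a minimum-jerk profile, holding, returning, and resting, in
#' protocol order. Coupled cross-plane co-movements are added per
#' [movement_spec()], Gaussian noise is injected per angle channel (so the
#' noise SD stays interpretable in degrees) and the channels are
#' recomposed into unit quaternions.
#'
#' @param cfg A [protocol_config()].
#' @return A list with `stream` (a [pose_stream()]) and `truth`, a list
#'   holding the episode windows, labels, true signed peaks and true
#'   signed coupling ratios per channel.
#' @export
simulate_protocol <- function(cfg = protocol_config()) {
  stopifnot(inherits(cfg, "protocol_config"))
  schedule <- list()
  cursor <- cfg$lead_in_s
  truth_rows <- list()
  for (m in cfg$movements) {
    dur <- 2 * m$rise_s + m$hold_s
    ep <- list(start_s = cursor, end_s = cursor + dur, rise_s = m$rise_s,
               hold_s = m$hold_s, channel = MOVEMENT_CHANNEL[[m$label]],
               peak_signed = MOVEMENT_SIGN[[m$label]] * m$peak_deg,
               coupling = m$coupling)
    schedule <- c(schedule, list(ep))
    truth_rows <- c(truth_rows, list(data.frame(
      label = m$label, start_s = ep$start_s, end_s = ep$end_s,
      peak_signed_deg = ep$peak_signed, stringsAsFactors = FALSE)))
    cursor <- cursor + dur + cfg$rest_s
  }
  total_s <- cursor + 0.5  # trailing neutral tail
  sa <- schedule_to_angles(schedule, total_s, cfg$rate_hz)
  ang <- sa$angles
  if (cfg$noise_sd_deg > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(cfg$seed)
    ang <- ang + matrix(stats::rnorm(length(ang), sd = cfg$noise_sd_deg),
                        nrow(ang), ncol(ang))
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }
  truth <- list(
    episodes = do.call(rbind, truth_rows),
    couplings = stats::setNames(
      lapply(cfg$movements, function(m) signed_coupling_truth(m$coupling)),
      vapply(cfg$movements, `[[`, "", "label")),
    noise_sd_deg = cfg$noise_sd_deg, seed = cfg$seed)
  list(stream = angles_to_stream(sa$t, ang, cfg$rate_hz), truth = truth)
}

#' Skull-rig validation trial specification
#'
#' One single-plane trial of the goniometer-instrumented skull-model
#' experiment: the head is moved in exactly one anatomical plane to a
#' target angle and held there.
#'
#' @param plane One of `"flexion_extension"`, `"lateral_flexion"`,
#'   `"rotation"`, or a movement direction name (e.g. `"flexion"`,
#'   `"right_rotation"`), in which case `angle_deg` is its unsigned
#'   magnitude.
#' @param angle_deg Target angle in degrees; signed when `plane` names a
#'   channel, unsigned when it names a direction.
#' @param rise_s Placement time in seconds.
#' @param settle_s Neutral settle time before movement (used for
#'   calibration) and hold time at target, seconds.
#' @param rate_hz Sampling rate (default 60).
#' @return A `rig_trial_spec` list.
#' @export
rig_trial_spec <- function(plane, angle_deg, rise_s = 1.5, settle_s = 2,
                           rate_hz = 60) {
  if (plane %in% MOVEMENT_LABELS) {
    stopifnot(angle_deg >= 0)
    angle_deg <- MOVEMENT_SIGN[[plane]] * angle_deg
    plane <- MOVEMENT_CHANNEL[[plane]]
  }
  plane <- match.arg(plane, ANGLE_CHANNELS)
  stopifnot(is.finite(angle_deg), rise_s > 0, settle_s > 0, rate_hz > 0)
  structure(list(plane = plane, angle_deg = angle_deg, rise_s = rise_s,
                 settle_s = settle_s, rate_hz = rate_hz),
            class = "rig_trial_spec")
}

channel_label <- function(channel, sign) {
  hit <- MOVEMENT_CHANNEL == channel &
    MOVEMENT_SIGN == (if (sign >= 0) 1 else -1)
  names(MOVEMENT_CHANNEL)[hit][1]
}

#' Simulate a skull-rig validation trial
#'
#' Digital twin of the rig experiment: a noise-free stream that settles
#' at neutral, moves in exactly one anatomical plane to the commanded
#' angle, and holds there. The ground truth carries the goniometer twin's
#' reading, i.e. the commanded angle rounded to the instrument's
#' whole-degree scale.
#'
#' @param spec A [rig_trial_spec()].
#' @return A list with `stream` (a [pose_stream()]) and `truth` (episode
#'   window, label, true signed peak, `goniometer_reading_deg`).
#' @examples
#' tr <- simulate_rig_trial(rig_trial_spec("flexion", 34))
#' tr$truth$goniometer_reading_deg   # 34
#' @export
simulate_rig_trial <- function(spec) {
  stopifnot(inherits(spec, "rig_trial_spec"))
  total_s <- spec$settle_s + spec$rise_s + spec$settle_s
  n <- round(spec$rate_hz * total_s)
  t <- seq(0, by = 1 / spec$rate_hz, length.out = n)
  ang <- matrix(0, n, 3, dimnames = list(NULL, ANGLE_CHANNELS))
  ang[, spec$plane] <- minimum_jerk_profile(t - spec$settle_s, spec$rise_s,
                                            spec$angle_deg)
  truth <- list(
    episodes = data.frame(
      label = channel_label(spec$plane, sign(spec$angle_deg)),
      start_s = spec$settle_s, end_s = total_s,
      peak_signed_deg = spec$angle_deg, stringsAsFactors = FALSE),
    goniometer_reading_deg = round(spec$angle_deg))
  list(stream = angles_to_stream(t, ang, spec$rate_hz), truth = truth)
}
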