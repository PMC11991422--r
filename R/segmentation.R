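# Offline movement-episode segmentation of a calibrated angle series.
# Episodes are one excursion from neutral and back, delimited by
# hysteresis on smoothed angular speed: start when speed > hi_dps, end
# when speed < lo_dps AND every channel is back inside the neutral band
# (so the hold at peak, where speed is ~0 but angles are large, does not
# end the episode).

#' Segmentation configuration
#'
#' @param hi_dps Speed threshold starting an episode, deg/s.
#' @param lo_dps Speed threshold (with the neutral-band condition) ending
#'   an episode, deg/s; must be `< hi_dps` for hysteresis.
#' @param smooth_s Centred moving-average window applied to the angle
#'   channels before differentiation and to the speed itself, seconds.
#' @param neutral_band_deg Half-width of the neutral band, degrees.
#' @param min_duration_s Episodes shorter than this are discarded.
#' @return A `segmentation_config` list.
#' @export
segmentation_config <- function(hi_dps = 10, lo_dps = 5, smooth_s = 0.25,
                                neutral_band_deg = 3, min_duration_s = 0.3) {
  stopifnot(hi_dps > lo_dps, lo_dps > 0, smooth_s > 0,
            neutral_band_deg > 0, min_duration_s >= 0)
  structure(list(hi_dps = hi_dps, lo_dps = lo_dps, smooth_s = smooth_s,
                 neutral_band_deg = neutral_band_deg,
                 min_duration_s = min_duration_s),
            class = "segmentation_config")
}

# centred moving average (odd window >= w samples), edge-padded
moving_average <- function(x, w) {
  if (w <= 1L) return(x)
  half <- w %/% 2
  n <- length(x)
  xp <- c(rep(x[1], half), x, rep(x[n], half))
  cs <- c(0, cumsum(xp))
  (cs[seq_len(n) + 2L * half + 1L] - cs[seq_len(n)]) / (2L * half + 1L)
}

#' Angular speed of an angle series
#'
#' Euclidean norm of the three per-channel derivatives. Each channel is
#' smoothed by a centred moving average, differentiated by a centred
#' finite difference whose stencil spans the same window (so the
#' derivative baseline is wide enough that 60 Hz sensor noise does not
#' set the speed floor), and the resulting speed is smoothed once more
#' with the same window.
#'
#' @param series An [angle_series()] with at least 2 samples.
#' @param smooth_s Smoothing window (and half-stencil) in seconds
#'   (default 0.25).
#' @return Numeric vector of speeds in deg/s, same length as the series
#'   (edge-padded).
#' @export
angular_speed <- function(series, smooth_s = 0.25) {
  t <- series$t_s
  n <- length(t)
  stopifnot(n >= 2L)
  dt <- stats::median(diff(t))
  w <- max(1L, min(round(smooth_s / dt), (n - 1L) %/% 2L))
  A <- as_angle_matrix(series)
  D <- matrix(0, n, 3)
  lo <- pmax(1L, seq_len(n) - w)
  hi <- pmin(n, seq_len(n) + w)
  for (j in 1:3) {
    s <- moving_average(A[, j], w)
    D[, j] <- (s[hi] - s[lo]) / (t[hi] - t[lo])
  }
  moving_average(sqrt(rowSums(D^2)), w)
}

label_for_extremum <- function(channel, value) {
  channel_label(channel, if (value >= 0) 1 else -1)
}

#' Segment an angle series into labelled movement episodes
#'
#' Walks the smoothed angular speed with hysteresis: an episode opens
#' when the speed exceeds `hi_dps` and closes at the first sample where
#' the speed has fallen below `lo_dps` and all three channels are back
#' inside the neutral band. Each episode is labelled by its dominant
#' channel (largest absolute excursion) and the sign of that channel's
#' extremum; ties between channels are broken in protocol-channel order.
#' Episodes shorter than `min_duration_s`, or never leaving the neutral
#' band, are discarded. An episode still open at the end of the series is
#' closed there (single rig trials hold the target angle to the end).
#'
#' @param series An [angle_series()] starting near neutral.
#' @param config A [segmentation_config()].
#' @return A data frame of class `"movement_episodes"` with columns
#'   `label`, `start_s`, `end_s`, `primary_channel`, `peak_signed_deg`,
#'   `peak_time_s`, ordered by start time. Empty (zero rows) when the
#'   series never leaves neutral.
#' @export
segment_episodes <- function(series, config = segmentation_config()) {
  stopifnot(inherits(config, "segmentation_config"))
  t <- series$t_s
  n <- length(t)
  A <- as_angle_matrix(series)
  empty <- data.frame(label = character(0), start_s = numeric(0),
                      end_s = numeric(0), primary_channel = character(0),
                      peak_signed_deg = numeric(0), peak_time_s = numeric(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("movement_episodes", "data.frame")
  if (n < 3L) return(empty)
  speed <- angular_speed(series, config$smooth_s)
  in_neutral <- apply(abs(A) <= config$neutral_band_deg, 1, all)
  # peaks are read off the smoothed channels so sensor noise does not
  # bias the extremum upward
  dt <- stats::median(diff(t))
  w <- max(1L, round(config$smooth_s / dt))
  As <- apply(A, 2, moving_average, w = w)

  rows <- list()
  open <- NA_integer_
  for (i in seq_len(n)) {
    if (is.na(open)) {
      if (speed[i] > config$hi_dps) open <- i
    } else if ((speed[i] < config$lo_dps && in_neutral[i]) || i == n) {
      rows <- c(rows, list(close_episode(open, i, t, As, config)))
      open <- NA_integer_
    }
  }
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  class(out) <- c("movement_episodes", "data.frame")
  out
}

close_episode <- function(i0, i1, t, A, config) {
  if (t[i1] - t[i0] < config$min_duration_s) return(NULL)
  seg <- A[i0:i1, , drop = FALSE]
  peaks <- apply(abs(seg), 2, max)
  if (max(peaks) <= config$neutral_band_deg) return(NULL)  # noise excursion
  ch <- ANGLE_CHANNELS[which.max(peaks)]  # which.max: first of ties, protocol order
  k <- which.max(abs(seg[, ch]))
  peak <- seg[k, ch]
  data.frame(label = label_for_extremum(ch, peak),
             start_s = t[i0], end_s = t[i1], primary_channel = ch,
             peak_signed_deg = peak, peak_time_s = t[i0:i1][k],
             stringsAsFactors = FALSE)
}

#' Check episodes against the examination-protocol order
#'
#' Compares detected episode labels with the fixed six-movement template
#' (flexion, extension, left side bend, right side bend, left rotation,
#' right rotation) and flags missing, extra and out-of-order movements.
#'
#' @param episodes A `movement_episodes` data frame from
#'   [segment_episodes()].
#' @return A list with `ok` (logical) and `flags`, a character vector of
#'   human-readable flags; empty when the episodes match the template
#'   exactly.
#' @export
validate_protocol_order <- function(episodes) {
  labs <- episodes$label
  flags <- character(0)
  for (m in setdiff(MOVEMENT_LABELS, labs)) {
    flags <- c(flags, sprintf("missing movement: %s", m))
  }
  for (m in setdiff(labs, MOVEMENT_LABELS)) {
    flags <- c(flags, sprintf("unknown movement: %s", m))
  }
  dup <- unique(labs[duplicated(labs)])
  for (m in dup) flags <- c(flags, sprintf("repeated movement: %s", m))
  # out-of-order: known, non-duplicated labels not in template relative order
  known <- labs[labs %in% MOVEMENT_LABELS & !labs %in% dup]
  pos <- match(known, MOVEMENT_LABELS)
  ooo <- which(diff(pos) < 0)
  for (k in ooo) {
    flags <- c(flags, sprintf("out of order: %s before %s", known[k], known[k + 1]))
  }
  list(ok = length(flags) == 0L, flags = flags)
}
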