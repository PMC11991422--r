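# Clinical outputs: signed ROM and duration per movement, left/right
# asymmetry, cross-plane compensation reports, norm-exceedance flags,
# Table-style session summaries and between-session comparison.

#' Signed range of motion of one episode
#'
#' ROM is the signed extremum of the episode's primary channel inside
#' its window — the maximal excursion a goniometer would read — not the
#' net displacement. Duration is the episode span.
#'
#' Before the extremum is taken the channel is smoothed by a short
#' centred moving average (`smooth_s`), so that the reading reflects the
#' movement's plateau rather than the upward-biased maximum of sensor
#' noise; noise-free plateaus are unaffected.
#'
#' @param episode One row of a `movement_episodes` data frame.
#' @param series The [angle_series()] the episode indexes into.
#' @param smooth_s Channel smoothing window in seconds (default 0.25).
#' @return A one-row data frame of class `"rom_result"`: `label`,
#'   `rom_signed_deg`, `duration_s`.
#' @export
compute_rom <- function(episode, series, smooth_s = 0.25) {
  sel <- series$t_s >= episode$start_s & series$t_s <= episode$end_s
  if (!any(sel)) stop("episode window contains no samples", call. = FALSE)
  ch <- smooth_channel(series[[episode$primary_channel]], series$t_s, smooth_s)[sel]
  rom <- ch[which.max(abs(ch))]
  expected_sign <- MOVEMENT_SIGN[[episode$label]]
  if (rom != 0 && sign(rom) != expected_sign) {
    warning(sprintf("ROM sign of %s episode contradicts its label's convention",
                    episode$label), call. = FALSE)
  }
  structure(data.frame(label = episode$label, rom_signed_deg = rom,
                       duration_s = episode$end_s - episode$start_s,
                       stringsAsFactors = FALSE),
            class = c("rom_result", "data.frame"))
}

smooth_channel <- function(x, t, smooth_s) {
  if (smooth_s <= 0 || length(x) < 3L) return(x)
  dt <- stats::median(diff(t))
  moving_average(x, max(1L, round(smooth_s / dt)))
}

rom_table <- function(episodes, series) {
  if (nrow(episodes) == 0L) {
    return(data.frame(label = character(0), rom_signed_deg = numeric(0),
                      duration_s = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(seq_len(nrow(episodes)), function(i) {
    as.data.frame(compute_rom(episodes[i, ], series))
  }))
}

PLANE_PAIRS <- list(
  flexion_extension = c("flexion", "extension"),
  lateral_flexion = c("left_lateral", "right_lateral"),
  rotation = c("left_rotation", "right_rotation"))

#' Left/right (paired-direction) asymmetry of one movement plane
#'
#' The same movement performed in opposite directions need not take the
#' same time nor reach the same magnitude; this reports both signed
#' differences, `left - right` (for flexion/extension: flexion minus
#' extension).
#'
#' @param left,right `rom_result` rows for the two directions of one
#'   plane.
#' @return A list with `duration_diff_s` and `rom_diff_deg`
#'   (difference of absolute ROMs).
#' @export
duration_asymmetry <- function(left, right) {
  pl <- MOVEMENT_CHANNEL[[left$label]]
  pr <- MOVEMENT_CHANNEL[[right$label]]
  if (pl != pr || left$label == right$label) {
    stop("episodes are not the paired directions of one plane", call. = FALSE)
  }
  list(duration_diff_s = left$duration_s - right$duration_s,
       rom_diff_deg = abs(left$rom_signed_deg) - abs(right$rom_signed_deg))
}

#' Normative cervical ranges
#'
#' Physiological limits per movement, in degrees. These are a
#' configuration input — published normative tables differ by source and
#' age group, so no values are hard-coded; pass your own, typically read
#' from a JSON/YAML config via [read_norms()].
#'
#' @param ... Named limits in degrees, e.g. `flexion = 50`,
#'   `right_rotation = 80`. Names must be movement labels; limits `> 0`.
#' @return A named numeric vector of class `"normative_ranges"`.
#' @export
normative_ranges <- function(...) {
  v <- c(...)
  if (length(v) == 0L) return(structure(numeric(0), class = "normative_ranges"))
  stopifnot(is.numeric(v), all(v > 0),
            all(names(v) %in% MOVEMENT_LABELS))
  structure(v, class = "normative_ranges")
}

#' Read normative ranges from a JSON file
#' @param path JSON file of `{"movement": limit_deg, ...}`.
#' @return A [normative_ranges()] vector.
#' @export
read_norms <- function(path) {
  v <- unlist(jsonlite::read_json(path, simplifyVector = TRUE))
  do.call(normative_ranges, as.list(v))
}

#' Detect cross-plane compensations and norm exceedance
#'
#' For one episode, reports the signed extremum of each off-plane
#' channel within the episode window and its coupling ratio (off-plane
#' peak / primary peak). A co-movement flag is raised when an off-plane
#' peak leaves the neutral band (small co-movements are physiological);
#' a norm-exceedance flag when the primary ROM exceeds the configured
#' physiological limit for that movement.
#'
#' @param episode One row of a `movement_episodes` data frame.
#' @param series The underlying [angle_series()].
#' @param norms A [normative_ranges()] vector (may be empty).
#' @param band_deg Off-plane neutral band in degrees (default 5).
#' @param smooth_s Channel smoothing window before extremum extraction,
#'   seconds (default 0.25, as in [compute_rom()]).
#' @return A list of class `"compensation_report"`: `label`,
#'   `primary_peak_deg`, `offplane` (data frame with `channel`,
#'   `peak_signed_deg`, `coupling_ratio`) and `flags`.
#' @export
detect_compensations <- function(episode, series, norms = normative_ranges(),
                                 band_deg = 5, smooth_s = 0.25) {
  sel <- series$t_s >= episode$start_s & series$t_s <= episode$end_s
  if (!any(sel)) stop("episode window contains no samples", call. = FALSE)
  A <- as_angle_matrix(series)
  A <- apply(A, 2, smooth_channel, t = series$t_s, smooth_s = smooth_s)
  A <- A[sel, , drop = FALSE]
  prim <- episode$primary_channel
  pk <- A[which.max(abs(A[, prim])), prim]
  off <- setdiff(ANGLE_CHANNELS, prim)
  off_pk <- vapply(off, function(ch) A[which.max(abs(A[, ch])), ch], 0)
  ratio <- if (pk != 0) off_pk / pk else rep(NA_real_, length(off))
  flags <- character(0)
  for (k in seq_along(off)) {
    if (abs(off_pk[k]) > band_deg) {
      flags <- c(flags, sprintf("co-movement: %s reached %+.1f deg during %s",
                                off[k], off_pk[k], episode$label))
    }
  }
  lim <- if (episode$label %in% names(norms)) norms[[episode$label]] else NA_real_
  if (is.finite(lim) && abs(pk) > lim) {
    flags <- c(flags, sprintf(
      "norm exceedance: |%s| = %.1f deg exceeds physiological limit %.0f deg",
      episode$label, abs(pk), lim))
  }
  structure(list(label = episode$label, primary_peak_deg = pk,
                 offplane = data.frame(channel = off,
                                       peak_signed_deg = unname(off_pk),
                                       coupling_ratio = unname(ratio),
                                       stringsAsFactors = FALSE),
                 flags = flags),
            class = "compensation_report")
}

#' @export
print.compensation_report <- function(x, ...) {
  cat(sprintf("<compensation_report> %s (primary peak %+.1f deg)\n",
              x$label, x$primary_peak_deg))
  print(x$offplane, row.names = FALSE)
  if (length(x$flags)) cat(paste0("  ! ", x$flags, collapse = "\n"), "\n")
  invisible(x)
}

#' Aggregate per-session ROM tables into a session summary
#'
#' Per movement: minimum, maximum and arithmetic mean of the signed ROM
#' across the provided sessions (no trimming), the mean duration, and the
#' mean total procedure time — the layout of a clinical results table.
#'
#' @param sessions A list of per-session ROM tables (data frames with
#'   `label`, `rom_signed_deg`, `duration_s`), or a single such table.
#' @return A list of class `"session_summary"` with `per_movement` (data
#'   frame: `movement`, `min_deg`, `max_deg`, `mean_deg`,
#'   `mean_duration_s`), `n_sessions` and `total_duration_s`.
#' @export
summarize_sessions <- function(sessions) {
  if (is.data.frame(sessions)) sessions <- list(sessions)
  if (length(sessions) == 0L) stop("no sessions to summarize", call. = FALSE)
  all_rows <- do.call(rbind, sessions)
  if (nrow(all_rows) == 0L) stop("sessions contain no movements", call. = FALSE)
  labs <- intersect(MOVEMENT_LABELS, unique(all_rows$label))
  labs <- c(labs, setdiff(unique(all_rows$label), MOVEMENT_LABELS))
  per <- do.call(rbind, lapply(labs, function(l) {
    r <- all_rows[all_rows$label == l, ]
    if (length(unique(sign(r$rom_signed_deg[r$rom_signed_deg != 0]))) > 1L) {
      warning(sprintf("mixed ROM signs for movement %s break its sign convention", l),
              call. = FALSE)
    }
    data.frame(movement = l, min_deg = min(r$rom_signed_deg),
               max_deg = max(r$rom_signed_deg),
               mean_deg = mean(r$rom_signed_deg),
               mean_duration_s = mean(r$duration_s),
               stringsAsFactors = FALSE)
  }))
  totals <- vapply(sessions, function(s) sum(s$duration_s), 0)
  structure(list(per_movement = per, n_sessions = length(sessions),
                 total_duration_s = mean(totals)),
            class = "session_summary")
}

#' @export
print.session_summary <- function(x, ...) {
  cat(sprintf("<session_summary> %d session(s), mean procedure duration %.1f s\n",
              x$n_sessions, x$total_duration_s))
  print(x$per_movement, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Compare two session summaries
#'
#' Per-movement change from session (or summary) `a` to `b`: the signed
#' ROM and duration deltas `b - a`, the quantity used to track mobility
#' over time across repeated examinations.
#'
#' @param a,b `session_summary` objects over the same movement set.
#' @return A data frame with `movement`, `rom_delta_deg`,
#'   `duration_delta_s`.
#' @export
compare_sessions <- function(a, b) {
  stopifnot(inherits(a, "session_summary"), inherits(b, "session_summary"))
  ma <- a$per_movement; mb <- b$per_movement
  if (!setequal(ma$movement, mb$movement)) {
    stop("sessions cover different movement sets", call. = FALSE)
  }
  mb <- mb[match(ma$movement, mb$movement), ]
  data.frame(movement = ma$movement,
             rom_delta_deg = mb$mean_deg - ma$mean_deg,
             duration_delta_s = mb$mean_duration_s - ma$mean_duration_s,
             stringsAsFactors = FALSE)
}
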