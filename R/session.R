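#' Analyze a head-pose session
#'
#' The package's central entry point: runs the full pipeline on a
#' recorded (or simulated) pose stream — neutral calibration, anatomical
#' angle decomposition, movement-episode segmentation, per-movement
#' signed ROM and duration, cross-plane compensation detection, and
#' protocol-order validation.
#'
#' @param stream A [pose_stream()], or a path to a session CSV readable
#'   by [read_session()].
#' @param calib Optional [neutral_calibration()]; by default the neutral
#'   is estimated from the stream's initial still window.
#' @param config A [segmentation_config()].
#' @param norms A [normative_ranges()] vector for norm-exceedance
#'   flagging (may be empty).
#' @param comp_band_deg Off-plane neutral band for co-movement flags,
#'   degrees.
#' @param meta Optional named list of session metadata (user_id,
#'   session_id, device, ...), carried into reports.
#' @return An object of class `"cervrom_session"` with components
#'   `angles` (the [angle_series()]), `calibration`, `episodes`, `rom`
#'   (per-movement table), `compensations`, `order` (protocol-order
#'   report), `asymmetry` (per-plane left/right differences where both
#'   directions are present), `config` and `meta`. Supports `print()`,
#'   `summary()`, `coef()` (named signed ROM vector) and `plot()` (the
#'   posturographic trajectory plot).
#' @examples
#' sim <- simulate_protocol(protocol_config(seed = 7))
#' fit <- analyze_session(sim$stream)
#' coef(fit)
#' summary(fit)
#' @export
analyze_session <- function(stream, calib = NULL,
                            config = segmentation_config(),
                            norms = normative_ranges(),
                            comp_band_deg = 5, meta = list()) {
  if (is.character(stream)) {
    sess <- read_session(stream)
    meta <- utils::modifyList(sess$meta, meta)
    stream <- sess$stream
  }
  stopifnot(inherits(stream, "pose_stream"))
  if (is.null(calib)) calib <- estimate_neutral(stream)
  series <- angles_timeseries(stream, calib)
  episodes <- segment_episodes(series, config)
  rom <- rom_table(episodes, series)
  comps <- lapply(seq_len(nrow(episodes)), function(i) {
    detect_compensations(episodes[i, ], series, norms, comp_band_deg)
  })
  asym <- session_asymmetry(rom)
  structure(list(angles = series, calibration = calib, episodes = episodes,
                 rom = rom, compensations = comps,
                 order = validate_protocol_order(episodes),
                 asymmetry = asym, config = config, norms = norms,
                 meta = meta, n_samples = length(stream),
                 rate_hz = stream$rate_hz),
            class = "cervrom_session")
}

session_asymmetry <- function(rom) {
  out <- list()
  for (plane in names(PLANE_PAIRS)) {
    pair <- PLANE_PAIRS[[plane]]
    l <- rom[rom$label == pair[1], ]
    r <- rom[rom$label == pair[2], ]
    if (nrow(l) == 1L && nrow(r) == 1L) {
      out[[plane]] <- duration_asymmetry(l, r)
    }
  }
  out
}

#' @export
print.cervrom_session <- function(x, ...) {
  cat(sprintf("<cervrom_session> %d samples @ %g Hz, %d episode(s)%s\n",
              x$n_samples, x$rate_hz, nrow(x$episodes),
              if (x$order$ok) ", protocol order OK" else ""))
  if (nrow(x$rom)) print(x$rom, row.names = FALSE, digits = 4)
  if (!x$order$ok) cat(paste0("  ! ", x$order$flags, collapse = "\n"), "\n")
  invisible(x)
}

#' Per-movement signed ROM of an analyzed session
#' @param object A `cervrom_session`.
#' @param ... Unused.
#' @return Named numeric vector of signed ROM in degrees.
#' @export
coef.cervrom_session <- function(object, ...) {
  stats::setNames(object$rom$rom_signed_deg, object$rom$label)
}

#' Summarize an analyzed session
#' @param object A `cervrom_session`.
#' @param ... Unused.
#' @return A [summarize_sessions()] `session_summary` of this session.
#' @export
summary.cervrom_session <- function(object, ...) {
  summarize_sessions(list(object$rom))
}

#' Posturographic trajectory plot of an analyzed session
#' @param x A `cervrom_session`.
#' @param ... Passed to [render_trajectory_plot()].
#' @export
plot.cervrom_session <- function(x, ...) {
  render_trajectory_plot(x$angles, x$episodes, ...)
}
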