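# Session file formats and report serialization. A session on disk is a
# samples CSV (t_s, qw, qx, qy, qz[, px, py, pz] -- quaternion column
# order is scalar-first and spelled out in the header to avoid the
# x,y,z,w ambiguity) plus a metadata JSON sidecar. Reports are a JSON
# bundle plus a one-row-per-movement summary CSV.

SESSION_COLS <- c("t_s", "qw", "qx", "qy", "qz")

#' Write a session to disk
#'
#' Serializes a pose stream as a samples CSV and a metadata JSON
#' sidecar. Numbers are written with 12 significant digits so the
#' write/read round trip reproduces the stream at full working
#' precision.
#'
#' @param stream A [pose_stream()].
#' @param path Path of the samples CSV; the metadata sidecar is written
#'   next to it as `<path without .csv>.meta.json`.
#' @param meta Named list of session metadata (`user_id`, `session_id`,
#'   `device`, ...); `rate_hz` is recorded automatically.
#' @return Invisibly, a character vector of the two file paths.
#' @export
write_session <- function(stream, path, meta = list()) {
  stopifnot(inherits(stream, "pose_stream"))
  df <- data.frame(t_s = stream$t, qw = stream$q[, 1], qx = stream$q[, 2],
                   qy = stream$q[, 3], qz = stream$q[, 4])
  if (!is.null(stream$p)) {
    df$px <- stream$p[, 1]; df$py <- stream$p[, 2]; df$pz <- stream$p[, 3]
  }
  for (j in seq_along(df)) df[[j]] <- formatC(df[[j]], format = "g", digits = 12)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta_path <- meta_path_for(path)
  meta$rate_hz <- stream$rate_hz
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(path, meta_path))
}

meta_path_for <- function(path) paste0(sub("\\.csv$", "", path), ".meta.json")

#' Read a session from disk
#'
#' Parses and validates a samples CSV written by [write_session()] (or
#' any file with the same columns). Missing quaternion columns are a
#' parse error; non-monotonic timestamps a validation error.
#'
#' @param path Path of the samples CSV.
#' @return A list with `stream` (a [pose_stream()]) and `meta` (the
#'   sidecar metadata, or an empty list if no sidecar exists).
#' @export
read_session <- function(path) {
  if (!file.exists(path)) stop("session file not found: ", path, call. = FALSE)
  df <- tryCatch(utils::read.csv(path, check.names = FALSE),
                 error = function(e) stop("malformed session CSV (", path, "): ",
                                          conditionMessage(e), call. = FALSE))
  missing <- setdiff(SESSION_COLS, names(df))
  if (length(missing)) {
    stop("session CSV is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!vapply(df[SESSION_COLS], is.numeric, TRUE))
  if (length(bad)) {
    stop("non-numeric values in session CSV column(s): ",
         paste(SESSION_COLS[bad], collapse = ", "), call. = FALSE)
  }
  if (is.unsorted(df$t_s, strictly = TRUE)) {
    i <- which(diff(df$t_s) <= 0)[1]
    stop(sprintf("timestamps not strictly increasing at data line %d", i + 1L),
         call. = FALSE)
  }
  meta_path <- meta_path_for(path)
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else list()
  rate <- if (!is.null(meta$rate_hz)) meta$rate_hz else 60
  p <- if (all(c("px", "py", "pz") %in% names(df))) {
    as.matrix(df[, c("px", "py", "pz")])
  } else NULL
  list(stream = pose_stream(df$t_s, as.matrix(df[, c("qw", "qx", "qy", "qz")]),
                            p = p, rate_hz = rate),
       meta = as.list(meta))
}

#' Geometric model of the posturographic trajectory plot
#'
#' Builds the plot as data before drawing: two fixed reference lines
#' crossing at the neutral origin at exactly 90 degrees (the
#' posturographic grid), and the measured head trace in grid
#' coordinates — horizontal = rotation (right +), vertical =
#' flexion-extension (flexion +), with the lateral-flexion channel
#' carried as the tilt of the moving head line. Plot geometry
#' (orthogonality, trace location) is asserted on this model, not on
#' rendered pixels.
#'
#' @param series An [angle_series()].
#' @param episodes Optional `movement_episodes` for shaded spans.
#' @return A list of class `"trajectory_plot_model"`: `ref_lines` (list
#'   of two unit direction vectors), `ref_angle_deg` (angle between
#'   them), `trace` (data frame `x`, `y`, `tilt_deg`), `episodes`.
#' @export
trajectory_plot_model <- function(series, episodes = NULL) {
  stopifnot(nrow(series) > 0)
  u <- c(1, 0)  # fixed horizontal reference line
  v <- c(0, 1)  # fixed vertical reference line
  ref_angle <- acos(sum(u * v)) * 180 / pi
  structure(list(
    ref_lines = list(horizontal = u, vertical = v),
    ref_angle_deg = ref_angle,
    trace = data.frame(x = series$rotation, y = series$flexion_extension,
                       tilt_deg = series$lateral_flexion),
    episodes = episodes),
    class = "trajectory_plot_model")
}

#' Render the posturographic trajectory plot
#'
#' Draws the [trajectory_plot_model()]: the two orthogonal reference
#' lines of the grid, the head trace coloured by time, and shaded
#' episode spans in a lower timeline panel. Axes carry the clinical sign
#' conventions.
#'
#' @param series An [angle_series()].
#' @param episodes Optional `movement_episodes`.
#' @param file Optional output image path (`.png` or `.pdf`); when
#'   `NULL`, draws on the active device.
#' @param width,height Device size in pixels (png) or inches (pdf).
#' @return Invisibly, the `trajectory_plot_model`.
#' @export
render_trajectory_plot <- function(series, episodes = NULL, file = NULL,
                                   width = 800, height = 800) {
  model <- trajectory_plot_model(series, episodes)
  if (!is.null(file)) {
    if (grepl("\\.pdf$", file)) {
      grDevices::pdf(file, width = width / 100, height = height / 100)
    } else {
      grDevices::png(file, width = width, height = height)
    }
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  lim <- max(10, abs(c(model$trace$x, model$trace$y))) * 1.1
  graphics::plot(NA, xlim = c(-lim, lim), ylim = c(-lim, lim), asp = 1,
                 xlab = "rotation [deg]  (left − | + right)",
                 ylab = "flexion-extension [deg]  (extension − | + flexion)",
                 main = "Head trajectory on posturographic grid")
  graphics::abline(h = 0, col = "goldenrod2", lwd = 2)  # fixed reference grid
  graphics::abline(v = 0, col = "goldenrod2", lwd = 2)
  n <- nrow(model$trace)
  cols <- grDevices::hcl.colors(max(n, 2), "Reds", rev = TRUE)
  graphics::segments(model$trace$x[-n], model$trace$y[-n],
                     model$trace$x[-1], model$trace$y[-1], col = cols[-1])
  if (!is.null(episodes) && nrow(episodes)) {
    for (i in seq_len(nrow(episodes))) {
      sel <- series$t_s >= episodes$start_s[i] & series$t_s <= episodes$end_s[i]
      graphics::points(model$trace$x[sel], model$trace$y[sel], pch = ".",
                       col = "red3")
    }
    graphics::legend("topleft", legend = episodes$label, bty = "n", cex = 0.8,
                     text.col = "red3")
  }
  invisible(model)
}

#' Export a report bundle
#'
#' Writes the analyzed session as a schema-checked report JSON and a
#' summary CSV with one row per movement (`movement, min_deg, max_deg,
#' mean_deg, mean_duration_s`). Output is deterministic: fixed key
#' order and fixed float formatting, so re-exporting an identical bundle
#' is byte-identical.
#'
#' @param fit A `cervrom_session` from [analyze_session()].
#' @param dir Output directory (created if needed).
#' @param name Basename for the report files (default `"report"`).
#' @return Invisibly, the paths written (`json`, `csv`).
#' @export
export_report <- function(fit, dir, name = "report") {
  stopifnot(inherits(fit, "cervrom_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  smry <- if (nrow(fit$rom)) summarize_sessions(list(fit$rom)) else NULL
  if (is.null(smry)) warning("no episodes detected; writing header-only summary",
                             call. = FALSE)
  bundle <- list(
    meta = fit$meta,
    n_samples = fit$n_samples,
    rate_hz = fit$rate_hz,
    episodes = fit$episodes,
    rom = fit$rom,
    compensations = lapply(fit$compensations, function(cr) {
      list(label = cr$label, primary_peak_deg = round(cr$primary_peak_deg, 2),
           offplane = within(cr$offplane, {
             peak_signed_deg <- round(peak_signed_deg, 2)
             coupling_ratio <- round(coupling_ratio, 4)
           }),
           flags = cr$flags)
    }),
    order = fit$order,
    asymmetry = fit$asymmetry,
    summary = if (is.null(smry)) NULL else list(
      per_movement = smry$per_movement,
      total_duration_s = round(smry$total_duration_s, 2)))
  check_report_schema(bundle)
  json_path <- file.path(dir, paste0(name, ".json"))
  csv_path <- file.path(dir, paste0(name, "_summary.csv"))
  jsonlite::write_json(bundle, json_path, auto_unbox = TRUE, digits = 4,
                       pretty = TRUE, null = "null", dataframe = "rows")
  per <- if (is.null(smry)) {
    data.frame(movement = character(0), min_deg = numeric(0),
               max_deg = numeric(0), mean_deg = numeric(0),
               mean_duration_s = numeric(0))
  } else smry$per_movement
  num <- vapply(per, is.numeric, TRUE)
  per[num] <- lapply(per[num], function(x) formatC(x, format = "f", digits = 2))
  utils::write.csv(per, csv_path, row.names = FALSE, quote = FALSE)
  invisible(c(json = json_path, csv = csv_path))
}

# minimal structural schema check, run before anything is written
check_report_schema <- function(bundle) {
  required <- c("meta", "n_samples", "rate_hz", "episodes", "rom",
                "compensations", "order", "summary")
  missing <- setdiff(required, names(bundle))
  if (length(missing)) {
    stop("report bundle missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(is.data.frame(bundle$episodes), is.data.frame(bundle$rom))
  if (length(bundle$compensations) != nrow(bundle$episodes)) {
    stop("every detected episode must appear exactly once in compensations",
         call. = FALSE)
  }
  need_cols <- c("label", "rom_signed_deg", "duration_s")
  if (!all(need_cols %in% names(bundle$rom)) && nrow(bundle$rom) > 0) {
    stop("rom table malformed", call. = FALSE)
  }
  invisible(TRUE)
}
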