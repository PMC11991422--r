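#' Head-pose stream
#'
#' A pose stream is the raw measurement record of a tracking session:
#' timestamped unit-quaternion head orientations sampled at a nominal rate
#' (60 Hz for the headset this package targets), optionally with a head
#' position in metres.
#'
#' @param t Numeric vector of timestamps in seconds from session start,
#'   strictly increasing, first value `>= 0`.
#' @param q An `n x 4` matrix of quaternion components in `w, x, y, z`
#'   order. Rows are normalized; rows far from unit norm trigger a warning.
#' @param p Optional `n x 3` matrix of head positions in metres.
#' @param rate_hz Nominal sampling rate in Hz (default 60). If the median
#'   inter-sample interval deviates from `1/rate_hz` by more than 10% a
#'   rate-mismatch warning is raised.
#' @return An object of class `"pose_stream"`: a list with elements
#'   `t`, `q`, `p` (or `NULL`) and `rate_hz`.
#' @seealso [angles_timeseries()], [simulate_protocol()], [read_session()]
#' @export
pose_stream <- function(t, q, p = NULL, rate_hz = 60) {
  t <- as.numeric(t)
  q <- as.matrix(q)
  if (ncol(q) != 4L) stop("q must have 4 columns (w, x, y, z)", call. = FALSE)
  if (length(t) != nrow(q)) stop("t and q lengths differ", call. = FALSE)
  if (length(t) < 1L) stop("empty stream", call. = FALSE)
  if (any(t < 0)) stop("timestamps must be non-negative", call. = FALSE)
  if (length(t) > 1L && any(diff(t) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  norms <- sqrt(rowSums(q^2))
  if (any(norms < 1e-12)) stop("zero quaternion in stream", call. = FALSE)
  if (any(abs(norms - 1) > QUAT_NORM_TOL)) {
    warning("non-unit quaternions in stream; normalizing", call. = FALSE)
  }
  q <- q / norms
  colnames(q) <- c("w", "x", "y", "z")
  if (!is.null(p)) {
    p <- as.matrix(p)
    if (nrow(p) != length(t) || ncol(p) != 3L) {
      stop("p must be an n x 3 matrix aligned with t", call. = FALSE)
    }
    colnames(p) <- c("px", "py", "pz")
  }
  if (length(t) > 2L && is.finite(rate_hz) && rate_hz > 0) {
    med_dt <- stats::median(diff(t))
    if (abs(med_dt - 1 / rate_hz) > 0.1 / rate_hz) {
      warning(sprintf(
        "rate mismatch: median interval %.4fs vs nominal %.4fs (%g Hz)",
        med_dt, 1 / rate_hz, rate_hz), call. = FALSE)
    }
  }
  structure(list(t = t, q = q, p = p, rate_hz = rate_hz), class = "pose_stream")
}

#' @export
print.pose_stream <- function(x, ...) {
  cat(sprintf("<pose_stream> %d samples, %.2f s @ nominal %g Hz%s\n",
              length(x$t), diff(range(x$t)), x$rate_hz,
              if (is.null(x$p)) "" else ", with position"))
  invisible(x)
}

#' Number of samples in a pose stream
#' @param x A `pose_stream`.
#' @export
length.pose_stream <- function(x) length(x$t)

#' Anatomical angle triple
#'
#' Signed cervical angles in degrees following the clinical sign
#' convention used throughout the package: flexion `+` / extension `-`
#' (sagittal plane), left lateral flexion `+` / right `-` (frontal plane),
#' right rotation `+` / left `-` (transverse plane). All three are exactly
#' zero at the calibrated neutral orientation.
#'
#' @param flexion_extension,lateral_flexion,rotation Angles in degrees.
#' @return A named numeric vector of class `"anatomical_angles"`.
#' @export
anatomical_angles <- function(flexion_extension = 0, lateral_flexion = 0, rotation = 0) {
  a <- c(flexion_extension = as.numeric(flexion_extension),
         lateral_flexion = as.numeric(lateral_flexion),
         rotation = as.numeric(rotation))
  stopifnot(all(is.finite(a)))
  if (any(a <= -180 | a > 180)) stop("angles must lie in (-180, 180]", call. = FALSE)
  structure(a, class = "anatomical_angles")
}

#' @export
print.anatomical_angles <- function(x, ...) {
  cat(sprintf("flexion-extension % .2f deg | lateral % .2f deg | rotation % .2f deg\n",
              x[["flexion_extension"]], x[["lateral_flexion"]], x[["rotation"]]))
  invisible(x)
}

ANGLE_CHANNELS <- c("flexion_extension", "lateral_flexion", "rotation")

#' Per-frame anatomical angle record
#'
#' The decomposed per-sample record behind session trajectory graphs: a
#' data frame with time and the three signed angle channels.
#'
#' @param t Timestamps in seconds.
#' @param flexion_extension,lateral_flexion,rotation Angle channels in
#'   degrees (equal length, aligned with `t`).
#' @return A data frame of class `"angle_series"` with columns `t_s`,
#'   `flexion_extension`, `lateral_flexion`, `rotation`.
#' @export
angle_series <- function(t, flexion_extension, lateral_flexion, rotation) {
  n <- length(t)
  stopifnot(length(flexion_extension) == n, length(lateral_flexion) == n,
            length(rotation) == n)
  structure(
    data.frame(t_s = as.numeric(t),
               flexion_extension = as.numeric(flexion_extension),
               lateral_flexion = as.numeric(lateral_flexion),
               rotation = as.numeric(rotation)),
    class = c("angle_series", "data.frame"))
}

as_angle_matrix <- function(series) {
  as.matrix(as.data.frame(series)[, ANGLE_CHANNELS, drop = FALSE])
}
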