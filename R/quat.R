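# Quaternion primitives. Orientations are unit quaternions stored as
# numeric vectors c(w, x, y, z) (scalar first). Streams keep an n x 4
# matrix with the same column order; the vectorised helpers below operate
# on those matrices row-wise.

QUAT_NORM_TOL <- 1e-6

#' Construct a quaternion
#'
#' Builds a quaternion from its scalar-first components. Quaternions within
#' `1e-6` of unit norm are accepted as orientations; anything else is
#' normalized with a warning, and the zero quaternion is an error.
#'
#' @param w,x,y,z Real components (scalar part first).
#' @param normalize If `TRUE` (default) the result is scaled to unit norm.
#' @return A numeric vector of class `"quat"` with components `w, x, y, z`.
#' @examples
#' quat(1, 0, 0, 0)              # identity
#' quat_from_axis_angle(c(0, 1, 0), 45)
#' @export
quat <- function(w, x = 0, y = 0, z = 0, normalize = TRUE) {
  if (length(w) == 4L && missing(x)) {
    q <- as.numeric(w)
  } else {
    q <- c(w, x, y, z)
  }
  stopifnot(length(q) == 4L, all(is.finite(q)))
  n <- sqrt(sum(q^2))
  if (n < 1e-12) {
    stop("zero quaternion does not represent an orientation", call. = FALSE)
  }
  if (normalize) {
    if (abs(n - 1) > QUAT_NORM_TOL) {
      warning(sprintf("quaternion norm %.6g deviates from 1 beyond tolerance; normalizing", n),
              call. = FALSE)
    }
    q <- q / n
  }
  structure(q, names = c("w", "x", "y", "z"), class = "quat")
}

#' @export
print.quat <- function(x, ...) {
  cat(sprintf("<quat> w=% .6f x=% .6f y=% .6f z=% .6f\n", x[1], x[2], x[3], x[4]))
  invisible(x)
}

#' Quaternion identity
#' @return The identity orientation as a `quat`.
#' @export
quat_identity <- function() quat(1, 0, 0, 0)

#' Hamilton product of two quaternions
#'
#' @param a,b Quaternions (`quat` or length-4 numeric, scalar first).
#' @return Their Hamilton product `a * b` as a `quat` (composition: apply
#'   `b`'s rotation first, then `a`'s, in the active convention).
#' @export
quat_multiply <- function(a, b) {
  quat(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
       a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
       a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
       a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1],
       normalize = FALSE)
}

#' Quaternion conjugate / inverse of a unit quaternion
#' @param q A unit quaternion.
#' @return The conjugate (= inverse for unit norm) as a `quat`.
#' @export
quat_conjugate <- function(q) quat(q[1], -q[2], -q[3], -q[4], normalize = FALSE)

#' Canonical hemisphere form
#'
#' `q` and `-q` encode the same orientation; the canonical representative
#' has non-negative scalar part.
#' @param q A quaternion.
#' @return `q` or `-q`, whichever has `w >= 0`.
#' @export
quat_canonical <- function(q) {
  if (q[1] < 0) quat(-q[1], -q[2], -q[3], -q[4], normalize = FALSE) else quat(q, normalize = FALSE)
}

#' Axis-angle construction
#' @param axis Length-3 rotation axis (need not be unit length).
#' @param angle_deg Rotation angle in degrees (right-hand rule about `axis`).
#' @return The corresponding unit `quat`.
#' @export
quat_from_axis_angle <- function(axis, angle_deg) {
  axis <- as.numeric(axis)
  stopifnot(length(axis) == 3L)
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) stop("rotation axis must be non-zero", call. = FALSE)
  axis <- axis / n
  h <- angle_deg * pi / 360  # half angle in radians
  quat(cos(h), sin(h) * axis[1], sin(h) * axis[2], sin(h) * axis[3], normalize = FALSE)
}

#' Rotation matrix of a unit quaternion
#' @param q A unit quaternion.
#' @return The 3x3 rotation matrix (active, column-vector convention).
#' @export
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Unit quaternion from a rotation matrix
#'
#' Shepperd's method: branch on the largest diagonal combination for
#' numerical stability.
#' @param m A 3x3 rotation matrix.
#' @return The canonical-hemisphere unit `quat`.
#' @export
quat_from_matrix <- function(m) {
  stopifnot(is.matrix(m), all(dim(m) == c(3, 3)))
  tr <- m[1, 1] + m[2, 2] + m[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(s / 4, (m[3, 2] - m[2, 3]) / s, (m[1, 3] - m[3, 1]) / s, (m[2, 1] - m[1, 2]) / s)
  } else if (m[1, 1] > m[2, 2] && m[1, 1] > m[3, 3]) {
    s <- sqrt(1 + m[1, 1] - m[2, 2] - m[3, 3]) * 2
    q <- c((m[3, 2] - m[2, 3]) / s, s / 4, (m[1, 2] + m[2, 1]) / s, (m[1, 3] + m[3, 1]) / s)
  } else if (m[2, 2] > m[3, 3]) {
    s <- sqrt(1 + m[2, 2] - m[1, 1] - m[3, 3]) * 2
    q <- c((m[1, 3] - m[3, 1]) / s, (m[1, 2] + m[2, 1]) / s, s / 4, (m[2, 3] + m[3, 2]) / s)
  } else {
    s <- sqrt(1 + m[3, 3] - m[1, 1] - m[2, 2]) * 2
    q <- c((m[2, 1] - m[1, 2]) / s, (m[1, 3] + m[3, 1]) / s, (m[2, 3] + m[3, 2]) / s, s / 4)
  }
  quat_canonical(quat(q[1], q[2], q[3], q[4]))
}

#' Geodesic angle between two orientations
#' @param a,b Unit quaternions.
#' @return Rotation angle in degrees taking `a` to `b` (hemisphere-safe).
#' @export
quat_angle_deg <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (sum(a * b) < 0) b <- -b
  # 4*atan2 form is accurate near zero where acos(dot) is not
  4 * atan2(sqrt(sum((a - b)^2)), sqrt(sum((a + b)^2))) * 180 / pi
}

# ---- row-wise matrix versions (n x 4, columns w,x,y,z) ----------------------

qm_normalize <- function(Q) Q / sqrt(rowSums(Q^2))

# normalize without the unit-norm warning (for intentional means)
quat_unit <- function(x) {
  x <- as.numeric(x)
  quat(x / sqrt(sum(x^2)), normalize = FALSE)
}

# hemisphere-align every row to a reference quaternion (flip rows with
# negative dot product)
qm_align <- function(Q, ref) {
  s <- sign(Q %*% as.numeric(ref))
  s[s == 0] <- 1
  Q * as.vector(s)
}

# row-wise Hamilton product of two n x 4 matrices (or one row recycled)
qm_multiply <- function(A, B) {
  if (is.null(dim(A))) A <- matrix(A, nrow = nrow(B), ncol = 4, byrow = TRUE)
  if (is.null(dim(B))) B <- matrix(B, nrow = nrow(A), ncol = 4, byrow = TRUE)
  cbind(
    A[, 1] * B[, 1] - A[, 2] * B[, 2] - A[, 3] * B[, 3] - A[, 4] * B[, 4],
    A[, 1] * B[, 2] + A[, 2] * B[, 1] + A[, 3] * B[, 4] - A[, 4] * B[, 3],
    A[, 1] * B[, 3] - A[, 2] * B[, 4] + A[, 3] * B[, 1] + A[, 4] * B[, 2],
    A[, 1] * B[, 4] + A[, 2] * B[, 3] - A[, 3] * B[, 2] + A[, 4] * B[, 1]
  )
}

qm_conjugate <- function(Q) cbind(Q[, 1], -Q[, 2], -Q[, 3], -Q[, 4])
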