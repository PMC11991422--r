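# Independent rotation-matrix oracle. Everything here goes through 3x3
# matrices built from first principles (no package quaternion code), so
# the kinematics implementation can be checked against a genuinely
# separate path.

rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
rot_y <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)

# rotation matrix about an arbitrary unit axis (Rodrigues' formula)
rot_axis <- function(axis, angle_deg) {
  a <- angle_deg * pi / 180
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

# matrix of a unit quaternion, written out independently of quat_to_matrix
oracle_quat_matrix <- function(q) {
  q <- unname(as.numeric(q))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(
    c(w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z), 2 * (x * z + w * y)),
    c(2 * (x * y + w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x)),
    c(2 * (x * z - w * y), 2 * (y * z + w * x), w^2 - x^2 - y^2 + z^2))
}

# anatomical angles from a rotation matrix: intrinsic Y-X-Z extraction
# plus the clinical sign map, derived directly from the product
# Ry(yaw) Rx(pitch) Rz(roll)
oracle_angles_from_matrix <- function(m) {
  pitch <- asin(max(-1, min(1, -m[2, 3])))
  yaw <- atan2(m[1, 3], m[3, 3])
  roll <- atan2(m[2, 1], m[2, 2])
  c(flexion_extension = -pitch, lateral_flexion = roll, rotation = -yaw) * 180 / pi
}

# matrix built from anatomical angles by composing the three elementary
# rotations (the forward direction of the oracle)
oracle_matrix_from_angles <- function(a) {
  rot_y(-a[3] * pi / 180) %*% rot_x(-a[1] * pi / 180) %*% rot_z(a[2] * pi / 180)
}

random_unit_quats <- function(n) {
  m <- matrix(stats::rnorm(4 * n), n, 4)
  m / sqrt(rowSums(m^2))
}

# Jaccard overlap of two closed intervals
interval_jaccard <- function(a0, a1, b0, b1) {
  inter <- max(0, min(a1, b1) - max(a0, b0))
  union <- max(a1, b1) - min(a0, b0)
  inter / union
}
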