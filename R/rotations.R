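# Rotation and Euler-angle utilities shared by the pose-fitting and joint
# kinematics code. Convention throughout: rotation matrices act on column
# vectors (world = R %*% local + t); Euler angles follow the intrinsic
# z-y-x order used for joint coordinate systems, in degrees.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

rot_x <- function(deg) {
  a <- deg2rad(deg)
  matrix(c(1, 0, 0,
           0, cos(a), sin(a),
           0, -sin(a), cos(a)), 3, 3)
}

rot_y <- function(deg) {
  a <- deg2rad(deg)
  matrix(c(cos(a), 0, -sin(a),
           0, 1, 0,
           sin(a), 0, cos(a)), 3, 3)
}

rot_z <- function(deg) {
  a <- deg2rad(deg)
  matrix(c(cos(a), sin(a), 0,
           -sin(a), cos(a), 0,
           0, 0, 1), 3, 3)
}

#' Compose a rotation from intrinsic z-y-x Euler angles
#'
#' Builds the rotation matrix `Rz(rz) %*% Ry(ry) %*% Rx(rx)`, i.e. an
#' intrinsic (body-fixed) rotation first about z, then the new y, then the
#' new x — the rotation order used by joint coordinate systems in marker
#' based motion analysis.
#'
#' @param rz,ry,rx rotations in degrees.
#' @return a 3x3 proper rotation matrix.
#' @seealso [euler_zyx_decompose()]
#' @export
euler_zyx_compose <- function(rz, ry, rx) {
  rot_z(rz) %*% rot_y(ry) %*% rot_x(rx)
}

#' Decompose a rotation into intrinsic z-y-x Euler angles
#'
#' Inverse of [euler_zyx_compose()]. The middle angle is returned in
#' `[-90, 90]` degrees; when `|ry|` is within ~0.057 deg (1e-3 rad) of 90
#' degrees the decomposition is degenerate (gimbal lock) and the returned
#' `gimbal` flag is set (values are still returned, with `rx` forced to 0).
#'
#' @param R a 3x3 rotation matrix.
#' @return a list with elements `rz`, `ry`, `rx` (degrees) and logical
#'   `gimbal`.
#' @export
euler_zyx_decompose <- function(R) {
  sy <- -R[3, 1]
  sy <- max(-1, min(1, sy))
  ry <- asin(sy)
  gimbal <- abs(abs(ry) - pi / 2) < 1e-3
  if (gimbal) {
    # rz and rx are not separable; conventionally attribute all to rz
    rz <- atan2(-R[1, 2], R[2, 2])
    rx <- 0
  } else {
    rz <- atan2(R[2, 1], R[1, 1])
    rx <- atan2(R[3, 2], R[3, 3])
  }
  list(rz = rad2deg(rz), ry = rad2deg(ry), rx = rad2deg(rx), gimbal = gimbal)
}

# rotation matrix -> unit quaternion (w, x, y, z), Shepperd's method
rot_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  q / sqrt(sum(q^2))
}

quat_to_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

# angle (deg) of the relative rotation between two rotation matrices
rotation_angle_deg <- function(R1, R2 = diag(3)) {
  Rrel <- t(R1) %*% R2
  ca <- (sum(diag(Rrel)) - 1) / 2
  rad2deg(acos(max(-1, min(1, ca))))
}
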