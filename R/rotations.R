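#' @title Rotations and rigid transforms
#' @description Internal helpers for body-fixed (intrinsic) x-y-z Euler
#'   rotations in degrees, quaternion utilities, and rigid transforms
#'   represented as `list(R = 3x3, p = length-3)`.
#' @name rotations
#' @keywords internal
NULL

DEG2RAD <- pi / 180
RAD2DEG <- 180 / pi

#' Rotation matrix from body-fixed xyz Euler angles
#'
#' Angles are interpreted as an intrinsic (body-fixed) rotation about x, then
#' the new y, then the new z, i.e. `R = Rx(a) %*% Ry(b) %*% Rz(c)`. This is
#' the convention used throughout the spine model: x mediolateral
#' (flexion-extension), y inferosuperior (axial rotation), z
#' posterior-anterior (lateroflexion).
#'
#' @param eul_deg numeric length-3, angles in degrees (x, y, z).
#' @return 3x3 rotation matrix.
#' @export
eul_to_rot <- function(eul_deg) {
  stopifnot(length(eul_deg) == 3L, is.finite(eul_deg))
  rot_xyz(eul_deg[1], eul_deg[2], eul_deg[3])
}

## unchecked fast path used by the kinematics inner loops (angles in degrees)
rot_xyz <- function(ax, ay, az) {
  a <- ax * DEG2RAD; b <- ay * DEG2RAD; c <- az * DEG2RAD
  ca <- cos(a); sa <- sin(a); cb <- cos(b); sb <- sin(b); cc <- cos(c); sc <- sin(c)
  ## column-major fill of R = Rx %*% Ry %*% Rz
  matrix(c(cb * cc, ca * sc + sa * sb * cc, sa * sc - ca * sb * cc,
           -cb * sc, ca * cc - sa * sb * sc, sa * cc + ca * sb * sc,
           sb, -sa * cb, ca * cb), nrow = 3)
}

#' Body-fixed xyz Euler angles from a rotation matrix
#'
#' Inverse of [eul_to_rot()]. When the middle angle approaches +/-90 deg the
#' decomposition degenerates (gimbal lock); a warning is raised beyond 80 deg,
#' a regime never reached by physiological intervertebral angles.
#'
#' @param R 3x3 rotation matrix.
#' @return numeric length-3, degrees.
#' @export
rot_to_eul <- function(R) {
  sb <- max(-1, min(1, R[1, 3]))
  b <- asin(sb)
  if (abs(b) > 80 * DEG2RAD) {
    warning("Euler decomposition near gimbal lock (|y angle| > 80 deg)")
  }
  a <- atan2(-R[2, 3], R[3, 3])
  c <- atan2(-R[1, 2], R[1, 1])
  c(a, b, c) * RAD2DEG
}

## unit quaternion (w, x, y, z) from rotation matrix; robust Shepperd method
rot_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
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
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Chordal mean of rotations
#'
#' Quaternion chordal L2 mean (largest-eigenvector method) with hemisphere
#' alignment against the first rotation. Unique and order-independent for the
#' small dispersions (one to a few degrees) produced by operator variability;
#' the mean of identical rotations is that rotation and symmetric pairs
#' average to their geodesic midpoint.
#'
#' @param rotations list of 3x3 rotation matrices.
#' @return 3x3 rotation matrix.
#' @export
mean_rotation <- function(rotations) {
  stopifnot(length(rotations) >= 1L)
  qs <- lapply(rotations, rot_to_quat)
  q0 <- qs[[1]]
  M <- matrix(0, 4, 4)
  for (q in qs) {
    if (sum(q * q0) < 0) q <- -q
    M <- M + tcrossprod(q)
  }
  ev <- eigen(M, symmetric = TRUE)
  quat_to_rot(ev$vectors[, 1])
}

## rigid transforms -----------------------------------------------------------

tf <- function(R = diag(3), p = c(0, 0, 0)) list(R = R, p = as.numeric(p))

tf_compose <- function(a, b) {
  list(R = a$R %*% b$R, p = as.numeric(a$R %*% b$p) + a$p)
}

tf_inv <- function(a) {
  Rt <- t(a$R)
  list(R = Rt, p = as.numeric(-Rt %*% a$p))
}

## apply transform to an n x 3 matrix of points (or a length-3 vector)
tf_apply <- function(a, pts) {
  if (is.null(dim(pts))) return(as.numeric(a$R %*% pts) + a$p)
  sweep(pts %*% t(a$R), 2, a$p, "+")
}

## transform from position + Euler degrees
tf_pose <- function(p, eul_deg) tf(eul_to_rot(eul_deg), p)
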