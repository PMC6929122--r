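# Quaternion and rotation-matrix algebra.
#
# Conventions used throughout the package:
#   * quaternions are numeric length-4 vectors, scalar-first: c(q0, qx, qy, qz)
#   * a unit quaternion q represents the rotation v1 = q (x) (0, v2) (x) q^-1,
#     i.e. it rotates vectors expressed in frame 2 into frame 1
#   * quaternion traces are N x 4 matrices, one quaternion per row

.check_finite <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop(sprintf("'%s' must be finite numeric", name), call. = FALSE)
  }
  invisible(x)
}

#' Normalize a quaternion to unit length
#'
#' @param q Numeric length-4 quaternion, scalar-first.
#' @return Unit quaternion.
#' @export
quat_normalize <- function(q) {
  .check_finite(q, "q")
  n <- sqrt(sum(q^2))
  if (n < 1e-12) stop("cannot normalize a near-zero quaternion", call. = FALSE)
  q / n
}

#' Canonicalize a unit quaternion under the q / -q ambiguity
#'
#' Flips the sign so that the scalar part is non-negative; when the scalar
#' part is (numerically) zero, the first non-zero vector component is made
#' positive.  Makes quaternion comparisons deterministic.
#'
#' @param q Unit quaternion.
#' @return The canonical representative of the same rotation.
#' @export
quat_canonical <- function(q) {
  if (q[1] < 0) return(-q)
  if (q[1] == 0 || abs(q[1]) < 1e-12) {
    for (i in 2:4) {
      if (abs(q[i]) > 1e-12) {
        if (q[i] < 0) return(-q)
        return(q)
      }
    }
  }
  q
}

#' Quaternion conjugate
#'
#' For unit quaternions the conjugate is the inverse rotation.
#'
#' @param q Quaternion.
#' @return Conjugate quaternion.
#' @export
quat_conjugate <- function(q) c(q[1], -q[2], -q[3], -q[4])

#' Hamilton product of two quaternions
#'
#' Composes rotations: \code{quat_multiply(q, p)} applies \code{p} first,
#' then \code{q}.  The result is renormalized to unit length.
#'
#' @param q,p Unit quaternions, scalar-first.
#' @return Unit quaternion \code{q (x) p}.
#' @export
quat_multiply <- function(q, p) {
  .check_finite(q, "q"); .check_finite(p, "p")
  out <- c(
    q[1] * p[1] - q[2] * p[2] - q[3] * p[3] - q[4] * p[4],
    q[1] * p[2] + q[2] * p[1] + q[3] * p[4] - q[4] * p[3],
    q[1] * p[3] - q[2] * p[4] + q[3] * p[1] + q[4] * p[2],
    q[1] * p[4] + q[2] * p[3] - q[3] * p[2] + q[4] * p[1]
  )
  quat_normalize(out)
}

#' Rotate a 3-vector by a unit quaternion
#'
#' Computes \code{q (x) (0, v) (x) q^-1}, i.e. expresses a frame-2 vector in
#' frame 1 when \code{q} is the frame-2-to-frame-1 rotation.
#'
#' @param q Unit quaternion.
#' @param v Numeric 3-vector.
#' @return Rotated 3-vector with the same norm as \code{v}.
#' @export
quat_rotate <- function(q, v) {
  .check_finite(q, "q"); .check_finite(v, "v")
  qv <- q[2:4]
  t2 <- 2 * cross3(qv, v)
  v + q[1] * t2 + cross3(qv, t2)
}

#' Convert a unit quaternion to a rotation matrix
#'
#' @param q Unit quaternion.
#' @return 3x3 rotation matrix \code{R} with \code{R \%*\% v == quat_rotate(q, v)}.
#' @export
quat_to_matrix <- function(q) {
  q <- quat_normalize(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Convert a rotation matrix to the canonical unit quaternion
#'
#' Uses Shepperd's method (largest diagonal pivot) for numerical stability.
#'
#' @param R 3x3 rotation matrix.
#' @return Canonical unit quaternion.
#' @export
quat_from_matrix <- function(R) {
  stopifnot(is.matrix(R), all(dim(R) == c(3, 3)))
  .check_finite(R, "R")
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > max(R[1, 1], R[2, 2], R[3, 3])) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s,
           (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s,
           0.25 * s,
           (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s,
           (R[1, 2] + R[2, 1]) / s,
           0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s,
           (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s,
           0.25 * s)
  }
  quat_canonical(quat_normalize(q))
}

#' Quaternion from an axis and an angle
#'
#' @param axis 3-vector rotation axis (need not be unit length).
#' @param angle Rotation angle in radians.
#' @return Unit quaternion.
#' @export
quat_from_axis_angle <- function(axis, angle) {
  .check_finite(axis, "axis"); .check_finite(angle, "angle")
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) stop("rotation axis must be non-zero", call. = FALSE)
  c(cos(angle / 2), sin(angle / 2) * axis / n)
}

#' Shortest-arc quaternion rotating one unit vector onto another
#'
#' Half-angle construction about \code{u x v}: the returned quaternion
#' rotates \code{u} onto \code{v} through the angle \code{acos(u . v)}.
#' Antiparallel inputs have an undefined rotation axis and raise an error.
#'
#' @param u,v Unit 3-vectors.
#' @return Unit quaternion \code{q} with \code{quat_rotate(q, u) == v}.
#' @export
quat_from_two_vectors <- function(u, v) {
  .check_finite(u, "u"); .check_finite(v, "v")
  d <- sum(u * v)
  if (d < -1 + 1e-8) {
    stop("degenerate axis: input vectors are (near) antiparallel", call. = FALSE)
  }
  ax <- cross3(u, v)
  na <- sqrt(sum(ax^2))
  if (na < 1e-12) return(c(1, 0, 0, 0))   # (near) parallel: identity limit
  ang <- acos(max(-1, min(1, d)))
  c(cos(ang / 2), sin(ang / 2) * ax / na)
}

#' Rotation angle of a rotation matrix (axis-angle magnitude)
#'
#' The single rotation angle of the axis-angle decomposition,
#' \code{acos((trace(R) - 1) / 2)}, in degrees.  Used to compare orientation
#' traces between an estimate and a reference.
#'
#' @param R 3x3 rotation matrix.
#' @return Angle in degrees in \[0, 180\].
#' @export
axis_angle_magnitude <- function(R) {
  stopifnot(is.matrix(R), all(dim(R) == c(3, 3)))
  .check_finite(R, "R")
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr < -1 - 1e-6 || tr > 3 + 1e-6) {
    stop("invalid rotation matrix: trace outside [-1, 3]", call. = FALSE)
  }
  acos(max(-1, min(1, (tr - 1) / 2))) * 180 / pi
}

#' Skew-symmetric (cross-product) matrix of a 3-vector
#'
#' \code{skew(v) \%*\% u} equals \code{v x u}.
#'
#' @param v Numeric 3-vector.
#' @return 3x3 skew-symmetric matrix.
#' @export
skew <- function(v) {
  .check_finite(v, "v")
  matrix(c(0, -v[3], v[2],
           v[3], 0, -v[1],
           -v[2], v[1], 0), nrow = 3, byrow = TRUE)
}

#' Cross product of two 3-vectors
#'
#' @param a,b Numeric 3-vectors.
#' @return \code{a x b}.
#' @export
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# ---- vectorized (row-wise) quaternion helpers for traces ----------------

# Hamilton product of two N x 4 quaternion trace matrices, row by row.
quat_multiply_rows <- function(Q, P) {
  cbind(
    Q[, 1] * P[, 1] - Q[, 2] * P[, 2] - Q[, 3] * P[, 3] - Q[, 4] * P[, 4],
    Q[, 1] * P[, 2] + Q[, 2] * P[, 1] + Q[, 3] * P[, 4] - Q[, 4] * P[, 3],
    Q[, 1] * P[, 3] - Q[, 2] * P[, 4] + Q[, 3] * P[, 1] + Q[, 4] * P[, 2],
    Q[, 1] * P[, 4] + Q[, 2] * P[, 3] - Q[, 3] * P[, 2] + Q[, 4] * P[, 1]
  )
}

quat_conjugate_rows <- function(Q) cbind(Q[, 1], -Q[, 2], -Q[, 3], -Q[, 4])

quat_normalize_rows <- function(Q) Q / sqrt(rowSums(Q^2))

# Rotate the rows of an N x 3 matrix V by the corresponding rows of an
# N x 4 quaternion trace.
quat_rotate_rows <- function(Q, V) {
  qv <- Q[, 2:4, drop = FALSE]
  t2 <- 2 * cross3_rows(qv, V)
  V + Q[, 1] * t2 + cross3_rows(qv, t2)
}

cross3_rows <- function(A, B) {
  cbind(A[, 2] * B[, 3] - A[, 3] * B[, 2],
        A[, 3] * B[, 1] - A[, 1] * B[, 3],
        A[, 1] * B[, 2] - A[, 2] * B[, 1])
}

# Axis-angle magnitude (degrees) between paired rows of two quaternion traces.
quat_angle_rows <- function(Q1, Q2) {
  dots <- abs(rowSums(Q1 * Q2))
  2 * acos(pmin(1, dots)) * 180 / pi
}
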