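# Unit-quaternion utilities (scalar-first convention) for water
# orientations.  The reference orientation places the oxygen at the origin,
# the H-O-H bisector along +z and the molecular plane in xz, so every water
# orientation is the rotation carrying that reference into the observed
# geometry.

.quat_normalize <- function(q) q / sqrt(sum(q^2))

# Hamilton product a x b, scalar-first
.quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

# rotation matrix (columns = images of the axes) from unit quaternion
.quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3)
}

# robust rotation-matrix -> quaternion (Shepperd's method)
.matrix_to_quat <- function(R) {
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
  .quat_normalize(q)
}

#' Orientational distance between two rotations
#'
#' The rotation-group metric `2 * acos(|q1 . q2|)` in radians: twice the
#' geodesic distance on the unit quaternion sphere, invariant under the
#' quaternion double cover (`q` and `-q` are the same rotation).  With
#' `water_symmetry = TRUE` the minimum over the H1/H2 exchange image of
#' `q2` (a 180-degree rotation about the molecular bisector) is returned.
#'
#' @param q1,q2 unit quaternions, scalar-first
#' @param water_symmetry fold the two-fold water symmetry into the metric
#' @return distance in radians, in `[0, pi]`
#' @export
orientational_distance <- function(q1, q2, water_symmetry = FALSE) {
  d <- 2 * acos(pmin(1, abs(sum(q1 * q2))))
  if (water_symmetry) {
    q2s <- .quat_multiply(q2, c(0, 0, 0, 1))  # pi about the bisector (z)
    d <- min(d, 2 * acos(pmin(1, abs(sum(q1 * q2s)))))
  }
  d
}

#' Minimum-image translational distance
#'
#' @param p1,p2 coordinate triples (A)
#' @param box orthorhombic box lengths (A)
#' @return Euclidean norm of the minimum-image displacement (A)
#' @export
translational_distance <- function(p1, p2, box) {
  d <- p2 - p1
  d <- d - box * round(d / box)
  sqrt(sum(d^2))
}

#' Uniform random unit quaternions
#'
#' Shoemake's subgroup algorithm, giving the uniform (Haar) distribution on
#' the rotation group.
#'
#' @param n number of quaternions
#' @return n x 4 matrix, scalar-first rows
#' @export
random_quaternions <- function(n) {
  u1 <- runif(n); u2 <- runif(n); u3 <- runif(n)
  cbind(sqrt(u1) * cos(2 * pi * u3),
        sqrt(1 - u1) * sin(2 * pi * u2),
        sqrt(1 - u1) * cos(2 * pi * u2),
        sqrt(u1) * sin(2 * pi * u3))
}

#' Orientation quaternion of a water molecule
#'
#' Returns the rotation carrying the reference water orientation (O at the
#' origin, H-O-H bisector along +z, molecular plane xz with H1 at +x) into
#' the observed geometry.
#'
#' @param o,h1,h2 coordinate triples of the oxygen and the two hydrogens
#' @return unit quaternion, scalar-first
#' @export
water_orientation <- function(o, h1, h2) {
  u1 <- (h1 - o) / sqrt(sum((h1 - o)^2))
  u2 <- (h2 - o) / sqrt(sum((h2 - o)^2))
  z <- u1 + u2; z <- z / sqrt(sum(z^2))
  x <- u1 - u2; x <- x / sqrt(sum(x^2))
  y <- c(z[2] * x[3] - z[3] * x[2],
         z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  .matrix_to_quat(cbind(x, y, z))
}
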