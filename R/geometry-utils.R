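## Small internal 3-D geometry helpers.  All take/return plain numeric
## vectors (length 3) or n x 3 matrices; no unit conversion happens here.

.unitv <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a near-zero vector")
  v / n
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## atan2-based angle: accurate near 0 and 180 where acos loses precision
.angle_deg <- function(a, b) {
  a <- .unitv(a); b <- .unitv(b)
  atan2(sqrt(sum(.cross3(a, b)^2)), sum(a * b)) * 180 / pi
}

## Rodrigues rotation matrix: rotate by angle_rad about unit axis
.rotation_matrix <- function(axis, angle_rad) {
  u <- .unitv(axis)
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle_rad) * K + (1 - cos(angle_rad)) * (K %*% K)
}

## Total-least-squares direction of a point cloud (first principal axis).
## Returns a unit vector; errors out if the cloud is degenerate (all points
## coincident within tol).
.tls_direction <- function(points, tol = 1e-9) {
  ctr <- colMeans(points)
  X <- sweep(points, 2, ctr)
  s <- svd(X)
  if (s$d[1] < tol) stop("degenerate point set: all points coincident")
  s$v[, 1]
}

## Plane through three points: returns list(normal = unit normal, point = p1).
.plane_through3 <- function(p1, p2, p3, tol = 1e-9) {
  n <- .cross3(p2 - p1, p3 - p1)
  nn <- sqrt(sum(n^2))
  if (nn < tol) stop("degenerate plane: points are collinear")
  list(normal = n / nn, point = p1)
}

.point_plane_distance <- function(p, plane) {
  abs(sum((p - plane$point) * plane$normal))
}

## Least-squares intersection point of a set of 3-D lines given by
## origins (n x 3) and unit directions (n x 3): solves
## sum_i (I - d_i d_i^T) x = sum_i (I - d_i d_i^T) o_i.
.ls_line_intersection <- function(origins, dirs) {
  A <- matrix(0, 3, 3)
  b <- numeric(3)
  for (i in seq_len(nrow(origins))) {
    d <- .unitv(dirs[i, ])
    P <- diag(3) - tcrossprod(d)
    A <- A + P
    b <- b + P %*% origins[i, ]
  }
  as.numeric(solve(A, b))
}
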