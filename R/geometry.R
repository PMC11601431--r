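# Small geometry helpers shared by the structure, feature and fixture code.

#' Pairwise Euclidean distances between two coordinate sets
#'
#' @param a,b numeric matrices with 3 columns (x, y, z), rows are points.
#' @return numeric matrix of dimension `nrow(a)` x `nrow(b)`.
#' @keywords internal
dist_mat <- function(a, b) {
  a <- matrix(as.numeric(a), ncol = 3L)
  b <- matrix(as.numeric(b), ncol = 3L)
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' Distances from one point to a coordinate set
#' @keywords internal
dist_to <- function(point, coords) {
  coords <- matrix(as.numeric(coords), ncol = 3L)
  sqrt(colSums((t(coords) - as.numeric(point))^2))
}

#' Dihedral angle defined by four points, in degrees in (-180, 180]
#' @keywords internal
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  b2n <- b2 / sqrt(sum(b2^2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2) / sqrt(sum(b2^2))
  atan2(y, x) * 180 / pi
}

#' Place a fourth atom from three reference atoms (natural extension)
#'
#' Given positions a, b, c, returns the position d such that the bond c-d has
#' length `bond`, the angle b-c-d equals `angle` (degrees) and the dihedral
#' a-b-c-d equals `torsion` (degrees).
#' @keywords internal
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- -torsion * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Deterministic, roughly uniform points on the unit sphere (golden spiral)
#' @keywords internal
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Rotation matrix mapping the +x axis onto a unit vector
#' @keywords internal
rotation_to <- function(u) {
  u <- u / sqrt(sum(u^2))
  # pick a helper axis not parallel to u
  h <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  w <- c(u[2] * h[3] - u[3] * h[2],
         u[3] * h[1] - u[1] * h[3],
         u[1] * h[2] - u[2] * h[1])
  w <- w / sqrt(sum(w^2))
  v <- c(w[2] * u[3] - w[3] * u[2],
         w[3] * u[1] - w[1] * u[3],
         w[1] * u[2] - w[2] * u[1])
  cbind(u, v, w)
}

#' Apply a rigid motion to an n x 3 coordinate matrix
#'
#' Utility used throughout the test-suite to assert rigid-motion invariance
#' of features. Rotation is about the origin, then translation.
#'
#' @param coords n x 3 matrix.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 vector.
#' @return transformed n x 3 matrix.
#' @export
rigid_transform <- function(coords, rotation = diag(3), translation = c(0, 0, 0)) {
  coords <- matrix(as.numeric(coords), ncol = 3L)
  sweep(coords %*% t(rotation), 2, translation, "+")
}

#' Rotation matrix about a coordinate axis
#' @param axis one of "x", "y", "z".
#' @param angle angle in degrees.
#' @export
rotation_matrix <- function(axis = c("x", "y", "z"), angle) {
  axis <- match.arg(axis)
  a <- angle * pi / 180
  ca <- cos(a); sa <- sin(a)
  switch(axis,
    x = matrix(c(1, 0, 0, 0, ca, -sa, 0, sa, ca), 3, 3, byrow = TRUE),
    y = matrix(c(ca, 0, sa, 0, 1, 0, -sa, 0, ca), 3, 3, byrow = TRUE),
    z = matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, 3, byrow = TRUE))
}
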