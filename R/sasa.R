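# Shrake-Rupley solvent-accessible surface area.
#
# No SASA implementation ships with the installed R stack, so the classic
# algorithm is implemented here: each atom is inflated by the probe radius
# and sampled with a deterministic golden-spiral quadrature; a sample point
# is accessible when it lies outside every neighbouring inflated sphere.

# Fixed van der Waals radii (Angstrom), heavy atoms.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)
VDW_DEFAULT <- 1.80

# rotation-equivariant orthonormal frame of a coordinate set: principal
# axes ordered by decreasing variance, each axis' sign chosen so the
# third central moment along it is non-negative
intrinsic_frame <- function(xyz) {
  if (nrow(xyz) < 3L) return(diag(3))
  ctr <- sweep(xyz, 2, colMeans(xyz))
  ev <- eigen(crossprod(ctr) / nrow(ctr), symmetric = TRUE)
  E <- ev$vectors
  for (k in 1:3) {
    m3 <- sum((ctr %*% E[, k])^3)
    if (m3 < 0) E[, k] <- -E[, k]
  }
  E
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' @param structure a `prot_structure`; all protein heavy atoms in all
#'   chains form the occluding environment.
#' @param probe_radius solvent probe radius in Angstrom (water: 1.4).
#' @param n_sphere_points number of quadrature points per atom; accuracy is
#'   roughly O(1/n).
#' @return numeric vector of per-atom accessible areas in Angstrom^2,
#'   aligned with `structure$atoms` rows, with attribute `res_key`.
#'   Unknown elements fall back to a generic 1.8 A radius with a warning.
#' @export
shrake_rupley_sasa <- function(structure, probe_radius = 1.4,
                               n_sphere_points = 960L) {
  at <- structure$atoms
  xyz <- as.matrix(at[, c("x", "y", "z")])
  n <- nrow(xyz)
  radii <- unname(VDW_RADII[at$element])
  unknown <- is.na(radii)
  if (any(unknown)) {
    warning(sprintf("unknown element(s) %s: using generic %.1f A radius",
                    paste(unique(at$element[unknown]), collapse = ", "),
                    VDW_DEFAULT))
    radii[unknown] <- VDW_DEFAULT
  }
  # orient the quadrature in a structure-intrinsic frame (principal axes,
  # signs fixed by the third central moments) so the computed areas are
  # invariant under rigid motion of the input to machine precision
  pts <- sphere_points(n_sphere_points) %*% t(intrinsic_frame(xyz))
  ext <- radii + probe_radius
  # neighbour candidates: spheres can only intersect within r_i + r_j + 2p
  dm2 <- dist_mat(xyz, xyz)^2
  area <- numeric(n)
  for (i in seq_len(n)) {
    cutoff <- ext[i] + radii + probe_radius
    nb <- which(dm2[i, ] < cutoff^2 & seq_len(n) != i)
    full <- 4 * pi * ext[i]^2
    if (length(nb) == 0L) {
      area[i] <- full
      next
    }
    # a quadrature point q (unit sphere) lies inside neighbour j iff
    # |a_i + R q - c_j|^2 < ext_j^2, i.e. q . (c_j - a_i) > t_j
    diffs <- xyz[nb, , drop = FALSE] -
      matrix(xyz[i, ], length(nb), 3L, byrow = TRUE)
    tj <- (dm2[i, nb] + ext[i]^2 - ext[nb]^2) / (2 * ext[i])
    proj <- tcrossprod(pts, diffs)
    acc <- sum(rowSums(proj > matrix(tj, n_sphere_points, length(nb),
                                     byrow = TRUE)) == 0L)
    area[i] <- full * acc / n_sphere_points
  }
  attr(area, "res_key") <- at$res_key
  area
}

#' Per-residue sidechain SASA
#'
#' Sums the per-atom areas of each residue's sidechain atoms (everything
#' except N, CA, C, O, OXT; for Gly the result is 0).
#'
#' @param structure a `prot_structure`.
#' @param sasa_map output of [shrake_rupley_sasa()] for the same structure.
#' @return named numeric vector keyed by `res_key`.
#' @export
sidechain_sasa <- function(structure, sasa_map) {
  at <- structure$atoms
  side <- !(at$name %in% c("N", "CA", "C", "O", "OXT"))
  keys <- unique(at$res_key)
  out <- vapply(keys, function(k) {
    sum(sasa_map[side & at$res_key == k])
  }, numeric(1))
  names(out) <- keys
  out
}
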