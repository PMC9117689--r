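# Internal geometric primitives shared by featurization, trajectory
# superposition and band alignment.

vec_norm <- function(v) sqrt(sum(v^2))

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Torsion angle of four points
#'
#' Signed dihedral angle (IUPAC convention, computed with the standard
#' atan2 construction) of four positions, reported in degrees and wrapped
#' into `[0, 360)`. Receptor helix-8 dihedrals routinely exceed 180
#' degrees, so the wrapped scale is used throughout rather than the
#' signed `(-180, 180]` one.
#'
#' @param p1,p2,p3,p4 Numeric length-3 position vectors (angstrom).
#' @return Angle in degrees in `[0, 360)`.
#' @export
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (vec_norm(n1) < 1e-10 || vec_norm(n2) < 1e-10) {
    abort("undefined dihedral: three of the four points are collinear",
          class = "conformscape_collinear_error")
  }
  m1 <- cross3(n1, b2 / vec_norm(b2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  ang %% 360
}

# Optimal proper rotation W (Kabsch, via SVD) such that P %*% W best
# matches Q in least squares; both inputs must already be centred.
kabsch_rotation <- function(P, Q) {
  H <- crossprod(P, Q)
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

# Superpose coordinate matrix P (n x 3) onto reference Q (n x 3):
# translate both centroids to origin, rotate P, then restore Q's centroid.
superpose_onto <- function(P, Q) {
  cp <- colMeans(P)
  cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp)
  Qc <- sweep(Q, 2, cq)
  W <- kabsch_rotation(Pc, Qc)
  sweep(Pc %*% W, 2, cq, `+`)
}

rmsd_xyz <- function(P, Q) sqrt(mean(rowSums((P - Q)^2)))
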