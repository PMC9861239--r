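#' @title Geometric kernels
#' @description
#' Angles, torsions, Kabsch least-squares superposition, RMSD, RMSF and the
#' radius of gyration — the primitives every trajectory descriptor and every
#' superposition-based analysis in the package is built on. All distances are
#' in angstrom and all angles in degrees.
#' @name geometry
NULL

# Vectorised row-wise helpers: arguments are n x 3 matrices.
rowdot <- function(a, b) rowSums(a * b)
rowcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}
as_row3 <- function(p) if (is.matrix(p)) p else matrix(p, ncol = 3)

#' Angle at a vertex
#'
#' @param p1,p2,p3 3-vectors (or n x 3 matrices for a vectorised call);
#'   `p2` is the vertex.
#' @return angle(s) in degrees, in `[0, 180]`
#' @export
vec_angle <- function(p1, p2, p3) {
  p1 <- as_row3(p1); p2 <- as_row3(p2); p3 <- as_row3(p3)
  a <- p1 - p2
  b <- p3 - p2
  na <- sqrt(rowdot(a, a)); nb <- sqrt(rowdot(b, b))
  if (any(na < 1e-9) || any(nb < 1e-9))
    stop_mnt("coincident points: angle undefined", "mnt_degenerate_error")
  cosv <- pmin(1, pmax(-1, rowdot(a, b) / (na * nb)))
  deg(acos(cosv))
}

#' Signed torsion (dihedral) angle
#'
#' IUPAC sign convention: looking down the `p2 -> p3` axis, a clockwise
#' rotation of the far bond relative to the near bond is positive. The value
#' is in `(-180, 180]`; it is unchanged by reversing the four points and flips
#' sign under mirror reflection.
#'
#' @param p1,p2,p3,p4 3-vectors (or n x 3 matrices for a vectorised call)
#' @return torsion(s) in degrees
#' @export
vec_dihedral <- function(p1, p2, p3, p4) {
  p1 <- as_row3(p1); p2 <- as_row3(p2); p3 <- as_row3(p3); p4 <- as_row3(p4)
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- rowcross(b1, b2)
  n2 <- rowcross(b2, b3)
  if (any(rowdot(n1, n1) < 1e-12) || any(rowdot(n2, n2) < 1e-12))
    stop_mnt("collinear bonded triple: torsion undefined", "mnt_degenerate_error")
  b2n <- b2 / sqrt(rowdot(b2, b2))
  x <- rowdot(n1, n2)
  y <- rowdot(rowcross(n1, n2), b2n)
  wrap180(deg(atan2(y, x)))
}

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimising the RMSD of `mobile`
#' onto `reference`; the reflection branch of the SVD solution is excluded by
#' the standard determinant sign correction.
#'
#' @param mobile,reference N x 3 coordinate matrices with matching rows
#' @return list with `rotation` (3 x 3, det +1), `translation` (length-3),
#'   `rmsd` (angstrom) and `fitted` (the transformed mobile coordinates); the
#'   transform maps a mobile point `p` to `p %*% rotation + translation`.
#' @export
kabsch <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3)
    stop_mnt("coordinate sets must be N x 3 with equal N", "mnt_shape_error")
  n <- nrow(mobile)
  if (n < 3) stop_mnt("need at least 3 points for superposition", "mnt_degenerate_error")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm)
  B <- sweep(reference, 2, cr)
  sv <- svd(A, nu = 0, nv = 0)$d
  if (sv[2] < 1e-9)   # <= 1 non-zero singular value: coincident or collinear
    stop_mnt("degenerate (collinear or coincident) point set", "mnt_degenerate_error")
  H <- crossprod(A, B)                      # 3 x 3 cross-covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)                 # maps row-vectors: p %*% R
  fitted <- A %*% R
  rmsd <- sqrt(sum((fitted - B)^2) / n)
  list(rotation = R, translation = cr - as.vector(cm %*% R),
       rmsd = rmsd, fitted = sweep(fitted, 2, cr, `+`))
}

#' Minimised RMSD between two coordinate sets
#' @inheritParams kabsch
#' @return RMSD in angstrom after optimal superposition
#' @export
rmsd_fit <- function(mobile, reference) kabsch(mobile, reference)$rmsd

#' Root-mean-square fluctuation per atom
#'
#' Frames are first superposed onto the iteratively refined mean structure
#' (see [merge_and_superpose()]); the fluctuation of each atom is the RMS of
#' its displacement from its time-averaged position.
#'
#' @param traj a [trajectory] with at least two frames
#' @param sel optional [selection()] applied first
#' @return numeric vector, one value (angstrom) per selected atom
#' @export
rmsf <- function(traj, sel = NULL) {
  if (!is.null(sel)) traj <- apply_selection(traj, sel)
  if (n_frames(traj) < 2)
    stop_mnt("RMSF needs at least two frames", "mnt_insufficient_data")
  X <- superpose_to_mean(traj$xyz)
  mu <- colMeans(X)
  D <- sweep(X, 2, mu)
  sq <- D^2
  per_atom <- matrix(colMeans(sq), ncol = 3, byrow = TRUE)
  sqrt(rowSums(per_atom))
}

#' Radius of gyration of one conformer
#'
#' Unweighted (all atoms equal mass): the RMS distance of the atoms from
#' their centroid.
#'
#' @param coords N x 3 coordinate matrix
#' @return radius of gyration in angstrom
#' @export
radius_of_gyration <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 1) stop_mnt("empty coordinate set", "mnt_selection_error")
  d <- sweep(coords, 2, colMeans(coords))
  sqrt(mean(rowSums(d^2)))
}
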