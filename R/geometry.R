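# Low-level vector geometry shared by the helix builder, the distance-geometry
# engine and the validation metrics.  All lengths in Angstrom, angles in degrees
# at the interface (radians internally).

unit_vec <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("zero-length vector has no direction")
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Bond angle at `b` formed by points `a-b-c`, in degrees
#' @noRd
bond_angle <- function(a, b, c) {
  v1 <- unit_vec(a - b)
  v2 <- unit_vec(c - b)
  acos(max(-1, min(1, sum(v1 * v2)))) * 180 / pi
}

#' Signed torsion angle a-b-c-d in degrees, IUPAC sign convention
#' @noRd
torsion_angle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit_vec(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Place a new atom from internal coordinates (NeRF construction).
#'
#' The new point D is bonded to `c` with bond length `bond`, forms angle
#' `angle` (degrees) with `b-c`, and torsion `tor` (degrees) about `b-c`
#' measured from `a`.
#' @noRd
place_atom <- function(a, b, c, bond, angle, tor) {
  th <- angle * pi / 180
  ph <- tor * pi / 180
  bc <- unit_vec(c - b)
  n <- unit_vec(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- bond * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  c + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

#' Optimal superposition (Kabsch) of coordinate sets
#'
#' Least-squares superposes `mobile` onto `fixed` (both n x 3 matrices, same
#' row order) allowing rotation and translation but not reflection, and
#' returns the transformed mobile coordinates with the RMSD as attribute
#' `"rmsd"`.
#'
#' @param mobile,fixed numeric matrices with one row per atom and columns
#'   x, y, z.
#' @return transformed `mobile` matrix with attribute `rmsd`.
#' @export
superpose <- function(mobile, fixed) {
  stopifnot(is.matrix(mobile), is.matrix(fixed),
            nrow(mobile) == nrow(fixed), ncol(mobile) == 3L, ncol(fixed) == 3L)
  cm <- colMeans(mobile)
  cf <- colMeans(fixed)
  P <- sweep(mobile, 2L, cm)
  Q <- sweep(fixed, 2L, cf)
  s <- svd(crossprod(P, Q))
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  out <- t(R %*% t(P)) + matrix(cf, nrow(P), 3L, byrow = TRUE)
  dimnames(out) <- dimnames(mobile)
  attr(out, "rmsd") <- sqrt(mean(rowSums((out - fixed)^2)))
  out
}

# rotation/centres of the optimal (reflection-free) superposition of
# `mobile` onto `fixed`
.kabsch_transform <- function(mobile, fixed) {
  cm <- colMeans(mobile)
  cf <- colMeans(fixed)
  P <- sweep(mobile, 2L, cm)
  Q <- sweep(fixed, 2L, cf)
  s <- svd(crossprod(P, Q))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(rotation = R, center_m = cm, center_f = cf)
}

#' RMSD after optimal superposition
#' @param a,b coordinate matrices (n x 3, same atom order).
#' @return root-mean-square deviation in Angstrom.
#' @export
rmsd_fit <- function(a, b) {
  attr(superpose(a, b), "rmsd")
}

#' Signed chiral volume of an L-alpha carbon centre
#'
#' Scalar triple product of the CA->N, CA->C and CA->CB vectors divided by 6.
#' Positive for L-amino acids in the convention used throughout the package.
#' @noRd
chiral_volume <- function(n, ca, c, cb) {
  v1 <- c - ca
  v2 <- n - ca
  v3 <- cb - ca
  sum(cross3(v1, v2) * v3) / 6
}
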