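# Small shared numeric helpers. Coordinates are always Angstrom, angles degrees.

DEG <- 180 / pi

#' @keywords internal
vnorm <- function(v) sqrt(sum(v * v))

#' Angle between two 3-vectors in degrees
#' @keywords internal
vec_angle <- function(a, b) {
  na <- vnorm(a); nb <- vnorm(b)
  if (na == 0 || nb == 0) stop("cannot take the angle of a zero vector")
  ct <- sum(a * b) / (na * nb)
  acos(max(-1, min(1, ct))) * DEG
}

#' Minimum-image displacement under an orthorhombic cell
#'
#' @param d displacement matrix (n x 3) or 3-vector
#' @param box cell lengths, length-3
#' @keywords internal
min_image <- function(d, box) {
  if (is.null(dim(d))) d <- matrix(d, ncol = 3)
  if (any(!is.finite(box)) || any(box <= 0)) return(d)
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  d
}

#' Mass-weighted centre of mass of a coordinate block
#' @keywords internal
com <- function(xyz, mass) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
  w <- mass / sum(mass)
  colSums(xyz * w)
}

#' All minimum-image pair distances between two coordinate blocks
#'
#' Returns an nA x nB matrix. O(nA*nB) memory; intended for the fixture-scale
#' selections this package analyses (probe atoms, residue groups, solvent shells).
#' @keywords internal
pair_dist <- function(A, B, box = NULL) {
  nA <- nrow(A); nB <- nrow(B)
  D <- matrix(0, nA, nB)
  for (k in 1:3) {
    d <- outer(A[, k], B[, k], "-")
    if (!is.null(box) && is.finite(box[k]) && box[k] > 0)
      d <- d - box[k] * round(d / box[k])
    D <- D + d * d
  }
  sqrt(D)
}

#' Coordinates of a subset of atoms in one frame, always as an n x 3 matrix
#' @keywords internal
frame_coords <- function(traj, idx, f) matrix(traj$coords[idx, , f], ncol = 3)

`%||%` <- function(a, b) if (is.null(a)) b else a
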