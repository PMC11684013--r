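# Residue-anchored geometry: axis vectors from anchor centres of mass, tilt
# and crossing angles of the transmembrane helices, receptor-head bending
# angles against the unit-cell vertical, inter-atom and centre-of-mass
# distance series, and percent-frequency angle histograms.

.anchor_com <- function(traj, f, idx) {
  com(frame_coords(traj, idx, f), traj$top$mass[idx])
}

#' Axis vector between two anchor centres of mass
#'
#' @param frame Frame; @param top Topology; @param idxA,idxB atom index sets
#' @return unit 3-vector from COM(A) to COM(B)
#' @export
axis_vector <- function(frame, top, idxA, idxB) {
  if (!length(idxA) || !length(idxB)) stop("anchor resolves to no atoms")
  a <- com(frame$coords[idxA, , drop = FALSE], top$mass[idxA])
  b <- com(frame$coords[idxB, , drop = FALSE], top$mass[idxB])
  v <- b - a
  nv <- vnorm(v)
  if (nv < 1e-9) stop("anchors are coincident; axis undefined")
  v / nv
}

#' Per-frame axis vectors over a trajectory
#'
#' @inheritParams axis_vector
#' @param traj Trajectory
#' @return n_frames x 3 matrix of unit vectors
#' @export
axis_vector_series <- function(traj, idxA, idxB) {
  nf <- n_frames(traj)
  V <- matrix(0, nf, 3)
  for (f in seq_len(nf))
    V[f, ] <- axis_vector(get_frame(traj, f), traj$top, idxA, idxB)
  V
}

#' Angles between a series of vectors and the unit-cell z axis
#'
#' `fold = TRUE` (tilt convention) maps angles above 90 degrees to
#' 180 - theta, so the value is direction-independent: psi(v) = psi(-v).
#'
#' @param V n x 3 matrix of (non-zero) vectors
#' @param fold fold to `[0, 90]`?
#' @return numeric vector of angles in degrees
#' @export
angle_to_cell <- function(V, fold = FALSE) {
  if (is.null(dim(V))) V <- matrix(V, ncol = 3)
  ang <- apply(V, 1, function(v) vec_angle(v, c(0, 0, 1)))
  if (fold) ang <- ifelse(ang > 90, 180 - ang, ang)
  ang
}

#' Transmembrane tilt-angle series (psi)
#'
#' Angle between the anchor axis (by default the Val73 -> Val92 direction of
#' the NKG2A helix) and the unit-cell vertical, folded to `[0, 90]`.
#'
#' @param traj Trajectory; @param idxA,idxB bottom/top anchor atom sets
#' @return per-frame tilt in degrees
#' @export
tilt_angle_series <- function(traj, idxA, idxB) {
  angle_to_cell(axis_vector_series(traj, idxA, idxB), fold = TRUE)
}

#' Helix crossing-angle series (phi)
#'
#' Angle between the two helix axis vectors, each spanning the bottom -> top
#' anchors of its helix; reported unfolded on `[0, 180]` so parallel and
#' antiparallel packing remain distinguishable.
#'
#' @param traj Trajectory
#' @param h1_bottom,h1_top,h2_bottom,h2_top anchor atom index sets
#' @return per-frame crossing angle in degrees
#' @export
crossing_angle_series <- function(traj, h1_bottom, h1_top, h2_bottom, h2_top) {
  V1 <- axis_vector_series(traj, h1_bottom, h1_top)
  V2 <- axis_vector_series(traj, h2_bottom, h2_top)
  vapply(seq_len(nrow(V1)), function(f) vec_angle(V1[f, ], V2[f, ]), 1.0)
}

#' Receptor-head bending angles (alpha_V, alpha_H) and 2D occupancy
#'
#' The vertical bending angle alpha_V tracks the Cys58 -> Ser110 COM vector
#' and the horizontal angle alpha_H the His184 -> Thr126 COM vector, both
#' against the unit-cell vertical. Also returns the joint (alpha_V, alpha_H)
#' occupancy grid as percent of snapshots.
#'
#' @param traj Trajectory
#' @param vertA,vertB,horizA,horizB anchor atom index sets
#' @param bin histogram box size in degrees (default 3)
#' @return list `alpha_v`, `alpha_h` (degree series), `grid` (matrix of % with
#'   bin-left edges as dimnames)
#' @export
bending_angles <- function(traj, vertA, vertB, horizA, horizB, bin = 3) {
  av <- angle_to_cell(axis_vector_series(traj, vertA, vertB))
  ah <- angle_to_cell(axis_vector_series(traj, horizA, horizB))
  edges <- seq(0, 180 + bin, by = bin)
  cv <- cut(av, edges, right = FALSE, labels = FALSE)
  ch <- cut(ah, edges, right = FALSE, labels = FALSE)
  nb <- length(edges) - 1
  grid <- matrix(0, nb, nb, dimnames = list(edges[-length(edges)],
                                            edges[-length(edges)]))
  for (f in seq_along(av)) grid[cv[f], ch[f]] <- grid[cv[f], ch[f]] + 1
  grid <- grid / length(av) * 100
  list(alpha_v = av, alpha_h = ah, grid = grid)
}

#' Inter-atom distance series
#'
#' Per-frame Euclidean distance between two atoms; with `minimum_image` the
#' distance is taken under the orthorhombic cell (for inter-molecular pairs).
#'
#' @param traj Trajectory; @param i,j atom indices; @param minimum_image logical
#' @return per-frame distance (A)
#' @export
atom_distance_series <- function(traj, i, j, minimum_image = TRUE) {
  stopifnot(length(i) == 1, length(j) == 1)
  if (i > n_atoms(traj) || j > n_atoms(traj)) stop("atom index out of range")
  nf <- n_frames(traj)
  vapply(seq_len(nf), function(f) {
    d <- traj$coords[j, , f] - traj$coords[i, , f]
    if (minimum_image) d <- as.vector(min_image(d, traj$box[f, ]))
    vnorm(d)
  }, 1.0)
}

#' Centre-of-mass distance series between two atom groups
#'
#' Mass-weighted centroids per frame (e.g. NKG2A residues 1-45 vs the TMD).
#'
#' @param traj Trajectory; @param idxA,idxB atom index sets
#' @return per-frame COM distance (A)
#' @export
com_distance_series <- function(traj, idxA, idxB) {
  if (!length(idxA) || !length(idxB)) stop("empty group")
  nf <- n_frames(traj)
  vapply(seq_len(nf), function(f)
    vnorm(.anchor_com(traj, f, idxB) - .anchor_com(traj, f, idxA)), 1.0)
}

#' Percent-frequency angle histogram
#'
#' Left-closed right-open bins anchored at 0 degrees; frequencies are percent
#' of all snapshots and sum to exactly 100.
#'
#' @param series angle series (degrees); @param bin bin width in degrees
#'   (1 for the TM angle distributions, 3 for the bending angles)
#' @return data.frame `bin_left_deg`, `pct`, class `AngleHistogram`
#' @export
angle_histogram <- function(series, bin = 1) {
  if (!length(series)) stop("empty angle series")
  if (bin <= 0) stop("bin width must be positive")
  edges <- seq(0, 180 + bin, by = bin)
  idx <- cut(series, edges, right = FALSE, labels = FALSE)
  counts <- tabulate(idx, nbins = length(edges) - 1)
  out <- data.frame(bin_left_deg = edges[-length(edges)],
                    pct = counts / length(series) * 100)
  class(out) <- c("AngleHistogram", "data.frame")
  attr(out, "bin") <- bin
  out
}
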