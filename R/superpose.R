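# Rigid-body superposition (Kabsch), iterative average structures, and frame
# windowing (equilibration skip / stride / alignment).

#' Least-squares rigid-body fit of one frame onto another
#'
#' Kabsch algorithm via SVD: finds the proper rotation + translation
#' minimising the RMSD between `mobile` and `reference` over `selection`,
#' then applies it to all atoms of `mobile`.
#'
#' @param mobile,reference Frame objects (or bare n x 3 coordinate matrices)
#' @param selection integer atom indices used for the fit (default: all)
#' @param weights optional per-selected-atom fit weights (e.g. masses)
#' @return list with `frame` (fitted Frame / matrix), `rmsd` (post-fit, over
#'   the selection), `R` (3 x 3 rotation) and `t` (translation)
#' @export
superpose <- function(mobile, reference, selection = NULL, weights = NULL) {
  mx <- if (inherits(mobile, "Frame")) mobile$coords else mobile
  rx <- if (inherits(reference, "Frame")) reference$coords else reference
  if (is.null(selection)) selection <- seq_len(nrow(mx))
  if (!length(selection)) stop("empty fit selection")
  if (max(selection) > nrow(mx) || max(selection) > nrow(rx))
    stop("fit selection exceeds atom count")
  A <- mx[selection, , drop = FALSE]
  B <- rx[selection, , drop = FALSE]
  if (nrow(A) != nrow(B)) stop("selection sizes differ between frames")
  w <- if (is.null(weights)) rep(1, nrow(A)) else weights
  w <- w / sum(w)
  ca <- colSums(A * w); cb <- colSums(B * w)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  H <- t(A0 * w) %*% B0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fit_all <- sweep(mx, 2, ca) %*% t(R)
  fit_all <- sweep(fit_all, 2, cb, "+")
  dd <- fit_all[selection, , drop = FALSE] - B
  rmsd <- sqrt(sum(w * rowSums(dd * dd)))
  out <- fit_all
  if (inherits(mobile, "Frame")) {
    out <- mobile
    out$coords <- fit_all
  }
  list(frame = out, rmsd = rmsd, R = R, t = cb - ca %*% t(R))
}

#' Superpose every frame of a trajectory onto a reference
#'
#' @param traj Trajectory; @param reference Frame or n x 3 matrix
#' @param selection fit selection (default all atoms)
#' @return list `traj` (fitted Trajectory), `rmsd` (per-frame, post-fit)
#' @export
fit_trajectory <- function(traj, reference, selection = NULL) {
  rx <- if (inherits(reference, "Frame")) reference$coords else reference
  nf <- n_frames(traj)
  rmsd <- numeric(nf)
  out <- traj
  for (f in seq_len(nf)) {
    s <- superpose(traj$coords[, , f, drop = TRUE], rx, selection)
    out$coords[, , f] <- s$frame
    rmsd[f] <- s$rmsd
  }
  list(traj = out, rmsd = rmsd)
}

#' Iteratively averaged structure over a trajectory window
#'
#' Frames are superposed onto the running mean and re-averaged until the mean
#' moves by less than `tol` (max per-coordinate change, Angstrom).
#'
#' @param traj Trajectory; @param selection fit selection
#' @param tol convergence tolerance (default 1e-6 A); @param max_iter cap
#' @return a Frame holding the converged mean coordinates
#' @export
average_structure <- function(traj, selection = NULL, tol = 1e-6,
                              max_iter = 50) {
  nf <- n_frames(traj)
  if (nf < 1) stop("cannot average an empty trajectory")
  mean_xyz <- traj$coords[, , 1, drop = TRUE]
  for (it in seq_len(max_iter)) {
    acc <- matrix(0, n_atoms(traj), 3)
    for (f in seq_len(nf))
      acc <- acc + superpose(traj$coords[, , f, drop = TRUE], mean_xyz,
                             selection)$frame
    new_mean <- acc / nf
    delta <- max(abs(new_mean - mean_xyz))
    mean_xyz <- new_mean
    if (delta < tol) break
  }
  structure(list(coords = mean_xyz, box = traj$box[1, ], time = NA_real_),
            class = "Frame")
}

#' Frame-window specification
#'
#' @param offset_ns drop frames with `time < offset_ns` (equilibration skip)
#' @param stride keep every `stride`-th remaining frame
#' @param align `"none"`, `"start"` (first kept frame), `"average"`
#'   (iteratively averaged structure), or a Frame to align onto
#' @param selection alignment selection (default: all atoms; receptor
#'   C-alphas in the pipeline)
#' @export
frame_window <- function(offset_ns = 0, stride = 1L, align = "none",
                         selection = NULL) {
  stopifnot(offset_ns >= 0, stride >= 1)
  structure(list(offset_ns = offset_ns, stride = as.integer(stride),
                 align = align, selection = selection), class = "FrameWindow")
}

#' Apply a FrameWindow to a trajectory
#'
#' Removes the equilibration span, applies the stride, then the requested
#' alignment. Errors if the window empties the trajectory.
#'
#' @param traj Trajectory; @param window FrameWindow
#' @return windowed (and optionally aligned) Trajectory
#' @export
apply_window <- function(traj, window) {
  keep <- which(traj$time >= window$offset_ns)
  if (!length(keep)) stop("window removes every frame")
  keep <- keep[seq(1, length(keep), by = window$stride)]
  out <- trajectory(traj$top, traj$coords[, , keep, drop = FALSE],
                    box = traj$box[keep, , drop = FALSE],
                    time = traj$time[keep])
  al <- window$align
  if (inherits(al, "Frame") || (is.character(al) && al != "none")) {
    ref <- if (inherits(al, "Frame")) al
           else if (al == "start") get_frame(out, 1)
           else if (al == "average") average_structure(out, window$selection)
           else stop("unknown alignment '", al, "'")
    out <- fit_trajectory(out, ref, window$selection)$traj
  }
  out
}
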