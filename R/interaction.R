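# Solvent exposure and interaction statistics: water RDFs around probe
# atoms, contact counting, contact/H-bond persistence tables, and a
# simplified three-state Kabsch-Sander secondary-structure assignment.

#' Radial distribution function of solvent around probe atoms
#'
#' `g(r) = <n(r)> / (rho * V_shell(r))`, averaged over frames and probe
#' atoms, with minimum-image distances and the solvent number density rho
#' taken from the instantaneous box volume each frame (NPT-safe). For a
#' uniform solvent g(r) tends to 1.
#'
#' @param traj Trajectory; @param probe,solvent atom index sets
#' @param bin radial bin width (A); @param r_max maximum radius (must not
#'   exceed half the smallest box length)
#' @return object of class `RDFCurve`: data.frame `r`, `g`, with attribute
#'   `coordination` (mean neighbour count within r_max per probe)
#' @export
rdf <- function(traj, probe, solvent, bin = 0.1, r_max = 10) {
  if (!length(solvent)) stop("empty solvent selection")
  if (!length(probe)) stop("empty probe selection")
  box_min <- min(traj$box, na.rm = TRUE)
  if (!is.finite(box_min)) stop("RDF needs a defined box")
  if (r_max > box_min / 2)
    stop("r_max (", r_max, " A) exceeds half the smallest box length (",
         round(box_min / 2, 2), " A)")
  edges <- seq(0, r_max, by = bin)
  if (edges[length(edges)] < r_max) edges <- c(edges, r_max)
  nb <- length(edges) - 1
  counts <- numeric(nb)
  nf <- n_frames(traj)
  rho_sum <- 0
  for (f in seq_len(nf)) {
    D <- pair_dist(frame_coords(traj, probe, f),
                   frame_coords(traj, solvent, f), traj$box[f, ])
    # a probe atom that is itself in the solvent set never pairs with itself
    if (length(common <- intersect(probe, solvent))) {
      for (a in common) D[match(a, probe), match(a, solvent)] <- Inf
    }
    idx <- cut(D[D < r_max], edges, right = FALSE, labels = FALSE)
    counts <- counts + tabulate(idx, nbins = nb)
    rho_sum <- rho_sum + length(solvent) / prod(traj$box[f, ])
  }
  rho <- rho_sum / nf
  vol <- 4 / 3 * pi * (edges[-1]^3 - edges[-length(edges)]^3)
  g <- counts / (nf * length(probe)) / (rho * vol)
  out <- data.frame(r = edges[-length(edges)] + bin / 2, g = g)
  class(out) <- c("RDFCurve", "data.frame")
  attr(out, "coordination") <- sum(counts) / (nf * length(probe))
  attr(out, "rho") <- rho
  out
}

#' Per-frame contact counts between two atom groups
#'
#' Counts atom pairs (a in A, b in B) within `cutoff` under minimum-image
#' distances. Pairs of identical atoms (overlapping groups) are excluded
#' with a warning.
#'
#' @param traj Trajectory; @param groupA,groupB atom index sets
#' @param cutoff contact distance (A, default 4)
#' @return integer vector, one count per frame
#' @export
contact_count_series <- function(traj, groupA, groupB, cutoff = 4) {
  if (!length(groupA) || !length(groupB)) stop("empty contact group")
  common <- intersect(groupA, groupB)
  if (length(common))
    warning(length(common), " atom(s) shared between groups; ",
            "self-pairs excluded")
  nf <- n_frames(traj)
  vapply(seq_len(nf), function(f) {
    D <- pair_dist(frame_coords(traj, groupA, f),
                   frame_coords(traj, groupB, f), traj$box[f, ])
    if (length(common))
      for (a in common) D[match(a, groupA), match(a, groupB)] <- Inf
    sum(D < cutoff)
  }, 1L)
}

#' Contact-persistence table over residue/atom pairs
#'
#' For each pair of selections, persistence is the percentage of frames in
#' which the minimum inter-group distance falls below `cutoff` (4 A in the
#' published protocol), alongside the mean of that minimum distance. By
#' convention the threshold applies to heavy atoms; pass `exclude_h = FALSE`
#' to keep hydrogens.
#'
#' @param traj Trajectory
#' @param pairs named list; each element `list(a = idx, b = idx)`
#' @param cutoff contact threshold (A); @param exclude_h drop hydrogens
#' @return data.frame `pair`, `mean_dist`, `persistence`, class
#'   `PersistenceTable`
#' @export
persistence <- function(traj, pairs, cutoff = 4, exclude_h = TRUE) {
  heavy <- which(traj$top$elem != "H")
  nf <- n_frames(traj)
  rows <- lapply(names(pairs), function(nm) {
    a <- pairs[[nm]]$a; b <- pairs[[nm]]$b
    if (exclude_h) { a <- intersect(a, heavy); b <- intersect(b, heavy) }
    if (!length(a) || !length(b)) stop("pair '", nm, "' resolves to no atoms")
    dmin <- vapply(seq_len(nf), function(f)
      min(pair_dist(frame_coords(traj, a, f),
                    frame_coords(traj, b, f), traj$box[f, ])), 1.0)
    data.frame(pair = nm, mean_dist = mean(dmin),
               persistence = 100 * mean(dmin < cutoff))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("PersistenceTable", "data.frame")
  out
}

#' Hydrogen-bond presence series and occupancy
#'
#' Geometric criterion: donor-acceptor heavy-atom distance at most
#' `dist_cutoff` (default 3.5 A) and donor-H...acceptor angle at least
#' `angle_cutoff` (default 120 degrees). When no hydrogen index is supplied
#' the angle gate is dropped with a warning (distance-only criterion).
#'
#' @param traj Trajectory; @param donor,acceptor single atom indices
#' @param hydrogen donor-bonded hydrogen index, or `NULL`
#' @param dist_cutoff,angle_cutoff geometric criteria
#' @return list `present` (logical per frame), `occupancy` (percent)
#' @export
hbond_series <- function(traj, donor, acceptor, hydrogen = NULL,
                         dist_cutoff = 3.5, angle_cutoff = 120) {
  nf <- n_frames(traj)
  d_da <- atom_distance_series(traj, donor, acceptor)
  ok <- d_da <= dist_cutoff
  if (is.null(hydrogen)) {
    warning("no donor hydrogen resolvable; using the distance-only criterion")
  } else {
    ang <- vapply(seq_len(nf), function(f) {
      h <- traj$coords[hydrogen, , f]
      v1 <- as.vector(min_image(traj$coords[donor, , f] - h, traj$box[f, ]))
      v2 <- as.vector(min_image(traj$coords[acceptor, , f] - h, traj$box[f, ]))
      vec_angle(v1, v2)
    }, 1.0)
    ok <- ok & ang >= angle_cutoff
  }
  list(present = ok, occupancy = 100 * mean(ok))
}

# ------------------------------------------------ secondary structure ------

# Kabsch-Sander electrostatic H-bond energy (kcal/mol) between the C=O of
# residue j and the N-H of residue i.
.ks_energy <- function(N, H, C, O) {
  q <- 0.084 * 332
  q * (1 / vnorm(O - N) + 1 / vnorm(C - H) - 1 / vnorm(O - H) - 1 / vnorm(C - N))
}

#' Simplified three-state secondary-structure assignment
#'
#' Kabsch-Sander backbone hydrogen bonds (`E < -0.5` kcal/mol with the
#' standard 0.084 * 332 electrostatic model) drive a three-state alphabet:
#' residues inside runs of at least two consecutive i -> i+4 turns become
#' helix (H), residues H-bonded to a partner more than four residues away in
#' sequence become strand (E), everything else coil (C). Amide hydrogens are
#' reconstructed from the previous residue's C=O direction when absent
#' (1.0 A from N along C->O reversed). Chains are treated as independent
#' segments.
#'
#' @param traj Trajectory with backbone atoms N, CA, C, O
#' @return object of class `SecondaryStructureSeries`: list `states`
#'   (residues x frames character matrix), `helix_fraction` (per residue),
#'   `residues` (chain/resno table)
#' @export
assign_secondary_structure <- function(traj) {
  top <- traj$top
  res <- unique(top[, c("chain", "resno")])
  nres <- nrow(res)
  nf <- n_frames(traj)
  idx_of <- function(r, nm) {
    i <- which(top$chain == res$chain[r] & top$resno == res$resno[r] &
               top$name == nm)
    if (length(i)) i[1] else NA_integer_
  }
  iN  <- vapply(seq_len(nres), idx_of, 1L, nm = "N")
  iCA <- vapply(seq_len(nres), idx_of, 1L, nm = "CA")
  iC  <- vapply(seq_len(nres), idx_of, 1L, nm = "C")
  iO  <- vapply(seq_len(nres), idx_of, 1L, nm = "O")
  iH  <- vapply(seq_len(nres), idx_of, 1L, nm = "H")
  if (all(is.na(iN)) || all(is.na(iC)))
    stop("no backbone N/C atoms found; cannot assign secondary structure")
  prev <- c(NA_integer_, seq_len(nres - 1))
  prev[c(TRUE, res$chain[-1] != res$chain[-nres])] <- NA   # chain breaks
  states <- matrix("C", nres, nf)
  for (f in seq_len(nf)) {
    xyz <- traj$coords[, , f, drop = TRUE]
    Hpos <- matrix(NA_real_, nres, 3)
    for (r in seq_len(nres)) {
      if (!is.na(iH[r])) Hpos[r, ] <- xyz[iH[r], ]
      else if (!is.na(prev[r]) && !is.na(iC[prev[r]]) && !is.na(iO[prev[r]])) {
        d <- xyz[iC[prev[r]], ] - xyz[iO[prev[r]], ]
        Hpos[r, ] <- xyz[iN[r], ] + d / vnorm(d)
      }
    }
    # bond[i, j]: N-H of residue i donates to C=O of residue j
    bond <- matrix(FALSE, nres, nres)
    for (i in seq_len(nres)) {
      if (is.na(iN[i]) || anyNA(Hpos[i, ])) next
      for (j in seq_len(nres)) {
        if (i == j || is.na(iC[j]) || is.na(iO[j])) next
        if (vnorm(xyz[iN[i], ] - xyz[iO[j], ]) > 5.5) next   # K-S far cutoff
        e <- .ks_energy(xyz[iN[i], ], Hpos[i, ], xyz[iC[j], ], xyz[iO[j], ])
        bond[i, j] <- e < -0.5
      }
    }
    same_chain <- outer(res$chain, res$chain, "==")
    bond <- bond & same_chain
    # i -> i+4 turns; two consecutive turns make residues i+1..i+5 helical
    turn <- rep(FALSE, nres)
    for (j in seq_len(nres)) if (j + 4 <= nres && bond[j + 4, j] &&
                                 res$chain[j] == res$chain[j + 4]) turn[j] <- TRUE
    st <- rep("C", nres)
    for (j in seq_len(nres - 1)) if (turn[j] && turn[j + 1])
      st[(j + 1):min(j + 5, nres)] <- "H"
    # distant ladders -> strand
    sep <- abs(outer(seq_len(nres), seq_len(nres), "-"))
    ladder <- (bond | t(bond)) & sep > 4
    st[st == "C" & rowSums(ladder) > 0] <- "E"
    states[, f] <- st
  }
  structure(list(states = states,
                 helix_fraction = rowMeans(states == "H"),
                 residues = res), class = "SecondaryStructureSeries")
}

#' @export
print.SecondaryStructureSeries <- function(x, ...) {
  cat(sprintf("SecondaryStructureSeries: %d residues x %d frames\n",
              nrow(x$states), ncol(x$states)))
  cat(sprintf("  mean helix fraction: %.2f\n", mean(x$helix_fraction)))
  invisible(x)
}
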