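# Synthetic-trajectory generators with analytic ground truth. Each generator
# emulates one class of observable from the membrane-receptor study so that
# the matching analysis operation has an exact oracle: correlated C-alpha
# displacement ensembles, rigid helix pairs at prescribed tilt/crossing
# angles, bilayer slabs with prescribed headgroup separation / area per
# lipid / chain order, uniform and shell solvent, contact-occupancy
# schedules, and ideal peptide backbones. All generators draw from one
# seeded RNG per call and are bit-reproducible under a fixed seed.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  expr
}

.rot_about <- function(axis, angle_deg) {
  u <- axis / vnorm(axis)
  th <- angle_deg / DEG
  c_ <- cos(th); s <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    c_ + ux^2 * (1 - c_),      ux * uy * (1 - c_) - uz * s, ux * uz * (1 - c_) + uy * s,
    uy * ux * (1 - c_) + uz * s, c_ + uy^2 * (1 - c_),      uy * uz * (1 - c_) - ux * s,
    uz * ux * (1 - c_) - uy * s, uz * uy * (1 - c_) + ux * s, c_ + uz^2 * (1 - c_)),
    3, 3, byrow = TRUE)
}

#' Correlated C-alpha displacement ensemble
#'
#' Generates a pseudo C-alpha trajectory whose per-atom displacements are
#' multivariate normal with a prescribed inter-atom correlation matrix: each
#' atom's 3-vector displacement is `sigma * L z`, with `L` the Cholesky factor
#' of the target matrix shared across x/y/z, so the displacement dot-product
#' correlation equals the target exactly in expectation.
#'
#' @param target symmetric positive semi-definite correlation matrix
#'   (unit diagonal); one row per atom
#' @param sigma per-atom displacement scale (A); scalar or per-atom vector
#' @param n_frames ensemble size; @param seed RNG seed
#' @param spacing base-position spacing along x (A)
#' @return Trajectory of CA pseudo-atoms (chain A, residues 1..n)
#' @export
gen_correlated_trajectory <- function(target, sigma = 1, n_frames = 1000,
                                      seed = 1, spacing = 10) {
  n <- nrow(target)
  stopifnot(ncol(target) == n)
  if (max(abs(target - t(target))) > 1e-12) stop("target matrix must be symmetric")
  if (max(abs(diag(target) - 1)) > 1e-12) stop("target diagonal must be 1")
  ev <- eigen(target, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) stop("target correlation matrix is not positive semi-definite")
  # PSD (possibly singular) square root via eigendecomposition
  ed <- eigen(target, symmetric = TRUE)
  L <- ed$vectors %*% diag(sqrt(pmax(ed$values, 0)), n)
  sigma <- rep_len(sigma, n)
  base <- cbind((seq_len(n) - 1) * spacing, 0, 0)
  coords <- .with_seed(seed, {
    arr <- array(0, c(n, 3, n_frames))
    for (k in 1:3) {
      Z <- matrix(stats::rnorm(n * n_frames), n, n_frames)
      arr[, k, ] <- sigma * (L %*% Z) + base[, k]
    }
    arr
  })
  top <- topology(name = rep("CA", n), resname = rep("ALA", n),
                  chain = rep("A", n), resno = seq_len(n), elem = rep("C", n))
  trajectory(top, coords, box = c(1000, 1000, 1000))
}

#' Rigid helix pair at prescribed tilt and crossing angles
#'
#' Two straight poly-CA "helix axes" of `len` residues (1.5 A rise), both in
#' the xz-plane: helix 1's axis makes exactly `tilt` degrees with the box z
#' axis and helix 2's axis makes exactly `crossing` degrees with helix 1.
#' Per-frame angular jitter of s.d. `noise_sd` degrees rotates each axis
#' about the y axis, so the per-frame tilt is `tilt + delta1` and the
#' per-frame crossing angle `|crossing + delta2 - delta1|`: both means stay
#' exactly at the prescription (away from the 0/90/180 folds).
#'
#' @param tilt psi, degrees in `[0, 90]`; @param crossing phi, degrees in `[0, 180]`
#' @param len residues per helix; @param noise_sd jitter s.d. (deg)
#' @param n_frames frames; @param seed RNG seed
#' @return list `traj` (chains A and B) and `map` (AnchorMap with `tm_a`,
#'   `tm_b` domains and helix end anchors)
#' @export
gen_helix_pair <- function(tilt = 45, crossing = 35, len = 26, noise_sd = 0,
                           n_frames = 100, seed = 1) {
  stopifnot(tilt >= 0, tilt <= 90, crossing >= 0, crossing <= 180)
  axis_xz <- function(theta_deg)
    c(sin(theta_deg / DEG), 0, cos(theta_deg / DEG))
  centres <- list(c(40, 40, 50), c(50, 40, 50))
  offs <- (seq_len(len) - (len + 1) / 2) * 1.5
  n <- 2L * len
  jit <- .with_seed(seed, matrix(stats::rnorm(2 * n_frames, 0, max(noise_sd, 0)),
                                 n_frames, 2))
  if (noise_sd == 0) jit[] <- 0
  coords <- array(0, c(n, 3, n_frames))
  for (f in seq_len(n_frames)) {
    b1 <- axis_xz(tilt + jit[f, 1])
    b2 <- axis_xz(tilt + crossing + jit[f, 2])
    coords[seq_len(len), , f]        <- t(centres[[1]] + outer(b1, offs))
    coords[len + seq_len(len), , f]  <- t(centres[[2]] + outer(b2, offs))
  }
  top <- topology(name = rep("CA", n), resname = rep("ALA", n),
                  chain = rep(c("A", "B"), each = len),
                  resno = c(seq_len(len), seq_len(len)), elem = rep("C", n))
  map <- anchor_map(
    anchors = list(
      helix_a_bottom = list(chain = "A", resno = 1:4,              name = "CA"),
      helix_a_top    = list(chain = "A", resno = (len - 3):len,    name = "CA"),
      helix_b_bottom = list(chain = "B", resno = 1:4,              name = "CA"),
      helix_b_top    = list(chain = "B", resno = (len - 3):len,    name = "CA")),
    domains = list(tm_a = list(chain = "A", resno = seq_len(len)),
                   tm_b = list(chain = "B", resno = seq_len(len))))
  list(traj = trajectory(top, coords, box = c(100, 100, 150)), map = map)
}

#' Coarse bilayer slab with prescribed structural parameters
#'
#' Pseudo-lipids on an xy grid, one per site, in two leaflets. Each lipid is a
#' headgroup bead (element `BD`, pooled headgroup electron count) whose z is
#' normal around +/- `d`/2, plus an acyl chain of `chain_len` carbons starting
#' 3.75 A below the bead (the glycerol/carbonyl gap of a real phospholipid,
#' which keeps the electron-density maximum on the headgroup plane) and
#' stepping 1.25 A toward the midplane, each carrying two hydrogens at 1.09 A.
#' C-H
#' directions are sampled so that `E[(3 cos^2 theta - 1)/2]` equals the
#' prescribed S_CD per carbon: with probability `p = (2 S + 1)/3` the C-H
#' bond lies along z, otherwise uniformly in the xy plane.
#'
#' @param d headgroup-plane separation (A); @param sigma_h headgroup z s.d. (A)
#' @param n_leaflet lipids per leaflet (arranged on a near-square grid)
#' @param box_xy box x/y lengths (A), length-2 or scalar
#' @param scd prescribed S_CD, scalar or per-carbon vector in `[-0.5, 1]`
#' @param chain_len acyl carbons per lipid; @param n_frames frames
#' @param seed RNG seed
#' @return list `traj`, `map` (lipid metadata), and `spec` (echo of the
#'   ground-truth parameters, including the implied area per lipid)
#' @export
gen_membrane_slab <- function(d = 30, sigma_h = 2, n_leaflet = 49,
                              box_xy = 120, scd = -0.2, chain_len = 8,
                              n_frames = 20, seed = 1) {
  stopifnot(d > 0, n_leaflet >= 1, chain_len >= 1)
  scd <- rep_len(scd, chain_len)
  if (any(scd < -0.5 | scd > 1))
    stop("prescribed S_CD outside the reachable range [-0.5, 1]")
  p_up <- (2 * scd + 1) / 3
  box_xy <- rep_len(box_xy, 2)
  box_z <- max(4 * d, 100)
  nx <- ceiling(sqrt(n_leaflet))
  sites <- expand.grid(x = seq_len(nx), y = seq_len(nx))[seq_len(n_leaflet), ]
  sx <- (sites$x - 0.5) * box_xy[1] / nx
  sy <- (sites$y - 0.5) * box_xy[2] / nx
  n_lip <- 2L * n_leaflet
  at_per_lip <- 1L + 3L * chain_len           # bead + (C + 2H) per carbon
  n <- n_lip * at_per_lip
  names_l <- c("BD", as.vector(rbind(paste0("C", seq_len(chain_len)),
                                     paste0("H", seq_len(chain_len), "A"),
                                     paste0("H", seq_len(chain_len), "B"))))
  elem_l <- c("BD", rep(c("C", "H", "H"), chain_len))
  top <- topology(name = rep(names_l, n_lip),
                  resname = rep("LIP", n),
                  chain = rep("L", n),
                  resno = rep(seq_len(n_lip), each = at_per_lip),
                  elem = rep(elem_l, n_lip))
  coords <- .with_seed(seed, {
    arr <- array(0, c(n, 3, n_frames))
    for (f in seq_len(n_frames)) {
      xyz <- matrix(0, n, 3)
      row <- 0L
      for (leaf in c(1, -1)) for (i in seq_len(n_leaflet)) {
        hz <- leaf * d / 2 + stats::rnorm(1, 0, sigma_h)
        xyz[row + 1L, ] <- c(sx[i], sy[i], hz)
        for (k in seq_len(chain_len)) {
          cz <- hz - leaf * (3.75 + k * 1.25)
          cpos <- c(sx[i], sy[i], cz)
          xyz[row + 3L * k - 1L, ] <- cpos
          for (h in 1:2) {
            if (stats::runif(1) < p_up[k]) {
              dir <- c(0, 0, sample(c(-1, 1), 1))
            } else {
              phi <- stats::runif(1, 0, 2 * pi)
              dir <- c(cos(phi), sin(phi), 0)
            }
            xyz[row + 3L * k - 1L + h, ] <- cpos + 1.09 * dir
          }
        }
        row <- row + at_per_lip
      }
      arr[, , f] <- xyz
    }
    arr
  })
  map <- anchor_map(lipids = list(resname = "LIP", head = "BD",
                                  carbon_prefix = "C",
                                  hydrogen_suffixes = c("A", "B")))
  spec <- list(d = d, sigma_h = sigma_h, n_leaflet = n_leaflet,
               box_xy = box_xy, scd = scd, chain_len = chain_len,
               area_per_lipid = box_xy[1] * box_xy[2] / n_leaflet)
  list(traj = trajectory(top, coords, box = c(box_xy, box_z)), map = map,
       spec = spec)
}

#' Uniform or shell solvent ensembles
#'
#' `kind = "uniform"`: ideal-gas water oxygens at a given number density in
#' the box (the RDF of this fixture is 1 at all r). `kind = "shell"`: one
#' probe atom at the box centre with `n_shell` oxygens at radius `r0`.
#'
#' @param kind `"uniform"` or `"shell"`
#' @param box cell lengths (length-3)
#' @param density number density (A^-3) for `"uniform"`
#' @param n_shell,r0 shell population and radius (A) for `"shell"`
#' @param n_frames frames; @param seed RNG seed
#' @return Trajectory (water oxygens, resname WAT; shell probe is atom 1,
#'   name `"P1"`, resname PRB)
#' @export
gen_solvent <- function(kind = c("uniform", "shell"), box = c(30, 30, 30),
                        density = 0.033, n_shell = 12, r0 = 4,
                        n_frames = 10, seed = 1) {
  kind <- match.arg(kind)
  if (kind == "uniform") {
    n <- round(density * prod(box))
    if (n < 1) stop("density too low: no solvent atoms in the box")
    coords <- .with_seed(seed, {
      arr <- array(0, c(n, 3, n_frames))
      for (f in seq_len(n_frames))
        for (k in 1:3) arr[, k, f] <- stats::runif(n, 0, box[k])
      arr
    })
    top <- topology(name = rep("O", n), resname = rep("WAT", n),
                    chain = rep("W", n), resno = seq_len(n), elem = rep("O", n))
    return(trajectory(top, coords, box = box))
  }
  n <- n_shell + 1L
  coords <- .with_seed(seed, {
    arr <- array(0, c(n, 3, n_frames))
    for (f in seq_len(n_frames)) {
      arr[1, , f] <- box / 2
      u <- stats::rnorm(3 * n_shell)
      dim(u) <- c(n_shell, 3)
      u <- u / sqrt(rowSums(u^2))
      arr[-1, , f] <- matrix(box / 2, n_shell, 3, byrow = TRUE) + r0 * u
    }
    arr
  })
  top <- topology(name = c("P1", rep("O", n_shell)),
                  resname = c("PRB", rep("WAT", n_shell)),
                  chain = c("X", rep("W", n_shell)),
                  resno = seq_len(n), elem = c("P", rep("O", n_shell)))
  trajectory(top, coords, box = box)
}

#' Two-atom contact-occupancy schedule
#'
#' The inter-atom distance is `r_in` (< 4 A) in exactly
#' `round(occupancy * n_frames)` frames and `r_out` otherwise; contact frames
#' are chosen by seeded sampling without replacement.
#'
#' @param occupancy target contact fraction in `[0, 1]`
#' @param n_frames frames; @param seed RNG seed
#' @param r_in,r_out in-contact / out-of-contact separations (A)
#' @return Trajectory of two CA pseudo-atoms (residues 1 and 2)
#' @export
gen_contact_schedule <- function(occupancy, n_frames = 100, seed = 1,
                                 r_in = 3, r_out = 8) {
  stopifnot(occupancy >= 0, occupancy <= 1, r_in < 4, r_out >= 4)
  k <- round(occupancy * n_frames)
  on_frames <- .with_seed(seed, sort(sample.int(n_frames, k)))
  coords <- array(0, c(2, 3, n_frames))
  coords[1, , ] <- 10
  sep <- rep(r_out, n_frames); sep[on_frames] <- r_in
  coords[2, 1, ] <- 10 + sep
  coords[2, 2:3, ] <- 10
  top <- topology(name = c("CA", "CA"), resname = c("ALA", "ALA"),
                  chain = c("A", "B"), resno = c(1L, 1L), elem = c("C", "C"))
  trajectory(top, coords, box = c(50, 50, 50))
}

# -- ideal peptide backbones (secondary-structure oracle) ---------------------

.nerf_place <- function(A, B, C, bond, angle, torsion) {
  ang <- angle / DEG; tor <- torsion / DEG
  bc <- C - B; bc <- bc / vnorm(bc)
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2], ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / vnorm(n)
  m <- c(n[2] * bc[3] - n[3] * bc[2], n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d <- c(-bond * cos(ang), bond * cos(tor) * sin(ang), bond * sin(tor) * sin(ang))
  C + d[1] * bc + d[2] * m + d[3] * n
}

#' Ideal peptide backbone at fixed (phi, psi)
#'
#' Builds an N/CA/C/O backbone chain with standard bond geometry and uniform
#' torsions: `phi = -57, psi = -47` gives an ideal alpha-helix whose
#' i -> i+4 amide hydrogen bonds score well below the Kabsch-Sander cutoff;
#' `phi = -140, psi = 135` gives an extended strand-like chain with none.
#'
#' @param n_res residues; @param phi,psi backbone torsions (deg)
#' @param n_frames replicate frames (identical geometry)
#' @return Trajectory (chain A, residues 1..n_res, atoms N/CA/C/O)
#' @export
gen_ideal_chain <- function(n_res = 12, phi = -57, psi = -47, n_frames = 1) {
  stopifnot(n_res >= 2)
  N <- CA <- C <- O <- matrix(0, n_res, 3)
  N[1, ] <- c(0, 0, 0); CA[1, ] <- c(1.458, 0, 0)
  C[1, ] <- .nerf_place(c(-1, 1, 0), N[1, ], CA[1, ], 1.525, 111.2, 0)
  for (i in seq_len(n_res)) {
    if (i > 1) {
      N[i, ]  <- .nerf_place(N[i - 1, ], CA[i - 1, ], C[i - 1, ], 1.329, 116.2, psi)
      CA[i, ] <- .nerf_place(CA[i - 1, ], C[i - 1, ], N[i, ], 1.458, 121.7, 180)
      C[i, ]  <- .nerf_place(C[i - 1, ], N[i, ], CA[i, ], 1.525, 111.2, phi)
    }
    O[i, ] <- .nerf_place(N[i, ], CA[i, ], C[i, ], 1.231, 120.8, psi + 180)
  }
  xyz <- matrix(0, 4 * n_res, 3)
  xyz[seq(1, by = 4, length.out = n_res), ] <- N
  xyz[seq(2, by = 4, length.out = n_res), ] <- CA
  xyz[seq(3, by = 4, length.out = n_res), ] <- C
  xyz[seq(4, by = 4, length.out = n_res), ] <- O
  xyz <- sweep(xyz, 2, apply(xyz, 2, min) - 10)   # keep coordinates positive
  top <- topology(name = rep(c("N", "CA", "C", "O"), n_res),
                  resname = rep("ALA", 4 * n_res),
                  chain = rep("A", 4 * n_res),
                  resno = rep(seq_len(n_res), each = 4),
                  elem = rep(c("N", "C", "C", "O"), n_res))
  coords <- array(rep(xyz, n_frames), c(4 * n_res, 3, n_frames))
  trajectory(top, coords, box = c(200, 200, 200))
}
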