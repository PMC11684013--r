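# Global-dynamics statistics: RMSD/RMSF/B-factors, Pearson dynamic
# cross-correlation with domain-pair correlation densities, mass-weighted
# C-alpha PCA (essential dynamics), and hierarchical conformation clustering.

.fitted_coords <- function(traj, selection, fit) {
  # returns traj with frames aligned per `fit`: "none", "start", "average",
  # or a Frame/matrix reference
  if (is.character(fit) && fit == "none") return(traj)
  ref <- if (inherits(fit, "Frame") || is.matrix(fit)) fit
         else if (identical(fit, "start")) get_frame(traj, 1)
         else if (identical(fit, "average")) average_structure(traj, selection)
         else stop("unknown fit reference '", fit, "'")
  fit_trajectory(traj, ref, selection)$traj
}

#' Per-frame RMSD against a reference structure
#'
#' @param traj Trajectory; @param reference Frame or n x 3 matrix (default:
#'   first frame)
#' @param selection atom indices entering both the fit and the RMSD
#' @param fit superpose each frame before measuring (default TRUE)
#' @return numeric vector, one RMSD (A) per frame
#' @export
rmsd_series <- function(traj, reference = NULL, selection = NULL, fit = TRUE) {
  if (is.null(reference)) reference <- get_frame(traj, 1)
  rx <- if (inherits(reference, "Frame")) reference$coords else reference
  if (is.null(selection)) selection <- seq_len(n_atoms(traj))
  if (!length(selection)) stop("empty selection")
  nf <- n_frames(traj)
  out <- numeric(nf)
  for (f in seq_len(nf)) {
    mx <- traj$coords[, , f, drop = TRUE]
    if (fit) {
      out[f] <- superpose(mx, rx, selection)$rmsd
    } else {
      d <- mx[selection, , drop = FALSE] - rx[selection, , drop = FALSE]
      out[f] <- sqrt(mean(rowSums(d * d)))
    }
  }
  out
}

#' Root-mean-square fluctuation and crystallographic B-factors
#'
#' Each frame is superposed onto the fit reference over `selection`; the RMSF
#' of atom i is the root-mean-square distance from its time-averaged
#' position. B-factor = (8 pi^2 / 3) RMSF^2.
#'
#' @param traj Trajectory; @param selection atoms reported (default: C-alphas)
#' @param fit `"average"`, `"start"`, `"none"`, or a reference Frame
#' @return data.frame with atom metadata, `rmsf` (A) and `bfactor` (A^2)
#' @export
rmsf <- function(traj, selection = NULL, fit = "average") {
  if (n_frames(traj) < 2) stop("RMSF needs at least two frames")
  if (is.null(selection)) selection <- select_calpha(traj)
  tr <- .fitted_coords(traj, selection, fit)
  X <- tr$coords[selection, , , drop = FALSE]
  mu <- apply(X, c(1, 2), mean)
  dev2 <- sweep(X, c(1, 2), mu)^2
  msf <- apply(dev2, 1, mean) * 3       # mean over frames of |dr|^2
  r <- sqrt(msf)
  data.frame(tr$top[selection, c("chain", "resno", "resname", "name")],
             rmsf = r, bfactor = 8 * pi^2 / 3 * r^2, row.names = NULL)
}

#' Dynamic cross-correlation matrix (DCCM)
#'
#' Pearson correlation of atomic displacement vectors:
#' `C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>)`, with `dr` the
#' displacement of each atom from its time-mean position after the frames are
#' RMS-fitted to the reference (by default the iteratively averaged
#' structure, removing global rotation/translation so only internal dynamics
#' remain). Values lie in [-1, 1]; the diagonal is exactly 1.
#'
#' @param traj Trajectory; @param selection atoms (default: C-alphas)
#' @param fit `"average"` (default), `"start"`, `"none"`, or a Frame
#' @return object of class `CorrelationMatrix`: list with `C` (labelled
#'   matrix), `atoms` (metadata), `fit`
#' @export
cross_correlation <- function(traj, selection = NULL, fit = "average") {
  if (n_frames(traj) < 2) stop("cross-correlation needs at least two frames")
  if (is.null(selection)) selection <- select_calpha(traj)
  if (!length(selection)) stop("empty selection")
  tr <- .fitted_coords(traj, selection, fit)
  X <- tr$coords[selection, , , drop = FALSE]           # n x 3 x f
  mu <- apply(X, c(1, 2), mean)
  D <- sweep(X, c(1, 2), mu)
  n <- length(selection); nf <- dim(X)[3]
  # <dr_i . dr_j> = (1/nf) sum_k sum_f D[i,k,f] D[j,k,f]
  cij <- matrix(0, n, n)
  for (k in 1:3) cij <- cij + D[, k, ] %*% t(D[, k, ])
  cij <- cij / nf
  v <- diag(cij)
  zero <- v <= .Machine$double.eps * 10
  if (any(zero))
    warning(sum(zero), " zero-variance atom(s); their correlations are NA")
  den <- sqrt(outer(v, v))
  C <- cij / den
  C[zero, ] <- NA_real_; C[, zero] <- NA_real_
  diag(C)[!zero] <- 1
  C <- pmin(pmax(C, -1), 1)
  lab <- paste0(tr$top$chain[selection], tr$top$resno[selection])
  dimnames(C) <- list(lab, lab)
  structure(list(C = C, atoms = tr$top[selection, , drop = FALSE],
                 selection = selection,
                 fit = if (is.character(fit)) fit else "frame"),
            class = "CorrelationMatrix")
}

#' @export
print.CorrelationMatrix <- function(x, ...) {
  cat(sprintf("CorrelationMatrix: %d residues (fit: %s)\n", nrow(x$C), x$fit))
  cat(sprintf("  C_ij range: %.3f .. %.3f\n", min(x$C, na.rm = TRUE),
              max(x$C, na.rm = TRUE)))
  invisible(x)
}

#' Simplified domain-pair correlation matrix
#'
#' Collapses a residue-level DCCM onto domain blocks. For domains A, B the
#' correlation score is the signed sum `CS(A,B) = sum_{i in A, j in B} C_ij`
#' over ordered residue pairs (diagonal blocks therefore include the i = j
#' self terms), and the correlation density divides CS by `|A| * |B|` so a
#' pair of single-residue domains reproduces the underlying `C_ij`. Summing
#' CS over the full domain-pair matrix recovers the grand sum of C.
#'
#' @param cc CorrelationMatrix; @param map AnchorMap with domain definitions
#' @return object of class `SimplifiedMatrix`: list with `cs` and `density`
#'   (domain x domain matrices) and `sizes`
#' @export
simplify_correlation <- function(cc, map) {
  traj_like <- cc$atoms
  dom <- lapply(map$domains, function(d)
    which(traj_like$chain %in% d$chain & traj_like$resno %in% d$resno))
  all_idx <- unlist(dom)
  if (anyDuplicated(all_idx)) stop("domain definitions overlap")
  if (!setequal(all_idx, seq_len(nrow(cc$C))))
    stop("domains do not cover every residue of the correlation matrix")
  nd <- length(dom)
  cs <- matrix(0, nd, nd, dimnames = list(names(dom), names(dom)))
  for (a in seq_len(nd)) for (b in seq_len(nd))
    cs[a, b] <- sum(cc$C[dom[[a]], dom[[b]], drop = FALSE])
  sizes <- vapply(dom, length, 1L)
  density <- cs / outer(sizes, sizes)
  structure(list(cs = cs, density = density, sizes = sizes),
            class = "SimplifiedMatrix")
}

#' @export
print.SimplifiedMatrix <- function(x, digits = 3, ...) {
  cat("SimplifiedMatrix: correlation densities\n")
  print(round(x$density, digits))
  invisible(x)
}

#' Mass-weighted C-alpha principal component analysis
#'
#' Essential dynamics: frames are RMS-fitted to the starting configuration,
#' coordinates are weighted by sqrt(mass), and the covariance matrix of the
#' flattened 3N-dimensional ensemble is eigendecomposed. Reports eigenvalues
#' (descending), variance fractions, cumulative variance and the per-frame
#' projections onto the leading components.
#'
#' @param traj Trajectory; @param selection atoms (default C-alphas)
#' @param fit `"start"` (default, the reference starting configuration),
#'   `"average"`, `"none"`, or a Frame
#' @param n_proj number of components to project frames onto
#' @return object of class `PCAResult`
#' @export
pca_dynamics <- function(traj, selection = NULL, fit = "start", n_proj = 2) {
  if (n_frames(traj) < 2) stop("PCA needs at least two frames")
  if (is.null(selection)) selection <- select_calpha(traj)
  tr <- .fitted_coords(traj, selection, fit)
  X <- tr$coords[selection, , , drop = FALSE]
  nf <- dim(X)[3]; n <- length(selection)
  M <- t(matrix(X, n * 3, nf))                # frames x 3N (atom-major)
  w <- rep(sqrt(tr$top$mass[selection]), 3)
  Mw <- sweep(M, 2, w, "*")
  mu <- colMeans(Mw)
  Dw <- sweep(Mw, 2, mu)
  keepcol <- apply(Dw, 2, function(x) stats::var(x) > .Machine$double.eps * 10)
  if (!all(keepcol))
    warning(sum(!keepcol), " zero-variance coordinate(s) excluded from PCA")
  if (!any(keepcol)) {
    return(structure(list(values = numeric(0), vectors = matrix(0, 0, 0),
                          var_frac = numeric(0), cum_var = numeric(0),
                          projections = matrix(0, nf, 0), selection = selection),
                     class = "PCAResult"))
  }
  S <- stats::cov(Dw[, keepcol, drop = FALSE])
  ed <- eigen(S, symmetric = TRUE)
  vals <- pmax(ed$values, 0)
  vf <- vals / sum(vals)
  k <- min(n_proj, length(vals))
  proj <- Dw[, keepcol, drop = FALSE] %*% ed$vectors[, seq_len(k), drop = FALSE]
  vec_full <- matrix(0, ncol(Dw), length(vals))
  vec_full[keepcol, ] <- ed$vectors
  structure(list(values = vals, vectors = vec_full, var_frac = vf,
                 cum_var = cumsum(vf), projections = proj,
                 selection = selection), class = "PCAResult")
}

#' @export
print.PCAResult <- function(x, ...) {
  k <- min(5, length(x$values))
  cat("PCAResult (mass-weighted essential dynamics)\n")
  if (k > 0)
    cat(sprintf("  PC%-2d var %.1f%%  (cum %.1f%%)\n", seq_len(k),
                100 * x$var_frac[seq_len(k)], 100 * x$cum_var[seq_len(k)]),
        sep = "")
  invisible(x)
}

#' Hierarchical agglomerative clustering of conformations
#'
#' Average-linkage agglomeration on the matrix of pairwise post-fit RMSDs
#' over `selection` (backbone atoms in the published protocol). Merging stops
#' once the smallest inter-cluster linkage exceeds `epsilon` (A); each
#' cluster is represented by its medoid (the frame minimising the summed
#' RMSD to its cluster mates, earliest frame on ties).
#'
#' @param traj Trajectory; @param selection atom indices (default: backbone
#'   N/CA/C/O atoms)
#' @param epsilon linkage cut distance in A (default 7)
#' @param method hclust linkage (default `"average"`)
#' @return object of class `ClusterResult`: `cluster` (per-frame id),
#'   `medoids` (frame index per cluster), `n_clusters`, `dist` (RMSD matrix)
#' @export
cluster_conformations <- function(traj, selection = NULL, epsilon = 7,
                                  method = "average") {
  if (is.null(selection))
    selection <- select_atoms(traj, name = c("N", "CA", "C", "O"))
  if (!length(selection)) selection <- seq_len(n_atoms(traj))
  nf <- n_frames(traj)
  if (nf == 1)
    return(structure(list(cluster = 1L, medoids = 1L, n_clusters = 1L,
                          dist = matrix(0, 1, 1)), class = "ClusterResult"))
  D <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1)) {
    ri <- traj$coords[, , i, drop = TRUE]
    for (j in (i + 1):nf)
      D[i, j] <- D[j, i] <- superpose(traj$coords[, , j, drop = TRUE], ri,
                                      selection)$rmsd
  }
  hc <- stats::hclust(stats::as.dist(D), method = method)
  cl <- stats::cutree(hc, h = epsilon)
  meds <- vapply(sort(unique(cl)), function(k) {
    idx <- which(cl == k)
    if (length(idx) == 1) return(idx)
    tot <- rowSums(D[idx, idx, drop = FALSE])
    idx[which.min(tot)]          # which.min takes the earliest on ties
  }, 1L)
  structure(list(cluster = cl, medoids = meds,
                 n_clusters = length(unique(cl)), dist = D),
            class = "ClusterResult")
}

#' @export
print.ClusterResult <- function(x, ...) {
  cat(sprintf("ClusterResult: %d cluster(s) over %d frames\n",
              x$n_clusters, length(x$cluster)))
  tab <- table(x$cluster)
  for (k in seq_along(tab))
    cat(sprintf("  cluster %s: %d frames, medoid frame %d\n",
                names(tab)[k], tab[k], x$medoids[k]))
  invisible(x)
}
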