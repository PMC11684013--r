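# Bilayer structural observables: normalized electron density profile and
# peak-to-peak thickness, area per lipid, leaflet assignment, and deuterium
# order parameters S_CD. The membrane normal is the z axis throughout.

#' Normalized electron density profile along the membrane normal
#'
#' Per frame, atomic electron counts (atomic numbers) of the selection are
#' binned along z relative to the electron-weighted bilayer centre; the
#' frame-averaged histogram is divided by bin volume and normalized to unit
#' maximum. The two peaks are the highest local maxima on either side of the
#' midplane after 3-bin moving-average smoothing; peak-to-peak distance is
#' the bilayer thickness. A profile without a distinct peak on each side
#' (e.g. a uniform slab) reports `NA` thickness with a warning.
#'
#' @param traj Trajectory; @param selection lipid atom indices
#' @param bin bin width along z (A, default 1)
#' @return object of class `DensityProfile`: data.frame `z`, `density`, with
#'   attributes `peaks` (z of the two peaks) and `thickness` (A)
#' @export
electron_density <- function(traj, selection = NULL, bin = 1) {
  if (is.null(selection)) selection <- seq_len(n_atoms(traj))
  if (!length(selection)) stop("empty lipid selection")
  nf <- n_frames(traj)
  ne <- traj$top$atomno[selection]
  zmax <- max(traj$box[, 3], na.rm = TRUE)
  if (!is.finite(zmax)) zmax <- diff(range(traj$coords[selection, 3, ])) + 2 * bin
  edges <- seq(-zmax / 2, zmax / 2 + bin, by = bin)
  acc <- numeric(length(edges) - 1)
  for (f in seq_len(nf)) {
    z <- traj$coords[selection, 3, f]
    z0 <- sum(z * ne) / sum(ne)                       # bilayer centre
    idx <- cut(z - z0, edges, right = FALSE, labels = FALSE)
    ok <- !is.na(idx)
    acc <- acc + unname(tapply(ne[ok], factor(idx[ok], seq_along(acc)), sum,
                               default = 0))
  }
  area <- mean(traj$box[, 1] * traj$box[, 2])
  if (!is.finite(area)) area <- 1
  dens <- acc / nf / (area * bin)                     # e- per A^3
  if (max(dens) > 0) dens <- dens / max(dens)
  centers <- edges[-length(edges)] + bin / 2
  # 3-bin moving average for peak finding only
  sm <- stats::filter(dens, rep(1 / 3, 3), sides = 2)
  sm[is.na(sm)] <- 0
  local_max <- which(diff(sign(diff(c(-Inf, sm, -Inf)))) < 0)
  lower <- local_max[centers[local_max] < 0]
  upper <- local_max[centers[local_max] >= 0]
  peaks <- c(NA_real_, NA_real_); thickness <- NA_real_
  if (length(lower) && length(upper)) {
    p1 <- lower[which.max(sm[lower])]
    p2 <- upper[which.max(sm[upper])]
    # a genuine bilayer has a trough between the leaflet peaks; a flat or
    # single-peaked profile does not
    trough <- min(sm[p1:p2])
    if (trough < 0.6 * min(sm[p1], sm[p2])) {
      peaks <- centers[c(p1, p2)]
      thickness <- abs(peaks[2] - peaks[1])
    }
  }
  if (is.na(thickness))
    warning("no distinct density peak on each side of the midplane; ",
            "thickness undefined")
  out <- data.frame(z = centers, density = dens)
  class(out) <- c("DensityProfile", "data.frame")
  attr(out, "peaks") <- peaks
  attr(out, "thickness") <- thickness
  attr(out, "bin") <- bin
  out
}

#' Bilayer peak-to-peak thickness
#' @param profile DensityProfile
#' @export
thickness <- function(profile) attr(profile, "thickness")

#' Assign lipids to leaflets
#'
#' Lipids whose headgroup z lies at or above the headgroup midplane go to the
#' upper leaflet, the rest to the lower; a lipid exactly at the midplane is
#' assigned upper by the >= convention.
#'
#' @param frame Frame; @param top Topology
#' @param head_idx headgroup atom indices (one per lipid)
#' @return factor (`"upper"`/`"lower"`) named by lipid residue number
#' @export
assign_leaflets <- function(frame, top, head_idx) {
  if (!length(head_idx)) stop("no headgroup atoms given")
  z <- frame$coords[head_idx, 3]
  mid <- mean(z)
  lab <- factor(ifelse(z >= mid, "upper", "lower"), levels = c("upper", "lower"))
  names(lab) <- top$resno[head_idx]
  lab
}

#' Area per lipid time series
#'
#' `box_x * box_y / n_leaflet` per frame; APL times the leaflet count equals
#' the lateral box area exactly by construction.
#'
#' @param traj Trajectory; @param n_leaflet lipids in the leaflet
#' @return numeric per-frame APL (A^2)
#' @export
area_per_lipid <- function(traj, n_leaflet) {
  if (n_leaflet < 1) stop("leaflet must contain at least one lipid")
  a <- traj$box[, 1] * traj$box[, 2]
  if (any(!is.finite(a))) stop("area per lipid needs a defined box")
  a / n_leaflet
}

#' Deuterium order parameters S_CD per acyl carbon
#'
#' `S_CD(k) = < (3 cos^2 theta - 1) / 2 >` over frames, lipids and the
#' hydrogens bonded to carbon k, with theta the C-H angle to the membrane
#' normal (z). Bonded hydrogens are resolved by the naming scheme in the
#' lipid metadata (carbon `C<k>` owns `H<k>A`, `H<k>B`, ...). The sign is
#' reported as computed (ordered chains in a bilayer give negative values,
#' around -0.2); carbons with no resolvable hydrogen are skipped with a
#' warning.
#'
#' @param traj Trajectory; @param map AnchorMap with `lipids` metadata
#' @return object of class `OrderParameterProfile`: data.frame `carbon`,
#'   `scd`, `n_samples`
#' @export
order_parameters <- function(traj, map) {
  lip <- map$lipids
  if (is.null(lip)) stop("AnchorMap carries no lipid metadata")
  top <- traj$top
  in_lip <- top$resname %in% lip$resname
  if (!any(in_lip)) stop("no lipid atoms in the topology")
  pre <- lip$carbon_prefix %||% "C"
  suf <- lip$hydrogen_suffixes %||% c("A", "B", "C")
  cn <- grep(paste0("^", pre, "[0-9]+$"), unique(top$name[in_lip]), value = TRUE)
  ks <- sort(as.integer(sub(pre, "", cn, fixed = TRUE)))
  if (!length(ks)) stop("no acyl carbons match the naming scheme")
  nf <- n_frames(traj)
  out <- data.frame(carbon = ks, scd = NA_real_, n_samples = 0L)
  lip_res <- interaction(top$chain, top$resno, drop = TRUE)
  for (r in seq_along(ks)) {
    k <- ks[r]
    cidx <- which(in_lip & top$name == paste0(pre, k))
    hnames <- paste0("H", k, suf)
    # pair each carbon with the hydrogens of the same lipid residue
    acc <- 0; nsmp <- 0L
    for (h in hnames) {
      hidx <- which(in_lip & top$name == h)
      if (!length(hidx)) next
      m <- match(lip_res[cidx], lip_res[hidx])
      ok <- !is.na(m)
      if (!any(ok)) next
      ci <- cidx[ok]; hi <- hidx[m[ok]]
      for (f in seq_len(nf)) {
        d <- frame_coords(traj, hi, f) - frame_coords(traj, ci, f)
        ct2 <- d[, 3]^2 / rowSums(d * d)
        acc <- acc + sum((3 * ct2 - 1) / 2)
        nsmp <- nsmp + length(ct2)
      }
    }
    if (nsmp == 0L) {
      warning("carbon ", pre, k, " has no resolvable bonded hydrogen; skipped")
      next
    }
    out$scd[r] <- acc / nsmp
    out$n_samples[r] <- nsmp
  }
  out <- out[!is.na(out$scd), , drop = FALSE]
  class(out) <- c("OrderParameterProfile", "data.frame")
  out
}
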