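# Config-driven orchestration: run the full analysis battery over a
# trajectory per a YAML/list config, with per-stage error capture, a file
# manifest, and a synthetic validation suite with a recovery table.

.write_csv <- function(df, path, meta = NULL) {
  con <- file(path, "wt")
  on.exit(close(con))
  if (!is.null(meta)) writeLines(paste0("# ", meta), con)
  utils::write.csv(format(df, digits = 6, trim = TRUE), con,
                   row.names = FALSE, quote = FALSE)
  path
}

#' Run the full analysis battery from a config
#'
#' Stages (each independently toggleable, failures logged and skipped):
#' windowing/alignment, RMSD + RMSF, cross-correlation + simplified matrix,
#' PCA, clustering, geometry battery (tilt psi, crossing phi, bending
#' alpha_V/alpha_H, anchor distances), membrane battery (electron density,
#' APL, S_CD), interaction battery (RDF, persistence, H-bonds, secondary
#' structure). Outputs are CSV/JSON files in `config$output_dir`.
#'
#' @param config list or path to a YAML config. Recognised fields:
#'   `structure` (PDB path) or `trajectory` (pre-built Trajectory),
#'   `anchor_map` (path or AnchorMap), `window` (`offset_ns`, `stride`,
#'   `align`), `output_dir`, and per-stage toggles under `stages` with
#'   parameters (`epsilon`, `cutoff`, `density_bin`, `angle_bin`, ...).
#' @return object of class `RunReport`: `manifest`, `warnings`, `errors`,
#'   `wall_time`, `config`
#' @export
run_analysis <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  t0 <- Sys.time()
  out_dir <- config$output_dir %||% "memsig_out"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- character(0); errs <- character(0); warns <- character(0)
  note <- function(stage, e) {
    msg <- sprintf("[%s] %s", stage, conditionMessage(e))
    message("stage failed: ", msg)
    errs <<- c(errs, msg)
  }
  traj <- if (!is.null(config$trajectory_object)) config$trajectory_object
          else {
            if (is.null(config$structure)) stop("config names no structure/trajectory")
            if (!file.exists(config$structure))
              stop("structure file does not exist: ", config$structure)
            tr <- read_structure(config$structure)
            if (!is.null(config$trajectory)) {
              if (!file.exists(config$trajectory))
                stop("trajectory file does not exist: ", config$trajectory)
              tr <- read_dcd(config$trajectory, tr$top)
            }
            tr
          }
  map <- config$anchor_map
  if (is.character(map)) map <- read_anchor_map(map)
  w <- config$window %||% list()
  sel_fit <- if (!is.null(w$selection)) w$selection else select_calpha(traj)
  if (!length(sel_fit)) sel_fit <- NULL
  window <- frame_window(offset_ns = w$offset_ns %||% 0,
                         stride = w$stride %||% 1,
                         align = w$align %||% "none", selection = sel_fit)
  traj <- apply_window(traj, window)
  st <- config$stages %||% list()
  on_stage <- function(name) {
    v <- st[[name]]
    if (is.list(v)) isTRUE(v$enabled %||% TRUE) else isTRUE(v)
  }
  stage_par <- function(name, key, default) {
    v <- st[[name]]
    if (is.list(v)) v[[key]] %||% default else default
  }
  emit <- function(df, file, meta) {
    p <- .write_csv(df, file.path(out_dir, file), meta)
    manifest <<- c(manifest, p)
  }
  withCallingHandlers({
    if (on_stage("rmsd")) tryCatch({
      r <- rmsd_series(traj, selection = sel_fit)
      emit(data.frame(time_ns = traj$time, rmsd_A = r), "rmsd.csv",
           "per-frame RMSD vs first windowed frame, C-alpha fit")
    }, error = function(e) note("rmsd", e))
    if (on_stage("rmsf")) tryCatch({
      emit(rmsf(traj, fit = "average"), "rmsf.csv",
           "RMSF/B-factor per C-alpha, fit: averaged structure")
    }, error = function(e) note("rmsf", e))
    if (on_stage("correlation")) tryCatch({
      cc <- cross_correlation(traj, fit = "average")
      emit(data.frame(residue = rownames(cc$C), cc$C, check.names = FALSE),
           "cross_correlation.csv", "DCCM, fit: averaged structure")
      if (!is.null(map) && length(map$domains)) {
        sm <- simplify_correlation(cc, map)
        p <- file.path(out_dir, "simplified_correlation.json")
        jsonlite::write_json(list(domains = names(sm$sizes),
                                  sizes = sm$sizes, cs = sm$cs,
                                  density = sm$density), p, digits = NA,
                             matrix = "rowmajor")
        manifest <- c(manifest, p)
      }
    }, error = function(e) note("correlation", e))
    if (on_stage("pca")) tryCatch({
      p <- pca_dynamics(traj, fit = "start")
      emit(data.frame(pc = seq_along(p$var_frac), var_frac = p$var_frac,
                      cum_var = p$cum_var), "pca_variance.csv",
           "mass-weighted C-alpha PCA, fit: starting configuration")
      if (ncol(p$projections) >= 2)
        emit(data.frame(time_ns = traj$time, pc1 = p$projections[, 1],
                        pc2 = p$projections[, 2]), "pca_projections.csv",
             "per-frame projections onto PC1/PC2")
    }, error = function(e) note("pca", e))
    if (on_stage("cluster")) tryCatch({
      eps <- stage_par("cluster", "epsilon", 7)
      cl <- cluster_conformations(traj, epsilon = eps)
      emit(data.frame(time_ns = traj$time, cluster = cl$cluster),
           "clusters.csv", paste0("average-linkage backbone-RMSD, epsilon ",
                                  eps, " A; medoids: ",
                                  paste(cl$medoids, collapse = " ")))
    }, error = function(e) note("cluster", e))
    if (on_stage("geometry") && !is.null(map)) tryCatch({
      bin1 <- stage_par("geometry", "angle_bin", 1)
      if (!is.null(map$anchors$val73)) {
        ps <- tilt_angle_series(traj, resolve_anchor(traj, map, "val73"),
                                resolve_anchor(traj, map, "val92"))
        emit(data.frame(time_ns = traj$time, tilt_deg = ps), "tilt.csv",
             "TM tilt psi vs unit-cell z, folded to [0,90]")
        emit(angle_histogram(ps, bin1), "tilt_hist.csv",
             paste0("tilt frequency, ", bin1, " deg bins, % of snapshots"))
      }
      if (!is.null(map$anchors$helix_a_bottom)) {
        cr <- crossing_angle_series(traj,
          resolve_anchor(traj, map, "helix_a_bottom"),
          resolve_anchor(traj, map, "helix_a_top"),
          resolve_anchor(traj, map, "helix_b_bottom"),
          resolve_anchor(traj, map, "helix_b_top"))
        emit(data.frame(time_ns = traj$time, crossing_deg = cr), "crossing.csv",
             "TM crossing angle phi, unfolded [0,180]")
        emit(angle_histogram(cr, bin1), "crossing_hist.csv",
             paste0("crossing frequency, ", bin1, " deg bins"))
      }
      if (!is.null(map$anchors$cys58)) {
        b3 <- stage_par("geometry", "bending_bin", 3)
        ba <- bending_angles(traj,
          resolve_anchor(traj, map, "cys58"), resolve_anchor(traj, map, "ser110"),
          resolve_anchor(traj, map, "his184"), resolve_anchor(traj, map, "thr126"),
          bin = b3)
        emit(data.frame(time_ns = traj$time, alpha_v = ba$alpha_v,
                        alpha_h = ba$alpha_h), "bending.csv",
             "receptor-head bending angles vs unit-cell z")
        emit(as.data.frame(ba$grid), "bending_grid.csv",
             paste0("2D (alpha_V, alpha_H) occupancy %, ", b3, " deg bins"))
      }
      if (!is.null(map$anchors$tyr8_oh)) {
        d <- atom_distance_series(traj, resolve_anchor(traj, map, "tyr8_oh"),
                                  resolve_anchor(traj, map, "tyr40_oh"))
        emit(data.frame(time_ns = traj$time, dist_A = d), "itim_distance.csv",
             "Tyr8-OH to Tyr40-OH distance")
      }
      if (!is.null(map$domains$NKG2A_ICD) && !is.null(map$domains$NKG2A_TMD)) {
        icd <- resolve_domains(traj, map, require_partition = FALSE)
        d <- com_distance_series(traj, icd$NKG2A_ICD, icd$NKG2A_TMD)
        emit(data.frame(time_ns = traj$time, dist_A = d), "icd_tmd_com.csv",
             "COM distance: NKG2A 1-45 vs TMD")
      }
    }, error = function(e) note("geometry", e))
    if (on_stage("membrane") && !is.null(map) && !is.null(map$lipids)) tryCatch({
      lip_sel <- select_atoms(traj, resname = map$lipids$resname)
      dprof <- electron_density(traj, lip_sel, bin = stage_par("membrane", "density_bin", 1))
      emit(as.data.frame(dprof), "electron_density.csv",
           sprintf("normalized (unit-max) electron density; thickness %.2f A",
                   thickness(dprof)))
      head_idx <- select_atoms(traj, name = map$lipids$head)
      if (length(head_idx)) {
        leaf <- assign_leaflets(get_frame(traj, 1), traj$top, head_idx)
        apl <- area_per_lipid(traj, sum(leaf == "upper"))
        emit(data.frame(time_ns = traj$time, apl_A2 = apl), "apl.csv",
             "area per lipid, upper leaflet")
      }
      scd <- order_parameters(traj, map)
      emit(as.data.frame(scd), "order_parameters.csv", "S_CD per acyl carbon")
    }, error = function(e) note("membrane", e))
    if (on_stage("interaction")) tryCatch({
      wat <- select_atoms(traj, resname = c("WAT", "HOH", "TIP3"), elem = "O")
      if (!is.null(map$anchors$tyr8_oh) && length(wat)) {
        rr <- rdf(traj, resolve_anchor(traj, map, "tyr8_oh"), wat,
                  bin = stage_par("interaction", "rdf_bin", 0.1),
                  r_max = stage_par("interaction", "rdf_rmax", 10))
        emit(as.data.frame(rr), "rdf_tyr8.csv", "water-O RDF around Tyr8 OH")
      }
      if (!is.null(map$anchors$asp106)) {
        prs <- persistence(traj, list(
          `Asp106-Lys135` = list(a = resolve_anchor(traj, map, "asp106"),
                                 b = resolve_anchor(traj, map, "lys135")),
          `Ser109-Lys135` = list(a = resolve_anchor(traj, map, "ser109"),
                                 b = resolve_anchor(traj, map, "lys135")),
          `Arg137-Asp149` = list(a = resolve_anchor(traj, map, "arg137"),
                                 b = resolve_anchor(traj, map, "asp149"))),
          cutoff = stage_par("interaction", "cutoff", 4))
        emit(prs, "persistence.csv", "mean distance (A) and % frames < cutoff")
      }
      if (any(traj$top$name == "N") && any(traj$top$name == "C")) {
        ss <- assign_secondary_structure(traj)
        emit(data.frame(ss$residues, helix_fraction = ss$helix_fraction),
             "helix_fraction.csv", "per-residue helix fraction (simplified DSSP)")
      }
    }, error = function(e) note("interaction", e))
  }, warning = function(wn) {
    warns <<- c(warns, conditionMessage(wn))
    invokeRestart("muffleWarning")
  })
  rep <- structure(list(manifest = manifest, warnings = warns, errors = errs,
                        wall_time = as.numeric(difftime(Sys.time(), t0,
                                                        units = "secs")),
                        config = config), class = "RunReport")
  log_path <- file.path(out_dir, "run_report.json")
  jsonlite::write_json(list(manifest = basename(manifest), warnings = warns,
                            errors = errs, wall_time_s = rep$wall_time,
                            package_version = as.character(utils::packageVersion("memsig"))),
                       log_path, auto_unbox = TRUE, digits = NA)
  rep$manifest <- c(rep$manifest, log_path)
  rep
}

#' @export
print.RunReport <- function(x, ...) {
  cat(sprintf("RunReport: %d output file(s), %d error(s), %.1f s\n",
              length(x$manifest), length(x$errors), x$wall_time))
  for (m in x$manifest) cat("  ", m, "\n")
  if (length(x$errors)) cat("errors:\n ", paste(x$errors, collapse = "\n  "), "\n")
  invisible(x)
}

#' Synthetic validation suite: prescribed vs recovered parameters
#'
#' Generates every fixture type (correlated ensemble, helix pair, membrane
#' slab, solvent, contact schedule, ideal backbones), runs the matching
#' analysis operation, and tabulates prescribed value, recovered value and
#' tolerance. Deterministic under a fixed seed.
#'
#' @param seed integer seed driving all generators
#' @param n_corr_frames ensemble size for the correlation fixture
#' @param out_dir optional directory for a CSV copy of the table
#' @return data.frame `observable`, `prescribed`, `recovered`, `tolerance`,
#'   `pass` (attribute `n` holds per-row problem sizes)
#' @export
run_synthetic_suite <- function(seed = 1, n_corr_frames = 10000,
                                out_dir = NULL) {
  seed <- as.integer(seed) %% 100000L
  row <- function(obs, presc, rec, tol, n)
    data.frame(observable = obs, prescribed = presc, recovered = rec,
               tolerance = tol, n = n, pass = abs(rec - presc) <= tol)
  out <- list()

  # correlation recovery
  Cn <- diag(6); Cn[1, 2] <- Cn[2, 1] <- 0.6; Cn[3, 4] <- Cn[4, 3] <- -0.4
  tr <- gen_correlated_trajectory(Cn, sigma = 1, n_frames = n_corr_frames,
                                  seed = seed)
  cc <- cross_correlation(tr, fit = "none")
  out$corr <- row("C12 (prescribed 0.6)", 0.6, cc$C[1, 2], 0.05, n_corr_frames)
  out$corr_max <- row("max |C - target|", 0,
                      max(abs(cc$C - Cn)), 0.05, n_corr_frames)

  # angle recovery
  hp0 <- gen_helix_pair(tilt = 45, crossing = 35, noise_sd = 0, n_frames = 5,
                        seed = seed)
  t0v <- tilt_angle_series(hp0$traj, resolve_anchor(hp0$traj, hp0$map, "helix_a_bottom"),
                           resolve_anchor(hp0$traj, hp0$map, "helix_a_top"))
  c0v <- crossing_angle_series(hp0$traj,
    resolve_anchor(hp0$traj, hp0$map, "helix_a_bottom"),
    resolve_anchor(hp0$traj, hp0$map, "helix_a_top"),
    resolve_anchor(hp0$traj, hp0$map, "helix_b_bottom"),
    resolve_anchor(hp0$traj, hp0$map, "helix_b_top"))
  out$tilt0 <- row("tilt psi, no noise", 45, mean(t0v), 1e-6, 5)
  out$cross0 <- row("crossing phi, no noise", 35, mean(c0v), 1e-6, 5)
  hp <- gen_helix_pair(tilt = 45, crossing = 35, noise_sd = 5, n_frames = 5000,
                       seed = seed + 1L)
  tv <- tilt_angle_series(hp$traj, resolve_anchor(hp$traj, hp$map, "helix_a_bottom"),
                          resolve_anchor(hp$traj, hp$map, "helix_a_top"))
  out$tilt_n <- row("tilt psi, 5 deg jitter", 45, mean(tv), 0.3, 5000)

  # membrane recovery
  for (dd in c(30, 37)) {
    slab <- gen_membrane_slab(d = dd, n_leaflet = 49, box_xy = 70,
                              scd = -0.2, n_frames = 20, seed = seed + dd)
    prof <- electron_density(slab$traj,
                             select_atoms(slab$traj, resname = "LIP"), bin = 1)
    out[[paste0("thick", dd)]] <- row(sprintf("thickness, d = %d A", dd), dd,
                                      thickness(prof), 1, 20)
    if (dd == 30) {
      scd <- order_parameters(slab$traj, slab$map)
      out$scd <- row("S_CD (prescribed -0.2)", -0.2, mean(scd$scd), 0.01,
                     sum(scd$n_samples))
    }
  }
  # study-scale leaflet arithmetic: 120 x 120 A^2, 225 lipids per leaflet
  slab_apl <- gen_membrane_slab(d = 30, n_leaflet = 225, box_xy = 120,
                                chain_len = 2, n_frames = 2, seed = seed + 6L)
  leaf <- assign_leaflets(get_frame(slab_apl$traj, 1), slab_apl$traj$top,
                          select_atoms(slab_apl$traj, name = "BD"))
  out$apl <- row("area per lipid (120x120/225)", 64,
                 area_per_lipid(slab_apl$traj, sum(leaf == "upper"))[1],
                 1e-9, 225)

  # RDF on the ideal-gas fixture
  solv <- gen_solvent("uniform", box = c(30, 30, 30), density = 0.02,
                      n_frames = 40, seed = seed + 2L)
  rr <- rdf(solv, probe = 1L, solvent = seq_len(n_atoms(solv)), bin = 0.25,
            r_max = 10)
  plateau <- mean(rr$g[rr$r > 2])
  out$rdf <- row("uniform-solvent g(r) plateau", 1, plateau, 0.05,
                 n_atoms(solv) * 40)

  # persistence schedule
  sch <- gen_contact_schedule(0.5, n_frames = 1000, seed = seed + 3L)
  pt <- persistence(sch, list(ab = list(a = 1L, b = 2L)), cutoff = 4)
  out$pers <- row("contact persistence (occupancy 0.5)", 50, pt$persistence,
                  1e-9, 1000)

  # PCA two-mode fixture: independent modes with variances 4 and 1
  tr2 <- gen_mode_trajectory(variances = c(4, 1), n_frames = n_corr_frames,
                             seed = seed + 4L)
  pc <- suppressWarnings(pca_dynamics(tr2, fit = "none"))
  out$pca <- row("PC1 variance fraction (4:1 modes)", 0.8, pc$var_frac[1],
                 0.01, n_corr_frames)

  # clustering on two separated conformations
  grp <- gen_two_state_trajectory(separation = 20, n_frames = 20,
                                  seed = seed + 5L)
  cl <- cluster_conformations(grp, epsilon = 7)
  out$clust <- row("clusters at 20 A split, epsilon 7", 2, cl$n_clusters, 0, 20)

  # secondary structure
  hel <- gen_ideal_chain(12, phi = -57, psi = -47)
  ss <- assign_secondary_structure(hel)
  out$helix <- row("interior helix fraction (ideal alpha)", 1,
                   mean(ss$helix_fraction[3:10]), 0, 12)
  ext <- gen_ideal_chain(12, phi = -140, psi = 135)
  ss2 <- assign_secondary_structure(ext)
  out$coil <- row("helix+strand content (extended chain)", 0,
                  mean(ss2$states != "C"), 0, 12)

  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    .write_csv(tab, file.path(out_dir, "recovery_table.csv"),
               paste0("synthetic recovery suite, seed ", seed))
  }
  tab
}

#' Two-conformation trajectory for clustering checks
#'
#' Frames split (first half / second half) between two conformations of a
#' random 10-atom backbone-labelled structure whose post-superposition RMSD
#' is exactly `separation`: the second state is a homothety (uniform
#' expansion about the centroid), which no rigid-body fit can reduce. Small
#' jitter keeps frames distinct.
#'
#' @param separation post-fit RMSD between the two states (A)
#' @param n_frames total frames (half per state); @param seed RNG seed
#' @export
gen_two_state_trajectory <- function(separation = 20, n_frames = 20, seed = 1) {
  n <- 10L
  .with_seed(seed, {
    base <- matrix(stats::runif(n * 3, 0, 20), n, 3)
    cen <- colMeans(base)
    Xc <- sweep(base, 2, cen)
    rmsq <- sqrt(mean(rowSums(Xc^2)))
    state2 <- sweep(Xc * (1 + separation / rmsq), 2, cen, "+")
    coords <- array(0, c(n, 3, n_frames))
    half <- n_frames %/% 2
    for (f in seq_len(n_frames)) {
      ref <- if (f <= half) base else state2
      coords[, , f] <- ref + matrix(stats::rnorm(n * 3, 0, 0.05), n, 3)
    }
    top <- topology(name = rep("CA", n), resname = rep("ALA", n),
                    chain = rep("A", n), resno = seq_len(n), elem = rep("C", n))
    trajectory(top, coords, box = c(100, 100, 100))
  })
}

#' Independent-mode displacement ensemble
#'
#' One atom per mode: atom i is displaced along x with variance
#' `variances[i]` (y/z frozen), giving a coordinate covariance whose
#' eigenvalues are exactly the prescribed variances — the closed-form
#' oracle for essential-dynamics variance fractions.
#'
#' @param variances per-mode variances (A^2); @param n_frames frames
#' @param seed RNG seed
#' @export
gen_mode_trajectory <- function(variances = c(4, 1), n_frames = 1000,
                                seed = 1) {
  n <- length(variances)
  base <- cbind((seq_len(n) - 1) * 10, 0, 0)
  coords <- .with_seed(seed, {
    arr <- array(0, c(n, 3, n_frames))
    for (i in seq_len(n))
      arr[i, 1, ] <- base[i, 1] + stats::rnorm(n_frames, 0, sqrt(variances[i]))
    for (k in 2:3) arr[, k, ] <- base[, k]
    arr
  })
  top <- topology(name = rep("CA", n), resname = rep("ALA", n),
                  chain = rep("A", n), resno = seq_len(n), elem = rep("C", n))
  trajectory(top, coords, box = c(1000, 1000, 1000))
}
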