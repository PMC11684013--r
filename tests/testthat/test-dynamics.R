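# RMSD/RMSF, cross-correlation + simplified matrices, PCA, clustering.

make_traj <- function(coords, masses = NULL, names = NULL) {
  n <- dim(coords)[1]
  top <- topology(name = names %||% rep("CA", n), resname = rep("ALA", n),
                  chain = rep("A", n), resno = seq_len(n))
  if (!is.null(masses)) top$mass <- masses
  trajectory(top, coords)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("rmsd_series matches closed forms and the Kabsch cross-check", {
  base <- matrix(c(0, 0, 0, 5, 0, 0, 0, 5, 0), 3, 3, byrow = TRUE)
  const <- make_traj(array(rep(base, 4), c(3, 3, 4)))
  expect_equal(rmsd_series(const), rep(0, 4), tolerance = 1e-10)

  # one atom displaced 3 A in a 3-atom frame, no fit: sqrt(9/3)
  moved <- base; moved[1, 1] <- moved[1, 1] + 3
  tr <- make_traj(array(c(base, moved), c(3, 3, 2)))
  expect_equal(rmsd_series(tr, fit = FALSE)[2], sqrt(3), tolerance = 1e-12)

  # random ensemble: per-frame fitted RMSD equals bio3d's Kabsch fit
  set.seed(12)
  n <- 8; nf <- 5
  ref <- matrix(runif(n * 3, 0, 15), n, 3)
  arr <- array(rep(ref, nf), c(n, 3, nf)) + array(rnorm(n * 3 * nf), c(n, 3, nf))
  tr2 <- make_traj(arr)
  ours <- rmsd_series(tr2, reference = ref)
  for (f in seq_len(nf)) {
    fit <- bio3d::fit.xyz(as.vector(t(ref)), as.vector(t(arr[, , f])),
                          fixed.inds = 1:(3 * n), mobile.inds = 1:(3 * n))
    theirs <- sqrt(mean(colSums((matrix(fit, 3) - t(ref))^2)))
    expect_equal(ours[f], theirs, tolerance = 1e-6)
  }
})

test_that("rmsf recovers isotropic jitter and the B-factor formula", {
  n <- 5; nf <- 3000; sigma <- 0.8
  set.seed(3)
  base <- matrix(runif(n * 3, 0, 30), n, 3)
  arr <- array(rep(base, nf), c(n, 3, nf)) +
    array(rnorm(n * 3 * nf, 0, sigma), c(n, 3, nf))
  tr <- make_traj(arr)
  r <- rmsf(tr, fit = "none")
  expect_equal(r$rmsf, rep(sigma * sqrt(3), n), tolerance = 0.05)
  # B-factor of RMSF = 1 A is 8 pi^2 / 3 = 26.32 A^2; column obeys the formula
  expect_equal(8 * pi^2 / 3, 26.31894, tolerance = 1e-5)
  expect_equal(r$bfactor, 8 * pi^2 / 3 * r$rmsf^2, tolerance = 1e-12)

  frozen <- make_traj(array(rep(base, 4), c(n, 3, 4)))
  expect_equal(rmsf(frozen, fit = "none")$rmsf, rep(0, n), tolerance = 1e-10)
  expect_error(rmsf(make_traj(array(base, c(n, 3, 1)))), "two frames")
})

test_that("cross-correlation obeys exact limits and rigid-motion invariance", {
  # mirrored displacements -> -1; self -> +1
  nf <- 60
  z <- rnorm(nf)
  arr <- array(0, c(2, 3, nf))
  arr[1, 1, ] <- z; arr[2, 1, ] <- -z
  arr[1, 2, ] <- 0; arr[2, 2, ] <- 10
  tr <- make_traj(arr)
  cc <- cross_correlation(tr, fit = "none")
  expect_equal(diag(cc$C), c(1, 1), ignore_attr = TRUE)
  expect_equal(cc$C[1, 2], -1, tolerance = 1e-12)

  # invariance: adding a global rigid motion per frame does not change C
  C <- diag(4); C[1, 3] <- C[3, 1] <- 0.5
  tr2 <- gen_correlated_trajectory(C, n_frames = 400, seed = 5)
  cc_plain <- cross_correlation(tr2, fit = "average")
  tr3 <- tr2
  for (f in seq_len(n_frames(tr2))) {
    rig <- random_rigid(f)
    tr3$coords[, , f] <- apply_rigid(tr2$coords[, , f], rig)
  }
  cc_moved <- cross_correlation(tr3, fit = "average")
  expect_equal(cc_moved$C, cc_plain$C, tolerance = 1e-6)

  # zero-variance atom flagged NA with warning
  arr2 <- arr; arr2[2, , ] <- 3
  expect_warning(ccz <- cross_correlation(make_traj(arr2), fit = "none"),
                 "zero-variance")
  expect_true(all(is.na(ccz$C[2, ])))
})

test_that("simplified matrices equal brute-force block sums and densities", {
  # hand-built 4x4 correlation matrix
  Cm <- matrix(c(1, .5, .2, -.1,
                 .5, 1, .0, .3,
                 .2, .0, 1, -.4,
                 -.1, .3, -.4, 1), 4, 4, byrow = TRUE)
  atoms <- topology(rep("CA", 4), rep("ALA", 4), rep("A", 4), 1:4)
  cc <- structure(list(C = Cm, atoms = atoms, fit = "none"),
                  class = "CorrelationMatrix")
  map <- anchor_map(domains = list(d1 = list(chain = "A", resno = 1:2),
                                   d2 = list(chain = "A", resno = 3:4)))
  sm <- simplify_correlation(cc, map)
  # brute force over ordered pairs
  expect_equal(sm$cs["d1", "d2"], sum(Cm[1:2, 3:4]))
  expect_equal(sm$density["d1", "d2"], mean(Cm[1:2, 3:4]))
  expect_equal(sm$density["d1", "d1"], mean(Cm[1:2, 1:2]))
  # grand-sum invariant
  expect_equal(sum(sm$cs), sum(Cm))

  # constant matrix: every density equals the constant
  ccc <- cc; ccc$C[] <- 0.5
  smc <- simplify_correlation(ccc, map)
  expect_true(all(abs(smc$density - 0.5) < 1e-12))

  # singleton domains reproduce the underlying C_ij
  map1 <- anchor_map(domains = list(a = list(chain = "A", resno = 1),
                                    b = list(chain = "A", resno = 2),
                                    c = list(chain = "A", resno = 3),
                                    d = list(chain = "A", resno = 4)))
  sm1 <- simplify_correlation(cc, map1)
  expect_equal(unname(sm1$density), unname(Cm))

  bad <- anchor_map(domains = list(a = list(chain = "A", resno = 1:3)))
  expect_error(simplify_correlation(cc, bad), "cover")
})

test_that("PCA reports exact variance fractions and matches brute force", {
  # motion along one axis only
  tr1 <- gen_mode_trajectory(variances = 2, n_frames = 300, seed = 2)
  p1 <- suppressWarnings(pca_dynamics(tr1, fit = "none"))
  expect_equal(p1$var_frac[1], 1)

  # 4:1 modes -> 0.8 / 0.2
  tr2 <- gen_mode_trajectory(variances = c(4, 1), n_frames = 10000, seed = 3)
  p2 <- suppressWarnings(pca_dynamics(tr2, fit = "none"))
  expect_equal(p2$var_frac[1:2], c(0.8, 0.2), tolerance = 0.01)
  expect_true(all(diff(p2$cum_var) >= -1e-12))
  expect_equal(sum(p2$var_frac), 1, tolerance = 1e-9)

  # equal masses: eigenvalues match an unweighted brute-force eigen(cov)
  set.seed(6)
  arr <- array(rnorm(4 * 3 * 200), c(4, 3, 200)) * 2
  tr3 <- make_traj(arr, masses = rep(12.011, 4))
  p3 <- pca_dynamics(tr3, fit = "none")
  flat <- t(matrix(arr, 12, 200))
  ev <- eigen(cov(flat), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(p3$values / 12.011, ev, tolerance = 1e-9)
  expect_equal(p3$var_frac, ev / sum(ev), tolerance = 1e-9)

  # permutation invariance of variance fractions
  perm <- c(3, 1, 4, 2)
  tr4 <- make_traj(arr[perm, , ], masses = rep(12.011, 4))
  p4 <- pca_dynamics(tr4, fit = "none")
  expect_equal(p4$var_frac, p3$var_frac, tolerance = 1e-9)
})

test_that("clustering splits separated states and is monotone in epsilon", {
  tr <- gen_two_state_trajectory(separation = 20, n_frames = 16, seed = 4)
  cl <- cluster_conformations(tr, epsilon = 7)
  expect_equal(cl$n_clusters, 2)
  expect_equal(unname(cl$cluster[1:8]), rep(cl$cluster[[1]], 8))
  expect_true(all(cl$medoids %in% seq_len(16)))
  expect_equal(cl$cluster[cl$medoids[1]], unique(cl$cluster[1:8]),
               ignore_attr = TRUE)

  # identical frames -> one cluster; epsilon above max RMSD -> one cluster
  const <- gen_two_state_trajectory(separation = 0.0001, n_frames = 6, seed = 1)
  expect_equal(cluster_conformations(const, epsilon = 7)$n_clusters, 1)
  expect_equal(cluster_conformations(tr, epsilon = 1000)$n_clusters, 1)

  # cluster count never increases with epsilon
  eps <- c(0.05, 0.5, 2, 7, 15, 25, 100)
  ns <- vapply(eps, function(e)
    cluster_conformations(tr, epsilon = e)$n_clusters, 1L)
  expect_true(all(diff(ns) <= 0))
})
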