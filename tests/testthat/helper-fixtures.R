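# Shared fixture builders for the test suite. Everything is generated in
# code; no stored data files.

# minimal hand-rolled PDB text (fixed-width) for parser tests
toy_pdb_lines <- function(coords, names = c("N", "CA", "C"),
                          chain = "A", resno = 1, elem = NULL) {
  n <- nrow(coords)
  chain <- rep_len(chain, n); resno <- rep_len(resno, n)
  el <- if (is.null(elem)) rep("", n) else rep_len(elem, n)
  c(sprintf("ATOM  %5d  %-3s ALA %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            seq_len(n), names, chain, resno,
            coords[, 1], coords[, 2], coords[, 3], el),
    "END")
}

write_toy_pdb <- function(...) {
  f <- tempfile(fileext = ".pdb")
  writeLines(toy_pdb_lines(...), f)
  f
}

# random rigid motion (proper rotation + translation)
random_rigid <- function(seed = 1) {
  set.seed(seed)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  R <- matrix(c(
    1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]), 2 * (q[2] * q[4] + q[1] * q[3]),
    2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2), 2 * (q[3] * q[4] - q[1] * q[2]),
    2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]), 1 - 2 * (q[2]^2 + q[3]^2)),
    3, 3, byrow = TRUE)
  list(R = R, t = runif(3, -20, 20))
}

apply_rigid <- function(xyz, rig) sweep(xyz %*% t(rig$R), 2, rig$t, "+")

# brute-force minimum RMSD over rotations: random-quaternion search with
# Nelder-Mead polish on an axis-angle parameterisation (independent of the
# SVD path used by superpose)
brute_force_rmsd <- function(A, B, n_start = 400, seed = 99) {
  set.seed(seed)
  Ac <- sweep(A, 2, colMeans(A)); Bc <- sweep(B, 2, colMeans(B))
  rot <- function(p) {
    th <- sqrt(sum(p^2))
    if (th < 1e-12) return(diag(3))
    u <- p / th; c_ <- cos(th); s <- sin(th)
    ux <- u[1]; uy <- u[2]; uz <- u[3]
    matrix(c(c_ + ux^2 * (1 - c_), ux * uy * (1 - c_) - uz * s, ux * uz * (1 - c_) + uy * s,
             uy * ux * (1 - c_) + uz * s, c_ + uy^2 * (1 - c_), uy * uz * (1 - c_) - ux * s,
             uz * ux * (1 - c_) - uy * s, uz * uy * (1 - c_) + ux * s, c_ + uz^2 * (1 - c_)),
           3, 3, byrow = TRUE)
  }
  obj <- function(p) {
    d <- Ac %*% t(rot(p)) - Bc
    sqrt(mean(rowSums(d * d)))
  }
  best <- Inf
  for (i in seq_len(n_start)) {
    p0 <- runif(3, -pi, pi)
    o <- optim(p0, obj, method = "Nelder-Mead",
               control = list(maxit = 300, reltol = 1e-12))
    if (o$value < best) best <- o$value
  }
  best
}

# O(N^2) reference loops, written plainly and independently of pair_dist
loop_min_image_dist <- function(a, b, box) {
  d <- a - b
  for (k in 1:3) d[k] <- d[k] - box[k] * round(d[k] / box[k])
  sqrt(sum(d^2))
}

loop_contact_count <- function(A, B, box, cutoff) {
  cnt <- 0L
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B)))
    if (loop_min_image_dist(A[i, ], B[j, ], box) < cutoff) cnt <- cnt + 1L
  cnt
}
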