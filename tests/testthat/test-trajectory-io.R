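# Structure/trajectory reading, selection, superposition and windowing.

test_that("PDB structures round-trip atoms, coordinates, chains and cell", {
  xyz <- matrix(c(1.1, 2.2, 3.3,
                  4.4, 5.5, 6.6,
                  7.7, 8.8, 9.9), 3, 3, byrow = TRUE)
  f <- write_toy_pdb(xyz, elem = c("N", "C", "C"))
  tr <- read_structure(f)
  expect_equal(n_atoms(tr), 3)
  expect_equal(unname(tr$coords[, , 1]), xyz)
  expect_equal(tr$top$name, c("N", "CA", "C"))

  # two chains preserved
  f2 <- write_toy_pdb(xyz, chain = c("A", "A", "B"), resno = c(1, 1, 1),
                      elem = c("N", "C", "C"))
  tr2 <- read_structure(f2)
  expect_equal(tr2$top$chain, c("A", "A", "B"))

  # full write -> read round-trip at 3-decimal precision, including CRYST1
  hp <- gen_helix_pair(n_frames = 3, noise_sd = 2, seed = 7)
  out <- tempfile(fileext = ".pdb")
  write_pdb(hp$traj, out)
  back <- read_structure(out)
  expect_equal(n_frames(back), 3)
  expect_equal(back$coords, round(hp$traj$coords, 3), tolerance = 1e-12)
  expect_equal(back$box[1, ], hp$traj$box[1, ])
  expect_identical(back$top$chain, hp$traj$top$chain)
  expect_identical(back$top$resno, hp$traj$top$resno)
})

test_that("elements are inferred from atom names when the column is absent", {
  xyz <- matrix(rnorm(12), 4, 3)
  f <- write_toy_pdb(xyz, names = c("OG", "CA", "1HB", "NZ"))
  expect_warning(tr <- read_structure(f), "inferring elements")
  # hand-built expectation table
  expect_equal(tr$top$elem, c("O", "C", "H", "N"))
  expect_equal(tr$top$atomno, c(8L, 6L, 1L, 7L))
})

test_that("malformed PDB records raise a parse error naming the line", {
  lines <- toy_pdb_lines(matrix(0, 2, 3), names = c("N", "CA"))
  lines[2] <- paste0(substr(lines[2], 1, 30), "   xx.bad", substr(lines[2], 40, 80))
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  expect_error(read_structure(f), "line 2")
})

test_that("DCD files written by the package are read back by an independent reader", {
  hp <- gen_helix_pair(n_frames = 4, noise_sd = 3, seed = 11)
  f <- tempfile(fileext = ".dcd")
  write_dcd(hp$traj, f)
  # bio3d's DCD reader is the independent cross-check of the writer
  xyz <- bio3d::read.dcd(f, verbose = FALSE)
  expect_equal(nrow(xyz), 4)
  expect_equal(ncol(xyz), 3 * n_atoms(hp$traj))
  got <- matrix(xyz[2, ], ncol = 3, byrow = TRUE)
  expect_equal(got, unname(hp$traj$coords[, , 2]), tolerance = 1e-5)
  # and the package's own reader recovers coordinates + cell
  tr <- read_dcd(f, hp$traj$top)
  expect_equal(tr$coords, hp$traj$coords, tolerance = 1e-5)
  expect_equal(tr$box[1, ], hp$traj$box[1, ])
  expect_error(read_dcd(f, hp$traj$top[1:3, ]), "atoms")
})

test_that("superposition removes rigid motion and matches a brute-force oracle", {
  set.seed(4)
  A <- matrix(runif(12, 0, 10), 4, 3)
  # identity fit
  expect_equal(superpose(A, A)$rmsd, 0, tolerance = 1e-10)
  # rigid 90-degree rotation about z plus translation is fully removable
  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  moved <- sweep(A %*% t(Rz), 2, c(5, -3, 2), "+")
  expect_equal(superpose(moved, A)$rmsd, 0, tolerance = 1e-10)
  # two distinct 4-point sets: SVD result equals brute-force minimisation
  B <- A + matrix(rnorm(12, 0, 1.5), 4, 3)
  expect_equal(superpose(A, B)$rmsd, brute_force_rmsd(A, B), tolerance = 1e-6)
})

test_that("superposition is idempotent and RMSD is invariant to pre-transforms", {
  set.seed(5)
  A <- matrix(runif(30, 0, 15), 10, 3)
  B <- A + matrix(rnorm(30, 0, 1), 10, 3)
  s1 <- superpose(A, B)
  s2 <- superpose(s1$frame, B)
  expect_lt(max(abs(s2$frame - s1$frame)), 1e-9)
  for (sd in 1:3) {
    rig <- random_rigid(sd)
    expect_equal(superpose(apply_rigid(A, rig), B)$rmsd, s1$rmsd,
                 tolerance = 1e-9)
  }
  expect_error(superpose(A, B, selection = integer(0)), "empty")
  expect_error(superpose(A, B[1:5, ], selection = 1:10), "atom count|sizes")
})

test_that("average_structure converges to the mean and recovers noisy copies", {
  hp <- gen_helix_pair(n_frames = 1, seed = 2)
  tr <- hp$traj
  const <- trajectory(tr$top, array(rep(tr$coords[, , 1], 4),
                                    c(n_atoms(tr), 3, 4)), box = tr$box[1, ])
  avg <- average_structure(const)
  expect_equal(avg$coords, const$coords[, , 1], tolerance = 1e-9)

  # two pre-aligned frames symmetric about a midpoint -> the midpoint
  # (displacement is a pure breathing mode, so no rotation can absorb it)
  base <- matrix(runif(30, 0, 10), 10, 3)
  d <- 0.02 * sweep(base, 2, colMeans(base))
  two <- trajectory(topology(rep("CA", 10), rep("ALA", 10), rep("A", 10), 1:10),
                    array(c(base + d, base - d), c(10, 3, 2)))
  expect_equal(average_structure(two)$coords, base, tolerance = 1e-6)

  # 100 noisy copies recover the structure within ~sigma/sqrt(100)
  set.seed(8)
  sigma <- 0.5
  noisy <- array(rep(base, 100), c(10, 3, 100)) +
    array(rnorm(3000, 0, sigma), c(10, 3, 100))
  ntr <- trajectory(two$top, noisy)
  rec <- average_structure(ntr)
  err <- sqrt(mean((superpose(rec$coords, base)$frame - base)^2))
  expect_lt(err, 5 * sigma / sqrt(100))
})

test_that("frame windows drop the equilibration span, stride and align", {
  n <- 40
  top <- topology(rep("CA", 2), rep("ALA", 2), rep("A", 2), 1:2)
  coords <- array(rnorm(2 * 3 * n), c(2, 3, n))
  tr <- trajectory(top, coords, time = seq_len(n) - 1)
  w <- apply_window(tr, frame_window(offset_ns = 10))
  expect_equal(n_frames(w), 30)
  expect_true(all(w$time >= 10))
  w2 <- apply_window(tr, frame_window(stride = 2))
  expect_equal(n_frames(w2), 20)
  expect_error(apply_window(tr, frame_window(offset_ns = n + 1)), "every frame")
  # alignment to the first kept frame zeroes its RMSD
  w3 <- apply_window(tr, frame_window(offset_ns = 5, align = "start"))
  expect_equal(rmsd_series(w3, fit = FALSE)[1], 0, tolerance = 1e-10)
})
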