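# RDFs, contacts, persistence, hydrogen bonds, secondary structure.

test_that("RDF is flat for an ideal gas and localized for a shell", {
  u <- gen_solvent("uniform", box = c(30, 30, 30), density = 0.03,
                   n_frames = 30, seed = 1)
  rr <- rdf(u, probe = 1L, solvent = seq_len(n_atoms(u)), bin = 0.5,
            r_max = 10)
  far <- rr$r > 2
  # per-bin 3-sigma bound from Poisson counts
  rho <- attr(rr, "rho")
  vol <- 4 / 3 * pi * ((rr$r + 0.25)^3 - (rr$r - 0.25)^3)
  sigma_bin <- 1 / sqrt(rho * vol * 30)
  expect_true(all(abs(rr$g[far] - 1) < 3 * sigma_bin[far] + 0.05))

  sh <- gen_solvent("shell", box = c(30, 30, 30), n_shell = 12, r0 = 4,
                    n_frames = 5, seed = 2)
  rs <- rdf(sh, probe = 1L, solvent = 2:n_atoms(sh), bin = 0.5, r_max = 10)
  expect_equal(rs$r[which.max(rs$g)], 4.25, tolerance = 0.5)

  expect_error(rdf(u, 1L, seq_len(n_atoms(u)), r_max = 16), "half the smallest")
  expect_error(rdf(u, integer(0), 1:5), "empty probe")
})

test_that("RDF bin counts equal exhaustive enumeration and integrate to the
           coordination number", {
  u <- gen_solvent("uniform", box = c(16, 16, 16), density = 0.05,
                   n_frames = 3, seed = 3)
  n <- n_atoms(u)
  rr <- rdf(u, probe = 1L, solvent = seq_len(n), bin = 0.5, r_max = 7)
  # O(N^2) oracle: count pairs per bin by plain loops
  counts <- numeric(length(rr$r))
  for (f in 1:3) {
    for (j in seq_len(n)[-1]) {
      dij <- loop_min_image_dist(u$coords[1, , f], u$coords[j, , f],
                                 u$box[f, ])
      if (dij < 7) {
        b <- floor(dij / 0.5) + 1
        counts[b] <- counts[b] + 1
      }
    }
  }
  rho <- attr(rr, "rho")
  vol <- 4 / 3 * pi * ((rr$r + 0.25)^3 - (rr$r - 0.25)^3)
  expect_equal(rr$g, counts / 3 / (rho * vol), tolerance = 1e-12)
  # coordination-number integral: sum(rho g 4 pi r^2 dr) = direct mean count
  integral <- sum(rho * rr$g * 4 * pi * rr$r^2 * 0.5)
  direct <- attr(rr, "coordination")
  expect_equal(integral, direct, tolerance = 0.01 * direct)
})

test_that("contact counts match brute-force enumeration and boundary rules", {
  # two groups 10 A apart -> 0; pair at 3.9 A -> 1
  top <- topology(rep("CA", 4), rep("ALA", 4), c("A", "A", "B", "B"),
                  c(1, 2, 1, 2))
  xyz <- rbind(c(0, 0, 0), c(0, 3, 0), c(10, 0, 0), c(3.9, 0, 0))
  tr <- trajectory(top, xyz, box = c(60, 60, 60))
  expect_equal(contact_count_series(tr, 1:2, 3, cutoff = 4), 0L)
  expect_equal(contact_count_series(tr, 1, 4, cutoff = 4), 1L)

  # random configurations: equality with the O(N^2) loop oracle
  set.seed(4)
  n <- 40
  topn <- topology(rep("CA", n), rep("ALA", n), rep("A", n), seq_len(n))
  for (rep_i in 1:3) {
    xyzn <- matrix(runif(n * 3, 0, 25), n, 3)
    trn <- trajectory(topn, xyzn, box = c(25, 25, 25))
    got <- contact_count_series(trn, 1:20, 21:40, cutoff = 4)
    want <- loop_contact_count(xyzn[1:20, ], xyzn[21:40, ], c(25, 25, 25), 4)
    expect_equal(got, want)
  }

  # overlapping groups: self-pairs excluded with a warning
  expect_warning(cc <- contact_count_series(tr, 1:2, 2:3, cutoff = 4),
                 "self-pairs")
  expect_equal(cc, 1L)   # only the 1-2 contact at 3 A remains
})

test_that("persistence reproduces occupancy schedules and distance means", {
  sch <- gen_contact_schedule(0.37, n_frames = 100, seed = 5)
  pt <- persistence(sch, list(ab = list(a = 1L, b = 2L)), cutoff = 4)
  expect_equal(pt$persistence, 37)
  sch2 <- gen_contact_schedule(0.5, n_frames = 1000, seed = 6)
  expect_equal(persistence(sch2, list(ab = list(a = 1L, b = 2L)))$persistence,
               50)
  # never in contact: 0 % and mean distance equals the mean separation
  sch0 <- gen_contact_schedule(0, n_frames = 50, seed = 7, r_out = 9)
  pt0 <- persistence(sch0, list(ab = list(a = 1L, b = 2L)))
  expect_equal(pt0$persistence, 0)
  expect_equal(pt0$mean_dist, 9)
})

test_that("hydrogen bonds need both the distance and the angle criterion", {
  # linear O-H...O at 2.8 A donor-acceptor
  top <- topology(c("OG", "HG", "OG1"), c("SER", "SER", "THR"),
                  c("B", "B", "A"), c(34, 34, 96), elem = c("O", "H", "O"))
  lin <- rbind(c(0, 0, 0), c(0.96, 0, 0), c(2.8, 0, 0))
  tr <- trajectory(top, lin, box = c(50, 50, 50))
  hb <- hbond_series(tr, donor = 1, acceptor = 3, hydrogen = 2)
  expect_true(hb$present[1])
  expect_equal(hb$occupancy, 100)

  # same distance but 90-degree donor-H-acceptor angle: rejected
  bent <- rbind(c(0, 0, 0), c(0.96, 0, 0), c(0.96, 2.63, 0))
  trb <- trajectory(top, bent, box = c(50, 50, 50))
  expect_equal(hbond_series(trb, 1, 3, 2)$occupancy, 0)

  # missing hydrogen falls back to distance-only with a warning
  expect_warning(hb2 <- hbond_series(trb, 1, 3, NULL), "distance-only")
  expect_equal(hb2$occupancy, 100)

  # jittered series equals per-frame brute-force evaluation
  set.seed(8)
  frames <- lapply(1:40, function(i) lin + matrix(rnorm(9, 0, 0.25), 3, 3))
  arr <- array(unlist(frames), c(3, 3, 40))
  trj <- trajectory(top, arr, box = c(50, 50, 50))
  hbj <- hbond_series(trj, 1, 3, 2)
  brute <- vapply(frames, function(m) {
    dda <- sqrt(sum((m[3, ] - m[1, ])^2))
    v1 <- m[1, ] - m[2, ]; v2 <- m[3, ] - m[2, ]
    ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
    dda <= 3.5 && ang >= 120
  }, TRUE)
  expect_identical(hbj$present, brute)
  expect_equal(hbj$occupancy, 100 * mean(brute))
})

test_that("secondary structure separates ideal helices from extended chains", {
  hel <- gen_ideal_chain(14, phi = -57, psi = -47)
  ss <- assign_secondary_structure(hel)
  # interior residues are helical; termini may be coil
  expect_true(all(ss$states[4:11, 1] == "H"))
  expect_equal(mean(ss$helix_fraction[4:11]), 1)

  ext <- gen_ideal_chain(14, phi = -140, psi = 135)
  ss2 <- assign_secondary_structure(ext)
  expect_true(all(ss2$states == "C"))

  # all-H series has helix fraction one
  expect_true(all(ss$helix_fraction[ss$states[, 1] == "H"] == 1))

  # invariance to rigid-body motion of every frame
  rig <- random_rigid(13)
  mov <- hel
  mov$coords[, , 1] <- apply_rigid(hel$coords[, , 1], rig)
  ss3 <- assign_secondary_structure(mov)
  expect_identical(ss3$states, ss$states)
})
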