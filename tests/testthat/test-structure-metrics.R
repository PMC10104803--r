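helix <- generate(synthetic_spec("structure_fixture",
                                 design = list(n_res = 20)))$data

test_that("PDB parsing retains coordinates and resolves altlocs", {
  pdb_lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00 20.00           N",
    "ATOM      2  CA  ALA A   1       1.500   0.000   0.000  1.00 22.00           C",
    "ATOM      3  CA BALA A   2       0.000   3.000   4.000  0.40 30.00           C",
    "ATOM      4  CA CALA A   2       0.100   3.000   4.000  0.60 31.00           C",
    "END")
  tf <- tempfile(fileext = ".pdb")
  writeLines(pdb_lines, tf)
  m <- read_structure(tf)
  expect_equal(nrow(m), 3L)  # one altloc survives
  kept <- m[m$resno == 2, ]
  expect_equal(kept$occ, 0.6)
  expect_equal(kept$x, 0.1)
  expect_equal(m$x[m$atom == "CA" & m$resno == 1], 1.5)

  empty <- tempfile(fileext = ".pdb")
  writeLines("END", empty)
  expect_error(read_structure(empty), "no ATOM records")
})

test_that("PDB and mmCIF renderings of one model parse identically", {
  pp <- tempfile(fileext = ".pdb"); write_structure_pdb(helix, pp)
  pc <- tempfile(fileext = ".cif"); write_structure_cif(helix, pc)
  mp <- read_structure(pp)
  mc <- read_structure(pc)
  expect_equal(nrow(mp), nrow(mc))
  for (col in c("chain", "resno", "atom", "x", "y", "z", "b")) {
    expect_equal(mp[[col]], mc[[col]])
  }
})

test_that("atom distances are exact, symmetric and rigid-invariant", {
  m <- helix[1:2, ]
  m$chain <- "A"; m$resno <- 1:2; m$atom <- "CA"
  m$x <- c(0, 3); m$y <- c(0, 4); m$z <- 0
  expect_equal(atom_distance(m, "A:1:CA", "A:2:CA"), 5)
  expect_equal(atom_distance(m, "A:2:CA", "A:1:CA"), 5)
  expect_equal(atom_distance(m, "A:1:CA", "A:1:CA"), 0)
  mt <- rigid_transform(m)
  expect_equal(atom_distance(mt, "A:1:CA", "A:2:CA"), 5, tolerance = 1e-9)
  expect_error(atom_distance(m, "A:9:CA", "A:1:CA"), "resolves to 0")
})

test_that("C-alpha RMSD is zero under rigid transforms and symmetric", {
  expect_lt(calpha_rmsd(helix, helix, "A")$rmsd, 1e-12)
  moved <- rigid_transform(helix)
  r <- calpha_rmsd(helix, moved, "A")
  expect_lt(r$rmsd, 1e-9)
  expect_equal(r$n_matched, 20L)

  # perturbed copy: symmetric and cross-checked against bio3d's fitter
  set.seed(3)
  pert <- moved
  pert$x <- pert$x + rnorm(nrow(pert), 0, 0.3)
  pert$y <- pert$y + rnorm(nrow(pert), 0, 0.3)
  pert$z <- pert$z + rnorm(nrow(pert), 0, 0.3)
  r_ab <- calpha_rmsd(helix, pert, "A")$rmsd
  r_ba <- calpha_rmsd(pert, helix, "A")$rmsd
  expect_lt(abs(r_ab - r_ba), 1e-9)

  ca_a <- helix[helix$atom == "CA", ]
  ca_b <- pert[pert$atom == "CA", ]
  xyz_a <- as.vector(t(as.matrix(ca_a[, c("x", "y", "z")])))
  xyz_b <- as.vector(t(as.matrix(ca_b[, c("x", "y", "z")])))
  fitted <- bio3d::fit.xyz(xyz_a, xyz_b,
                           fixed.inds = seq_along(xyz_a),
                           mobile.inds = seq_along(xyz_b))
  ref_rmsd <- sqrt(mean(colSums(matrix((fitted - xyz_a)^2, nrow = 3))))
  expect_equal(r_ab, ref_rmsd, tolerance = 1e-6)

  expect_error(calpha_rmsd(helix, helix, "A", resno_range = c(1, 2)),
               "fewer than 3")
})

test_that("normalized B-factors divide by the selection-wide mean", {
  uniform <- helix; uniform$b <- 30
  pu <- normalized_bfactors(uniform, "A")
  expect_true(all(abs(pu$normalized_b - 1) < 1e-12))

  # scale invariance
  doubled <- helix; doubled$b <- helix$b * 2
  expect_equal(normalized_bfactors(doubled, "A")$normalized_b,
               normalized_bfactors(helix, "A")$normalized_b,
               tolerance = 1e-12)

  # two residues, equal atom counts, b = 20 and 40 -> 2/3 and 4/3
  two <- helix[helix$resno %in% 1:2, ]
  two$b <- ifelse(two$resno == 1, 20, 40)
  p2 <- normalized_bfactors(two, "A")
  expect_equal(p2$normalized_b, c(2 / 3, 4 / 3), tolerance = 1e-12)

  # atom-count-weighted mean of normalized values is exactly 1
  pr <- normalized_bfactors(helix, "A")
  expect_equal(sum(pr$normalized_b * pr$n_atoms) / sum(pr$n_atoms), 1,
               tolerance = 1e-9)
  expect_equal(attr(pr, "overall_b"), mean(helix$b[!helix$is_h]))

  zero <- helix; zero$b <- 0
  expect_error(normalized_bfactors(zero, "A"), "zero")
})

test_that("B-factor deltas classify stabilization sign per residue", {
  pr <- normalized_bfactors(helix, "A")
  self <- bfactor_delta(pr, pr)
  expect_true(all(self$delta == 0))
  expect_true(all(self$classification == "equal"))

  # uniformly flexible baseline vs 10% stiffer comparison profile
  flat <- helix; flat$b <- 30
  pa <- normalized_bfactors(flat, "A")
  pb <- pa; pb$normalized_b <- pa$normalized_b * 1.1
  d <- bfactor_delta(pa, pb)
  expect_true(all(abs(d$delta - (-0.1)) < 1e-12))
  expect_true(all(d$classification == "lower"))

  other <- pr; other$resno <- other$resno + 1000
  expect_error(bfactor_delta(pr, other), "no residues")
})

test_that("torsion angles follow the IUPAC convention and its symmetries", {
  base <- helix[1:4, ]
  base$chain <- "Z"; base$resno <- 1:4; base$atom <- "CA"
  cis <- base; cis$x <- c(0, 1, 2, 3); cis$y <- c(1, 0, 0, 1); cis$z <- 0
  expect_equal(dihedral(cis, "Z:1:CA", "Z:2:CA", "Z:3:CA", "Z:4:CA"), 0)

  trans <- cis; trans$y <- c(1, 0, 0, -1)
  expect_equal(dihedral(trans, "Z:1:CA", "Z:2:CA", "Z:3:CA", "Z:4:CA"), 180)

  skew <- cis; skew$z <- c(0.5, 0, 0, 0.8)
  ang <- dihedral(skew, "Z:1:CA", "Z:2:CA", "Z:3:CA", "Z:4:CA")
  mirror <- skew; mirror$z <- -mirror$z
  expect_equal(dihedral(mirror, "Z:1:CA", "Z:2:CA", "Z:3:CA", "Z:4:CA"),
               -ang, tolerance = 1e-9)
  moved <- rigid_transform(skew, angle = 1.1, axis = c(1, 2, 0.5))
  expect_equal(dihedral(moved, "Z:1:CA", "Z:2:CA", "Z:3:CA", "Z:4:CA"),
               ang, tolerance = 1e-9)

  line <- cis; line$y <- c(0, 0, 0, 1)  # first three collinear
  expect_error(dihedral(line, "Z:1:CA", "Z:2:CA", "Z:3:CA", "Z:4:CA"),
               "collinear")
  expect_error(dihedral(cis, "Z:1:CA", "Z:1:CA", "Z:3:CA", "Z:4:CA"),
               "distinct")
})
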