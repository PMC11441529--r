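# Structure/trajectory I/O and geometric primitives.

test_that("a hand-written PDB is read in file order with CRYST1 box", {
  pdb <- tempfile(fileext = ".pdb")
  writeLines(c(
    "CRYST1  100.000  100.000  100.000  90.00  90.00  90.00 P 1           1",
    "ATOM      1  N   ALA A   1      11.000  12.000  13.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      12.500  12.000  13.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1      14.000  12.000  13.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1      15.000  13.000  13.000  1.00  0.00           O",
    "ATOM      5  NZ  LYS B   2      20.000  20.000  20.000  1.00  0.00           N",
    "END"), pdb)
  tr <- read_structure(pdb, subunit_map = c(A = "I", B = "II"))
  expect_equal(n_atoms(tr), 5)
  expect_equal(tr$atoms$name, c("N", "CA", "C", "O", "NZ"))
  expect_equal(tr$box[1, ], c(100, 100, 100))
  expect_equal(get_frame(tr, 1)[1, ], c(x = 11, y = 12, z = 13))
  expect_setequal(unname(tr$subunit_map), c("I", "II"))
  # vdW radii assigned per element
  expect_equal(tr$atoms$vdw[1], bondi_radii()[["N"]])
})

test_that("triclinic cells and unknown elements are rejected", {
  pdb <- tempfile(fileext = ".pdb")
  writeLines(c(
    "CRYST1  100.000  100.000  100.000  90.00  99.00  90.00 P 1           1",
    "ATOM      1  N   ALA A   1      11.000  12.000  13.000  1.00  0.00           N",
    "END"), pdb)
  expect_error(read_structure(pdb), "triclinic")
  pdb2 <- tempfile(fileext = ".pdb")
  writeLines(c(
    "CRYST1  100.000  100.000  100.000  90.00  90.00  90.00 P 1           1",
    "ATOM      1 XX   UNK A   1      11.000  12.000  13.000  1.00  0.00          XX",
    "END"), pdb2)
  expect_error(read_structure(pdb2), "element")
})

test_that("structure write/read round trip preserves order, names and coords", {
  g <- fix_canonical()
  path <- tempfile(fileext = ".pdb")
  write_structure(g$traj, path, frame = 3)
  rt <- read_structure(path, subunit_map = g$traj$subunit_map)
  expect_equal(rt$atoms$name, g$traj$atoms$name)
  expect_equal(rt$atoms$resid, g$traj$atoms$resid)
  expect_equal(rt$atoms$chain, g$traj$atoms$chain)
  expect_lt(max(abs(get_frame(rt, 1) - get_frame(g$traj, 3))), 1e-3 + 1e-9)
})

test_that("DCD round trip preserves frames, times and displacements", {
  set.seed(1)
  frames <- lapply(1:10, function(f) matrix(runif(15, 10, 90), 5, 3))
  frames[[4]] <- frames[[1]]           # frame 4 repeats frame 1
  tr <- make_traj(frames, times = (0:9) * 0.5)
  dcd <- tempfile(fileext = ".dcd")
  write_dcd(tr, dcd)
  rt <- read_trajectory(tr, dcd)
  expect_equal(n_frames(rt), 10)
  expect_true(all(diff(rt$times) > 0))
  expect_equal(diff(rt$times)[1], 0.5, tolerance = 1e-6)
  expect_equal(get_frame(rt, 4), get_frame(rt, 1))
  # per-frame displacements survive the single-precision round trip
  d_orig <- get_frame(tr, 2) - get_frame(tr, 1)
  d_rt <- get_frame(rt, 2) - get_frame(rt, 1)
  expect_lt(max(abs(d_rt - d_orig)), 1e-4)
})

test_that("trajectory atom-count mismatch and XTC input are errors", {
  tr5 <- make_traj(matrix(runif(15, 10, 90), 5, 3))
  tr4 <- make_traj(matrix(runif(12, 10, 90), 4, 3))
  dcd <- tempfile(fileext = ".dcd")
  write_dcd(tr5, dcd)
  expect_error(read_trajectory(tr4, dcd), "mismatch")
  expect_error(read_trajectory(tr5, "whatever.xtc"), "XTC")
})

test_that("min_image_distance handles wrapping and matches the 27-image oracle", {
  expect_equal(min_image_distance(c(0, 0, 0), c(9, 0, 0), c(10, 10, 10)), 1)
  expect_equal(min_image_distance(c(3, 4, 5), c(3, 4, 5), c(10, 10, 10)), 0)
  set.seed(7)
  box <- c(30, 40, 25)
  a <- matrix(runif(3000), ncol = 3) * rep(box, each = 1000)
  b <- matrix(runif(3000), ncol = 3) * rep(box, each = 1000)
  got <- min_image_distance(a, b, box)
  want <- vapply(seq_len(nrow(a)), function(i)
    oracle_min_image(a[i, ], b[i, ], box), 0)
  expect_equal(got, want, tolerance = 1e-10)
  # never exceeds half the box diagonal
  expect_true(all(got <= sqrt(sum((box / 2)^2)) + 1e-12))
})

test_that("superpose_rmsd matches the quaternion oracle and is rigid-invariant", {
  expect_equal(superpose_rmsd(diag(3), diag(3))$rmsd, 0)
  m <- matrix(rnorm(30), 10, 3)
  shifted <- sweep(m, 2, c(5, 0, 0), "+")
  expect_equal(superpose_rmsd(shifted, m, fit = TRUE)$rmsd, 0, tolerance = 1e-12)
  expect_equal(superpose_rmsd(shifted, m, fit = FALSE)$rmsd, 5)
  set.seed(3)
  for (rep in 1:5) {
    ref <- matrix(rnorm(60), 20, 3)
    mob <- ref + matrix(rnorm(60, 0, 0.3), 20, 3)
    sp <- superpose_rmsd(mob, ref)
    expect_equal(sp$rmsd, oracle_quaternion_rmsd(mob, ref), tolerance = 1e-6)
    expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
    # invariance under an arbitrary rigid transform of the mobile set
    th <- runif(3, 0, 2 * pi)
    R <- matrix(c(cos(th[1]), -sin(th[1]), 0, sin(th[1]), cos(th[1]), 0,
                  0, 0, 1), 3, 3)
    mob2 <- sweep(mob %*% R, 2, c(3, -8, 2), "+")
    expect_equal(superpose_rmsd(mob2, ref)$rmsd, sp$rmsd, tolerance = 1e-9)
  }
  expect_error(superpose_rmsd(matrix(0, 2, 3), matrix(0, 2, 3)), "3 points")
})

test_that("identity and similarity percentages behave as defined", {
  self <- pairwise_align("MKTAYIAKQR", "MKTAYIAKQR")
  pc <- identity_similarity(self)
  expect_equal(pc$identity, 100)
  expect_equal(pc$similarity, 100)
  pc2 <- identity_similarity(pairwise_align("AAAA", "AATT"))
  expect_equal(pc2$identity, 50)
  # symmetric under swapping the two rows of the alignment
  aln <- pairwise_align("MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ", "MKTAYIDKQRHISFVKSNFSRQLEERLGMIEVQ")
  sw <- aln; sw$aligned_a <- aln$aligned_b; sw$aligned_b <- aln$aligned_a
  expect_equal(identity_similarity(aln), identity_similarity(sw))
  # and end-to-end for swapped inputs
  rev <- pairwise_align("MKTAYIDKQRHISFVKSNFSRQLEERLGMIEVQ", "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ")
  expect_equal(identity_similarity(rev), identity_similarity(aln))
  # all-gap columns only -> error
  bad <- list(aligned_a = "--", aligned_b = "--", substitution_matrix = "BLOSUM62")
  expect_error(identity_similarity(bad), "no residue")
})
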