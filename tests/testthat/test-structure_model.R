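test_that("conformer construction enforces its invariants", {
  atoms <- tibble::tibble(resid = c(1, 1, 2), elety = c("N", "CA", "CA"),
                          x = c(0, 1.4, 5), y = 0, z = 0)
  cf <- conformer(atoms)
  expect_s3_class(cf, "conformer")
  expect_equal(n_residues(cf), 2L)
  # missing CA is reported with the residue index
  bad <- tibble::tibble(resid = 1:3, elety = c("CA", "CA", "N"),
                        x = c(0, 3.8, 7.6), y = 0, z = 0)
  expect_error(conformer(bad), "residue 3")
  expect_error(conformer(atoms[1:2, ]), "at least 2")
  expect_error(conformer(atoms, sequence = "QQQ"), "sequence length")
})

test_that("PDB round trip preserves models, order and coordinates", {
  ens <- ensemble(list(make_ideal("helix", 20),
                       perturb_conformer(make_ideal("helix", 20), 1.5, seed = 3)))
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(ens, tf)
  back <- read_pdb(tf)
  expect_length(back, 2L)
  for (m in 1:2) {
    expect_identical(back[[m]]$atoms$elety, ens[[m]]$atoms$elety)
    expect_identical(back[[m]]$atoms$resid, ens[[m]]$atoms$resid)
    dev <- max(abs(as.matrix(back[[m]]$atoms[, c("x", "y", "z")]) -
                     as.matrix(ens[[m]]$atoms[, c("x", "y", "z")])))
    expect_lt(dev, 1e-3)
  }
  expect_identical(back[[1]]$sequence, ens[[1]]$sequence)
  expect_error(write_pdb(ensemble(list()), tf), "empty")
})

test_that("single-model PDB files and CA-only traces read back", {
  cf <- make_self_avoiding_coil(12, seed = 5)
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(cf, tf)
  back <- read_pdb(tf)
  expect_length(back, 1L)
  expect_lt(max(abs(ca_coords(back[[1]]) - ca_coords(cf))), 1e-3)
  tx <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(ensemble(list(cf, cf)), tx)
  bx <- read_xyz(tx)
  expect_length(bx, 2L)
  expect_lt(max(abs(ca_coords(bx[[2]]) - ca_coords(cf))), 1e-5)
  expect_error(read_pdb(withr::local_tempfile(fileext = ".pdb")), "not found")
})

test_that("a PDB residue without CA is a parse error naming the residue", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   GLN A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  GLN A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  N   GLN A   2       3.000   1.000   0.000  1.00  0.00           N",
    "ATOM      4  CA  GLN A   2       4.458   1.000   0.000  1.00  0.00           C",
    "ATOM      5  N   GLN A   3       6.000   2.000   0.000  1.00  0.00           N",
    "END"), tf)
  expect_error(read_pdb(tf), "residue 3 has no CA")
})

test_that("superposed RMSD is zero for rigid copies and symmetric", {
  co <- make_self_avoiding_coil(40, seed = 2)
  set.seed(10)
  for (k in 1:5) {
    moved <- transform_conformer(co, random_proper_rotation(),
                                 stats::rnorm(3, sd = 10))
    expect_lt(superpose_rmsd(co, moved), 1e-6)
  }
  expect_equal(superpose_rmsd(co, co), 0)
  other <- make_self_avoiding_coil(40, seed = 3)
  expect_equal(superpose_rmsd(co, other), superpose_rmsd(other, co))
  short <- make_self_avoiding_coil(20, seed = 2)
  expect_error(superpose_rmsd(co, short), "different numbers")
})

test_that("superposed RMSD matches a brute-force rotation-grid minimization", {
  a <- conformer_from_ca(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)))
  b <- conformer_from_ca(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 1, 0)))
  p <- ca_coords(a); q <- ca_coords(b)
  pc <- sweep(p, 2, colMeans(p)); qc <- sweep(q, 2, colMeans(q))
  rotz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1),
                             3, 3, byrow = TRUE)
  roty <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0, -sin(t), 0, cos(t)),
                             3, 3, byrow = TRUE)
  best <- Inf
  for (al in seq(0, 2 * pi, length.out = 50))
    for (be in seq(0, pi, length.out = 25))
      for (ga in seq(0, 2 * pi, length.out = 50)) {
        r <- rotz(al) %*% roty(be) %*% rotz(ga)
        best <- min(best, sqrt(sum((pc %*% r - qc)^2) / 3))
      }
  # the grid value upper-bounds the closed-form optimum
  expect_lt(abs(superpose_rmsd(a, b) - best), 1e-3)
  expect_lte(superpose_rmsd(a, b), best + 1e-9)
})

test_that("time-ordered ensembles require increasing timestamps", {
  f1 <- make_self_avoiding_coil(10, seed = 1); f1$timestamp <- 0
  f2 <- make_self_avoiding_coil(10, seed = 2); f2$timestamp <- 10
  ens <- ensemble(list(f1, f2), is_time_ordered = TRUE)
  expect_equal(timestamps(ens), c(0, 10))
  f2$timestamp <- 0
  expect_error(ensemble(list(f1, f2), is_time_ordered = TRUE),
               "strictly increasing")
})
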