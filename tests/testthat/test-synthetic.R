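test_that("ideal motifs have the advertised geometry and assignments", {
  h <- make_ideal("helix", 20)
  ss <- assign_secondary_structure(h)
  expect_gte(sum(ss$codes == "H"), 14)

  e <- make_ideal("extended", 10)
  expect_equal(radius_of_gyration(e), 3.8 * sqrt((100 - 1) / 12),
               tolerance = 0.05)
  expect_setequal(unique(e$atoms$elety), c("N", "CA", "C", "O"))

  hp <- make_ideal("hairpin", 16)
  cm <- build_contact_map(hp)
  expect_gte(nrow(cm), 3)
  expect_true(all(cm$sep >= 3))
  expect_error(make_ideal("helix", 4), "n >= 6")
})

test_that("self-avoiding coils respect their construction constraints", {
  co <- make_self_avoiding_coil(60, seed = 7)
  xyz <- ca_coords(co)
  bonds <- sqrt(rowSums(diff(xyz)^2))
  expect_equal(bonds, rep(3.8, 59), tolerance = 1e-9)
  dm <- as.matrix(stats::dist(xyz))
  nonbonded <- abs(row(dm) - col(dm)) > 1
  expect_gte(min(dm[nonbonded]), 4.0)
  # determinism
  expect_identical(ca_coords(make_self_avoiding_coil(60, seed = 7)), xyz)
})

test_that("different coil seeds give structurally distant chains", {
  set.seed(1)
  pairs <- matrix(sample.int(500, 60), ncol = 2)
  rms <- apply(pairs, 1, function(p)
    superpose_rmsd(make_self_avoiding_coil(60, seed = p[1]),
                   make_self_avoiding_coil(60, seed = p[2])))
  expect_gte(mean(rms > 2), 0.95)
})

test_that("planted knotted chains classify to their construction type", {
  for (kt in c("0_1", "3_1")) {
    ch <- make_knotted_chain(60, kt, c(5, 5), seed = 3)
    bonds <- sqrt(rowSums(diff(ca_coords(ch))^2))
    expect_true(all(abs(bonds - 3.8) <= 0.05))
    expect_equal(classify_knot(ch, seed = 11)$knot_type, kt)
  }
  expect_equal(classify_knot(make_knotted_chain(70, "4_1", c(5, 5), seed = 2),
                             seed = 5)$knot_type, "4_1")
  expect_equal(classify_knot(make_knotted_chain(100, "5_2", c(10, 10), seed = 2),
                             seed = 5)$knot_type, "5_2")
  expect_error(make_knotted_chain(25, "3_1", c(5, 5)), "too small")
})

test_that("backbone reconstruction keeps CAs and ideal peptide bonds", {
  co <- make_self_avoiding_coil(30, seed = 9)
  bb <- backbone_from_ca(co)
  expect_setequal(unique(bb$atoms$elety), c("N", "CA", "C", "O"))
  expect_equal(ca_coords(bb), ca_coords(co), tolerance = 1e-12)
  at <- bb$atoms
  cn <- vapply(1:29, function(i) {
    ci <- at[at$resid == i & at$elety == "C", c("x", "y", "z")]
    ni <- at[at$resid == i + 1 & at$elety == "N", c("x", "y", "z")]
    sqrt(sum((ci - ni)^2))
  }, numeric(1))
  expect_true(all(abs(cn - 1.33) <= 0.05))
  stretched <- conformer_from_ca(cbind(seq(0, 50, by = 5), 0, 0))
  expect_error(backbone_from_ca(stretched), "CA spacing")
})

test_that("perturbation is seeded, unbiased and has the expected magnitude", {
  co <- make_self_avoiding_coil(60, seed = 4)
  expect_identical(perturb_conformer(co, 0, seed = 1)$atoms, co$atoms)
  p1 <- perturb_conformer(co, 0.5, seed = 8)
  expect_identical(perturb_conformer(co, 0.5, seed = 8)$atoms, p1$atoms)
  rms <- vapply(1:100, function(s)
    polyknot:::raw_rmsd(ca_coords(perturb_conformer(co, 0.5, seed = s)),
                        ca_coords(co)), numeric(1))
  expect_equal(mean(rms), 0.5 * sqrt(3), tolerance = 0.15)
})

test_that("sieve fixtures realize their planted cluster plan", {
  plan <- data.frame(start = c(0, 200, 400), end = c(60, 260, 460),
                     ss = c(40, 45, 50))
  fx <- make_sieve_fixture(plan, seed = 2)
  expect_equal(fx$n_clusters_true, 3L)
  expect_true(all(diff(timestamps(fx$ensemble)) > 0))
  expect_error(
    make_sieve_fixture(data.frame(start = c(0, 30), end = c(50, 80),
                                  ss = c(40, 40))),
    "overlapping")
})
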