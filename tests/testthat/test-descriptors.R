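test_that("contact map matches the overlap criterion and the brute-force oracle", {
  # residues 50 A apart: no contact (CA-only backbone mode)
  far <- conformer_from_ca(rbind(c(0, 0, 0), c(3.8, 0, 0),
                                 c(50, 0, 0), c(53.8, 0, 0)))
  expect_equal(nrow(build_contact_map(far)), 0L)

  # two CA atoms 3.0 A apart overlap (enlarged radii sum 4.66 A)
  atoms <- tibble::tibble(
    resid = c(1L, 2L, 3L, 4L), elety = "CA",
    x = c(0, 3.8, 1.9, 5.7), y = c(0, 0, 3.0, 3.0), z = 0)
  near <- conformer(atoms)
  cm <- build_contact_map(near, min_separation = 2L)
  expect_true(any(cm$i == 1 & cm$j == 3))

  # hairpin map equals exhaustive all-atom-pair scan
  hp <- hairpin16()
  cm <- build_contact_map(hp)
  oracle <- oracle_contacts(hp)
  expect_equal(as.matrix(cm[, c("i", "j")]), oracle,
               ignore_attr = TRUE)
  expect_true(all(cm$sep >= 3))
  # native distances are the CA-CA distances
  ca <- ca_coords(hp)
  nd <- sqrt(rowSums((ca[cm$i, , drop = FALSE] - ca[cm$j, , drop = FALSE])^2))
  expect_equal(cm$native_distance, nd)
})

test_that("radius of gyration matches the colinear closed form and is rigid-motion invariant", {
  n <- 10
  colinear <- conformer_from_ca(cbind(3.8 * (0:(n - 1)), 0, 0))
  expect_equal(radius_of_gyration(colinear), 3.8 * sqrt((n^2 - 1) / 12),
               tolerance = 1e-6)
  set.seed(3)
  co <- make_self_avoiding_coil(40, seed = 6)
  rg <- radius_of_gyration(co)
  for (k in 1:3) {
    moved <- transform_conformer(co, random_proper_rotation(), stats::rnorm(3, sd = 20))
    expect_equal(radius_of_gyration(moved), rg, tolerance = 1e-9)
  }
})

test_that("shape parameter w separates rods, disks and spheres", {
  set.seed(42)
  rod <- conformer_from_ca(cbind(seq(0, 100, length.out = 300), 0, 0) +
                             matrix(stats::rnorm(900, sd = 1e-4), 300))
  disk_t <- stats::runif(3000, 0, 2 * pi)
  disk_r <- 10 * sqrt(stats::runif(3000))
  disk <- conformer_from_ca(cbind(disk_r * cos(disk_t), disk_r * sin(disk_t), 0))
  u <- matrix(stats::rnorm(9000), ncol = 3)
  u <- u / sqrt(rowSums(u^2)) * stats::runif(3000)^(1 / 3) * 10
  sphere <- conformer_from_ca(u)
  for (k in 1:3) {
    rot <- random_proper_rotation()
    expect_equal(shape_parameter_w(transform_conformer(rod, rot)), 2,
                 tolerance = 0.05)
    expect_equal(shape_parameter_w(transform_conformer(disk, rot)), -0.25,
                 tolerance = 0.05)
    expect_lt(abs(shape_parameter_w(transform_conformer(sphere, rot))), 0.02)
  }
})

test_that("mean coordination counts neighbors plus contacts", {
  co <- conformer_from_ca(ca_coords(make_self_avoiding_coil(60, seed = 2)))
  cm_empty <- build_contact_map(backbone_from_ca(
    conformer_from_ca(cbind(3.8 * (0:59), 0, 0))))
  expect_equal(nrow(cm_empty), 0L)
  expect_equal(mean_coordination(cm_empty), 2 * 59 / 60, tolerance = 1e-9)

  # adding one contact raises the mean by exactly 2/N
  cm1 <- tibble::tibble(i = 1L, j = 30L, native_distance = 5, sep = 29L)
  class(cm1) <- class(cm_empty)
  attr(cm1, "n_residues") <- 60L
  expect_equal(mean_coordination(cm1) - mean_coordination(cm_empty), 2 / 60)

  # brute-force per-residue tally on a compact chain
  ch <- make_knotted_chain(40, "3_1", c(2, 2), seed = 5)
  cm <- build_contact_map(backbone_from_ca(ch))
  n <- 40
  z <- rep(2, n); z[c(1, n)] <- 1
  for (k in seq_len(nrow(cm))) {
    z[cm$i[k]] <- z[cm$i[k]] + 1
    z[cm$j[k]] <- z[cm$j[k]] + 1
  }
  expect_equal(mean_coordination(cm), mean(z))
})

test_that("contact order evaluates the normalized mean sequence separation", {
  mk <- function(n, ij) {
    cm <- tibble::tibble(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]),
                         native_distance = 5,
                         sep = as.integer(ij[, 2] - ij[, 1]))
    class(cm) <- c("contact_map", class(tibble::tibble()))
    attr(cm, "n_residues") <- n
    cm
  }
  expect_equal(contact_order(mk(4, rbind(c(1, 4)))), 3 / (4 * 1))
  expect_equal(contact_order(mk(10, rbind(c(2, 6), c(3, 9)))), (4 + 6) / (10 * 2))
  expect_error(contact_order(mk(5, matrix(numeric(0), 0, 2))), "zero contacts")
})

test_that("secondary structure assignment recognizes the ideal motifs", {
  ss_h <- assign_secondary_structure(make_ideal("helix", 20))
  expect_gte(ss_h$ss_alpha, 70)
  ss_hp <- assign_secondary_structure(hairpin16())
  expect_gt(ss_hp$ss_beta, 0)
  expect_gte(ss_hp$ss_total, 30)
  ss_e <- assign_secondary_structure(make_ideal("extended", 10))
  expect_equal(ss_e$ss_beta, 0)
  expect_equal(ss_hp$ss_total, ss_hp$ss_alpha + ss_hp$ss_beta + ss_hp$ss_turn)
  ca_only <- make_self_avoiding_coil(10, seed = 1)
  expect_error(assign_secondary_structure(ca_only), "missing backbone")
})

test_that("Maxwell threshold and volatility follow the finite-size count", {
  expect_equal(stiff_limit(1e9), 6, tolerance = 1e-6)
  expect_equal(stiff_limit(60), 5.8)
  expect_equal(stiff_limit(12), 5.0)
  expect_true(is_volatile(5.0, 60))
  expect_false(is_volatile(7.67, 60))
  expect_false(is_volatile(5.8, 60))  # boundary counts as stiff
})

test_that("descriptor tables are rigid-motion invariant", {
  hp <- hairpin16()
  d0 <- describe_conformer(hp)
  set.seed(8)
  moved <- transform_conformer(hp, random_proper_rotation(), c(12, -5, 3))
  d1 <- describe_conformer(moved)
  for (col in c("r_g", "w", "ss_alpha", "ss_beta", "ss_turn", "z_mean",
                "co", "n_contacts"))
    expect_equal(d1[[col]], d0[[col]], tolerance = 1e-6)
  # z lower bound attained exactly without contacts
  ext <- describe_conformer(make_ideal("extended", 12))
  expect_equal(ext$z_mean, 2 * 11 / 12)
})
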