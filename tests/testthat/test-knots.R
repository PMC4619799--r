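test_that("KMT reduction collapses simple chains and is idempotent", {
  line <- cbind(seq(0, 34.2, by = 3.8), 0, 0)
  expect_equal(nrow(kmt_reduce(line)), 2L)
  ch <- make_knotted_chain(60, "3_1", c(5, 5), seed = 1)
  red <- kmt_reduce(ca_coords(ch))
  expect_lt(nrow(red), 60)
  red2 <- kmt_reduce(red)
  expect_equal(nrow(red2), nrow(red))
  # reduction preserves the classification
  expect_equal(classify_knot(red, seed = 2)$knot_type,
               classify_knot(ca_coords(ch), seed = 2)$knot_type)
})

test_that("KMT reduction never changes the classification on random fixtures", {
  set.seed(20)
  for (k in 1:12) {
    x <- if (k %% 3 == 0) ca_coords(make_knotted_chain(50, "3_1", c(4, 4), seed = k))
         else ca_coords(make_self_avoiding_coil(30, seed = k))
    before <- classify_knot(x, n_closures = 32, seed = k)$knot_type
    after <- classify_knot(kmt_reduce(x), n_closures = 32, seed = k)$knot_type
    expect_equal(after, before)
  }
})

test_that("stochastic closures are seeded and classify simple cases", {
  t <- seq(0, 2 * pi * 0.999, length.out = 60)
  near_circle <- cbind(10 * cos(t), 10 * sin(t), 0.01 * t)
  cls <- close_chain(near_circle, n_closures = 16, seed = 5)
  expect_length(cls, 16L)
  cls2 <- close_chain(near_circle, n_closures = 16, seed = 5)
  expect_identical(cls, cls2)
  expect_equal(classify_knot(near_circle, seed = 2)$knot_type, "0_1")
})

test_that("Alexander invariants separate the knot table in scope", {
  t <- seq(0, 2 * pi, length.out = 61)[-61]
  circle <- cbind(cos(t), sin(t), 0 * t)
  expect_equal(alexander_invariants(circle, seed = 1), c(1L, 1L))
  expected <- list("3_1" = c(3L, 7L), "4_1" = c(5L, 11L),
                   "5_1" = c(5L, 31L), "5_2" = c(7L, 1L))
  for (kt in names(expected)) {
    cur <- polyknot:::knot_parametric_curve(kt)
    cl <- polyknot:::resample_polyline(cur, 200, closed = TRUE)
    for (s in 1:3)
      expect_equal(alexander_invariants(cl, seed = s), expected[[kt]],
                   info = paste(kt, "seed", s))
  }
})

test_that("open-chain classification is invariant under rigid motion, scaling and reversal", {
  ch <- ca_coords(make_knotted_chain(60, "3_1", c(5, 5), seed = 6))
  base <- classify_knot(ch, seed = 3)
  expect_equal(base$knot_type, "3_1")
  expect_gte(base$closure_votes, 0.9)
  set.seed(9)
  rot <- random_proper_rotation()
  moved <- ch %*% t(rot) + matrix(c(30, -12, 7), nrow(ch), 3, byrow = TRUE)
  expect_equal(classify_knot(moved, seed = 4)$knot_type, "3_1")
  expect_equal(classify_knot(ch * 0.37, seed = 4)$knot_type, "3_1")
  expect_equal(classify_knot(ch[nrow(ch):1, ], seed = 4)$knot_type, "3_1")
})

test_that("short random coils are essentially never knotted", {
  types <- vapply(1:25, function(s)
    classify_knot(make_self_avoiding_coil(20, seed = s),
                  n_closures = 32, seed = s)$knot_type, character(1))
  expect_true(all(types == "0_1"))
})

test_that("knot-core trimming recovers the planted core within 3 residues", {
  ch <- trefoil80()
  planted <- attr(ch, "planted_core")
  kc <- trefoil80_core()
  expect_equal(kc$knot_type, "3_1")
  expect_lte(abs(kc$k_minus - planted[1]), 3)
  expect_lte(abs(kc$k_plus - planted[2]), 3)
  expect_equal(kc$delta_k, kc$k_plus - kc$k_minus + 1L)
  # the reported core still classifies to the full-chain type
  core_chain <- ca_coords(ch)[kc$k_minus:kc$k_plus, ]
  expect_equal(classify_knot(core_chain, seed = 13)$knot_type, "3_1")
  expect_error(knot_core(make_self_avoiding_coil(20, seed = 1)), "unknotted")
})

test_that("shallow knots extend over most of the chain", {
  shallow <- make_knotted_chain(40, "3_1", c(2, 2), seed = 3)
  kc <- knot_core(shallow, seed = 7)
  expect_gte(kc$delta_k, 0.5 * 40)
})

test_that("untying under stretch requires a knotted start and bounds its fraction", {
  ext <- extended16_model()
  expect_error(untying_under_stretch(ext, n_seeds = 1), "knotted")
  deep <- backbone_from_ca(make_knotted_chain(35, "3_1", c(7, 7), seed = 2))
  m <- build_go_model(deep, build_contact_map(deep))
  res <- pk_cached("untie_deep",
                   untying_under_stretch(m, go_params(), n_seeds = 4, base_seed = 1))
  expect_gte(res$fraction_untied, 0)
  expect_lte(res$fraction_untied, 1)
  expect_equal(res$initial_type, "3_1")
  expect_length(res$final_types, 4L)
})

test_that("deep knots untie less often than shallow knots", {
  deep <- backbone_from_ca(make_knotted_chain(35, "3_1", c(7, 7), seed = 2))
  shallow <- backbone_from_ca(make_knotted_chain(35, "3_1", c(1, 1), seed = 2))
  md <- build_go_model(deep, build_contact_map(deep))
  ms <- build_go_model(shallow, build_contact_map(shallow))
  res_d <- pk_cached("untie_deep",
                     untying_under_stretch(md, go_params(), n_seeds = 4, base_seed = 1))
  res_s <- untying_under_stretch(ms, go_params(), n_seeds = 4, base_seed = 1)
  expect_lte(res_d$fraction_untied, res_s$fraction_untied)
})
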