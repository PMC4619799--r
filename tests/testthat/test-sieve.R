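test_that("the SS sieve keeps strictly structured frames in order", {
  expect_equal(ss_sieve(c(10, 40, 50, 20), threshold = 30), c(2L, 3L))
  expect_equal(ss_sieve(c(10, 20, 25), threshold = 30), integer(0))
  expect_equal(ss_sieve(c(10, 20, 25), threshold = 0), 1:3)
  expect_equal(ss_sieve(c(30, 30.0001), threshold = 30), 2L)  # strict
  expect_error(ss_sieve(c(10, 20), threshold = 30, n_frames = 3), "per frame")
})

test_that("time clustering splits at gaps and picks max-SS representatives", {
  cl <- time_cluster(times = c(0, 10, 20, 100, 110), ss = c(35, 60, 40, 50, 45),
                     gap_threshold = 50)
  expect_equal(nrow(cl), 2L)
  expect_equal(cl$members[[1]], 1:3)
  expect_equal(cl$representative, c(2L, 4L))   # SS 60 and SS 50
  # earliest frame wins SS ties
  cl2 <- time_cluster(c(0, 5, 10), c(40, 40, 40))
  expect_equal(cl2$representative, 1L)
  single <- time_cluster(5, 33)
  expect_equal(nrow(single), 1L)
  expect_equal(single$representative, 1L)
})

test_that("greedy RMSD independence keeps one conformer per structural group", {
  base <- make_self_avoiding_coil(30, seed = 1)
  copies <- lapply(1:5, function(i) base)
  expect_equal(structural_independence(copies), 1L)

  distant <- lapply(1:5, function(i) make_self_avoiding_coil(30, seed = 100 + i))
  rms <- combn(5, 2, function(p) superpose_rmsd(distant[[p[1]]], distant[[p[2]]]))
  expect_true(all(rms > 2))
  expect_equal(structural_independence(distant), 1:5)

  # 5 planted groups: tight within (0.2 A noise), distant between
  groups <- unlist(lapply(1:5, function(g)
    lapply(1:3, function(r)
      perturb_conformer(distant[[g]], 0.2, seed = g * 10 + r))),
    recursive = FALSE)
  expect_length(structural_independence(groups), 5L)
  expect_error(structural_independence(list(base, make_self_avoiding_coil(20, 1))),
               "chain length")
})

test_that("the full sieve recovers planted clusters and is monotone", {
  plan <- data.frame(start = c(0, 200, 400), end = c(60, 260, 460),
                     ss = c(40, 45, 50))
  fx <- make_sieve_fixture(plan, seed = 2)
  sr <- run_sieve(fx$ensemble, ss_values = fx$ss)
  expect_equal(nrow(sr$clusters), fx$n_clusters_true)
  expect_length(sr$independent_idx, 3L)
  g <- glance(sr)
  expect_true(g$n_independent <= g$n_clusters)
  expect_true(g$n_clusters <= g$n_structured_frames)
  expect_true(g$n_structured_frames <= g$n_input_frames)

  # all frames below the SS threshold: nothing survives
  low <- make_sieve_fixture(data.frame(start = 0, end = 100, ss = 20), seed = 3)
  sr_low <- run_sieve(low$ensemble, ss_values = low$ss)
  expect_equal(sr_low$n_structured_frames, 0L)
  expect_length(sr_low$independent_idx, 0L)

  # invariance under a constant timestamp offset
  shifted <- lapply(unclass(fx$ensemble), function(cf) {
    cf$timestamp <- cf$timestamp + 1000
    cf
  })
  sr_shift <- run_sieve(ensemble(shifted, is_time_ordered = TRUE),
                        ss_values = fx$ss)
  expect_equal(nrow(sr_shift$clusters), nrow(sr$clusters))
  expect_equal(sr_shift$independent_idx, sr$independent_idx)
})

test_that("independence kinetics fits the accumulation slope", {
  ik <- independence_kinetics(0:10, 0.62 * (0:10) + 2)
  expect_equal(ik$slope, 0.62, tolerance = 1e-9)
  expect_equal(independence_kinetics(0:5, rep(4, 6))$slope, 0)
  set.seed(4)
  t <- seq(0, 99)
  y <- 0.28 * t + 1 + stats::rnorm(100, sd = 0.5)
  fit <- independence_kinetics(t, y)
  expect_lt(abs(fit$slope - 0.28), 3 * fit$slope_se)
  expect_error(independence_kinetics(0:1, 0:1), ">= 3")
})
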