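test_that("the native state sits at the bottom of the contact energy", {
  hp <- hairpin16()
  cm <- build_contact_map(hp)
  m <- hairpin16_model()
  expect_equal(go_energy(m), -1 * nrow(cm), tolerance = 1e-9)

  # each contact potential has zero derivative at its native distance
  for (k in seq_len(nrow(cm))) {
    r0 <- cm$native_distance[k]
    v <- function(r) ((r0 / r)^12 - 2 * (r0 / r)^6)
    num_deriv <- (v(r0 + 1e-6) - v(r0 - 1e-6)) / 2e-6
    expect_lt(abs(num_deriv), 1e-6)
  }
  expect_equal(length(extended16_model()$contact_i), 0L)
})

test_that("undamped integration conserves energy", {
  m <- hairpin16_model()
  m$coords <- ca_coords(perturb_conformer(hairpin16(), 0.02, seed = 7))
  p <- go_params(temperature = 0, damping = 0, timestep = 5e-4, seed = 1)
  tr <- run_langevin(m, p, n_steps = 1e5, sample_stride = 500)
  expect_lt(max(tr$energy) - min(tr$energy), 1e-4)
})

test_that("the thermostat equilibrates to the target temperature", {
  p <- go_params(seed = 3)
  tr <- run_langevin(hairpin16_model(), p, n_steps = 2e5, sample_stride = 50)
  ke <- tr$kinetic[tr$sample_t > 100]
  # equipartition: mean kinetic energy per degree of freedom = T/2
  expect_equal(mean(ke) / (3 * 16), 0.15, tolerance = 0.1)
})

test_that("Langevin trajectories are deterministic per seed", {
  p <- go_params(seed = 11)
  t1 <- run_langevin(hairpin16_model(), p, n_steps = 5000, traj_stride = 1000)
  t2 <- run_langevin(hairpin16_model(), p, n_steps = 5000, traj_stride = 1000)
  expect_identical(t1$final_coords, t2$final_coords)
  p2 <- go_params(seed = 12)
  t3 <- run_langevin(hairpin16_model(), p2, n_steps = 5000)
  expect_false(identical(t1$final_coords, t3$final_coords))
})

test_that("pulling a contact-free chain articulates no force peak", {
  fc <- pull_constant_speed(extended16_model(), go_params(seed = 5))
  expect_equal(fc$f_max, 0)
  expect_equal(fc$n_p, 0L)
  fc2 <- pull_constant_speed(extended16_model(), go_params(seed = 6))
  expect_equal(fc2$f_max, 0)
})

test_that("pulling a hairpin ruptures its contacts with articulated peaks", {
  fc <- hairpin16_pull()
  expect_gte(fc$n_p, 1)
  expect_gt(fc$f_max, 0.1)
  # terminates essentially fully extended
  e2e <- sqrt(sum((fc$final_coords[16, ] - fc$final_coords[1, ])^2))
  expect_gte(e2e, 0.9 * fc$contour_length)
  # every cross-strand contact breaks, at a recorded displacement
  sc <- unfolding_scenario(fc)
  expect_true(all(sc$broken))
  expect_true(all(sc$d_break[sc$broken] > 0))
  expect_true(all(sc$d_break[sc$broken] <= fc$contour_length + 5))
  expect_equal(sc$sep, abs(sc$j - sc$i))
})

test_that("peak detection applies the height and prominence thresholds", {
  flat_top <- c(rep(0.02, 10), seq(0.02, 1.2, length.out = 8), rep(1.2, 4),
                seq(1.2, 0.02, length.out = 8), rep(0.02, 10))
  c1 <- tibble::tibble(d = seq_along(flat_top), force = flat_top)
  pk <- detect_force_peaks(c1)
  expect_equal(pk$f_max, 1.2, tolerance = 0.01)
  expect_equal(pk$n_p, 1L)

  c2 <- tibble::tibble(d = 1:40, force = 0.02 + 0.02 * sin(1:40))
  expect_equal(detect_force_peaks(c2)$f_max, 0)
  expect_equal(detect_force_peaks(c2)$n_p, 0L)

  two <- c(rep(0.05, 8), seq(0.05, 0.5, length.out = 6), rep(0.5, 3),
           seq(0.5, 0.05, length.out = 6), rep(0.05, 6),
           seq(0.05, 1.0, length.out = 6), rep(1, 3),
           seq(1.0, 0.05, length.out = 6), rep(0.05, 8))
  c3 <- tibble::tibble(d = seq_along(two), force = two)
  pk3 <- detect_force_peaks(c3)
  expect_equal(pk3$n_p, 2L)
  expect_equal(pk3$f_max, 1.0, tolerance = 0.01)
  # a terminal monotone rise is not a peak
  c4 <- tibble::tibble(d = 1:20, force = c(rep(0.05, 10), seq(0.1, 2, length.out = 10)))
  expect_equal(detect_force_peaks(c4)$n_p, 0L)
  expect_error(detect_force_peaks(tibble::tibble(d = numeric(), force = numeric())),
               "empty")
})

test_that("F_max is reproducible across thermal seeds within 30%", {
  m <- hairpin16_model()
  fm <- vapply(1:12, function(s)
    pull_constant_speed(m, go_params(seed = s))$f_max, numeric(1))
  expect_lt(stats::sd(fm) / mean(fm), 0.30)
  expect_true(all(fm > 0.1))
})

test_that("force conversion to piconewton uses the 110 pN.A calibration", {
  expect_equal(eps_to_pN(1), 110)
  expect_equal(eps_to_pN(c(2.1, 2.3)), c(231, 253))
})
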