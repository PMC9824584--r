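test_that("stage-1 size law matches direct evaluation and is monotone", {
  expect_equal(stage1_size(0, 3, 10, 0.125), 3)
  expect_equal(stage1_size(10, 1, 10, 0.125), 2^0.125, tolerance = 1e-10)
  expect_equal(2^0.125, 1.09051, tolerance = 1e-5)
  t <- seq(0, 100, by = 1)
  expect_true(all(diff(stage1_size(t, 2, 5, 0.1)) > 0))
  expect_error(stage1_size(-1, 2, 5, 0.1), "non-negative")
})

test_that("stage-2 size law has the master-curve values and limits", {
  tau <- 7
  expect_equal(stage2_size(1e9 * tau, 5, tau), 5)
  expect_equal(stage2_size(tau, 1, tau), (1 - exp(-1))^0.2, tolerance = 1e-12)
  expect_equal((1 - exp(-1))^0.2, 0.91235, tolerance = 1e-5)
  expect_equal(stage2_size(3 * tau, 1, tau), 0.98984, tolerance = 1e-5)
  t <- seq(0, 50, by = 0.5)
  expect_true(all(diff(stage2_size(t, 4, tau)) > 0))
  expect_error(stage2_size(0.01, 4, tau, bc = 1.5), "negative")
})

test_that("velocities are the analytic derivatives of the size laws", {
  R0 <- 4; tau_s <- 3; alpha <- 0.11
  expect_equal(stage1_velocity(0, R0, tau_s, alpha), alpha * R0 / tau_s)
  for (t in c(0.5, 2, 9)) {
    expect_equal(stage1_velocity(t, R0, tau_s, alpha),
                 num_deriv(function(x) stage1_size(x, R0, tau_s, alpha), t),
                 tolerance = 1e-8)
  }
  RF <- 9; tau_c <- 40
  for (t in c(5, 20, 100)) {
    expect_equal(stage2_velocity(t, RF, tau_c),
                 num_deriv(function(x) stage2_size(x, RF, tau_c), t),
                 tolerance = 1e-7)
  }
  expect_identical(stage2_velocity(0, RF, tau_c), Inf)
  expect_lt(stage2_velocity(100 * tau_c, RF, tau_c), 1e-12)
})

test_that("alpha <-> nu_b mappings are mutually inverse", {
  expect_equal(alpha_from_nub(0.5), 0.125)
  expect_equal(nub_from_alpha(0.0979), 0.455, tolerance = 1e-3)
  x <- seq(0.35, 0.59, by = 0.01)
  expect_equal(nub_from_alpha(alpha_from_nub(x)), x, tolerance = 1e-12)
  expect_error(nub_from_alpha(0.5), "1/2")
})

test_that("predicted time scaling forms behave as stated", {
  p <- model_params()
  t1 <- predicted_times(500, R0 = 4, p, a_c = 0.18, xc = 2.36)
  t2 <- predicted_times(1000, R0 = 4, p, a_c = 0.18, xc = 2.36)
  expect_equal(t2$tau_c / t1$tau_c, 2^2.36, tolerance = 1e-12)
  # doubling N multiplies the theoretical (xc = 2) form by 4 exactly
  q1 <- predicted_times(100, R0 = 4, p)$tau_c
  q2 <- predicted_times(200, R0 = 4, p)$tau_c
  expect_equal(q2 / q1, 4)
  expect_equal(predicted_xs(0, 0.125, 0.5), 8 / 3 - 2, tolerance = 1e-12)
  expect_error(predicted_xs(0, 0.1, 1 / 3), "singular")
})

test_that("Flory free energy minimizes at the nu = 3/5 coil size", {
  p <- model_params()
  rstar <- vapply(c(100, 400), function(N) {
    stats::optimize(function(R) free_energies(R, N, p)$F_flory,
                    c(0.5, 200))$minimum
  }, 0)
  expect_equal(log(rstar[2] / rstar[1]) / log(4), 0.6, tolerance = 1e-3)
  # blob form decreases monotonically in R at nu_b = 0.5
  R <- seq(1, 10, by = 0.1)
  expect_true(all(diff(free_energies(R, 64, p)$F_blob) < 0))
  # doubling v_ex doubles only the second Flory term
  a <- free_energies(2, 64, p, v_ex = 1)$F_flory
  b <- free_energies(2, 64, p, v_ex = 2)$F_flory
  expect_equal(b - a, 64^2 / 2^3)
})

test_that("SI unit mapping reproduces the nucleic-acid reference scales", {
  map <- unit_map()
  expect_equal(simulation_time_unit(map) * 1e12, 3.86, tolerance = 0.005)
  expect_equal(to_real_units(map, 2.16e6) * 1e6, 8.35, tolerance = 0.02)
  expect_equal(to_real_units(map, 0), 0)
  # linear and invertible
  expect_equal(to_real_units(map, 5) / to_real_units(map, 1), 5)
})

test_that("expansion time and demarcation exponents follow the definitions", {
  expect_equal(expansion_time(4.03e5), 1.209e6)
  expect_equal(stage2_size(expansion_time(1), 1, 1), 0.98984,
               tolerance = 1e-5)
  dl <- demarcation_lines(xs = 0.61, xc = 2.36, nu_s = 1 / 3, nu_c = 0.6)
  expect_equal(attr(dl$t_sphere, "exponent"), (0.61 - 2.36) / (1 / 3),
               tolerance = 1e-12)
  expect_equal(attr(dl$t_sphere, "exponent"), -5.25, tolerance = 1e-10)
  expect_equal(dl$t_coil(2), 2^((2.36 - 0.61) / 0.6))
})
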