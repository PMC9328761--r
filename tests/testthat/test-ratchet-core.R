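test_that("gap-opening factor matches its closed form and bounds", {
  expect_identical(boltzmann_step_factor(0, 2.7, 0.5), 1)
  # exponent -1 by construction
  expect_equal(boltzmann_step_factor(4.114 / 2.7, 2.7, 1), exp(-1),
    tolerance = 1e-12
  )
  # hand-evaluated oracle: exp(-1 * 2.7 * 0.6 / 4.114)
  expect_equal(boltzmann_step_factor(1, 2.7, 0.6), 0.6745042,
    tolerance = 1e-6
  )
})

test_that("log of the gap factor is exactly linear in force, gap and angle", {
  const <- physical_constants()
  set.seed(1)
  for (i in 1:20) {
    f <- runif(1, 0, 6)
    d <- runif(1, 0.5, 8)
    s <- runif(1, 0.05, 1)
    b <- boltzmann_step_factor(f, d, s, const)
    expect_true(b > 0 && b <= 1)
    expect_equal(log(b), -f * d * s / const$kBT, tolerance = 1e-14)
    # linearity: doubling any factor squares the factor's contribution
    expect_equal(boltzmann_step_factor(2 * f, d, s, const), b^2,
      tolerance = 1e-12
    )
    expect_equal(boltzmann_step_factor(f, 2 * d, s, const), b^2,
      tolerance = 1e-12
    )
  }
  expect_error(boltzmann_step_factor(-1, 2.7, 0.5), "f_eff")
  expect_error(boltzmann_step_factor(1, 2.7, 1.5), "sin_theta")
  expect_error(boltzmann_step_factor(1, 2.7, 0), "sin_theta")
  expect_error(boltzmann_step_factor(1, -2.7, 0.5), "delta")
})

test_that("contact angle follows from end density and polymer length density", {
  const <- physical_constants()
  # perpendicular filaments saturate the bound exactly
  c_a <- 77
  e_sat <- c_a * const$molarity_to_density * const$subunit_rise * 1e-3
  expect_equal(sin_theta_from_network(e_sat, c_a), 1, tolerance = 1e-12)
  # unit-conversion oracle: 150 / (150 * 602.2 * 0.0027)
  expect_equal(sin_theta_from_network(150, 150),
    150 / (150 * 602.2 * 0.0027),
    tolerance = 1e-12
  )
  expect_error(
    sin_theta_from_network(500, 150),
    "Geometric inconsistency"
  )
  # never exceeds 1; composition with the gap factor is monotone
  # decreasing in end density at fixed polymer and force
  e_grid <- seq(20, 200, by = 20)
  s <- sin_theta_from_network(e_grid, 150)
  expect_true(all(s <= 1))
  b <- boltzmann_step_factor(2, 2.7, s)
  expect_true(all(diff(b) < 0))
})

test_that("equal load sharing gives force per filament in pN", {
  expect_identical(force_per_filament(0, 100), 0)
  expect_identical(force_per_filament(1020, 1020), 1)
  expect_equal(force_per_filament(1276, 400), 3.19, tolerance = 1e-12)
  expect_error(force_per_filament(10, 0), "barbed_end_density")
  expect_error(force_per_filament(-1, 10), "stress")
})

test_that("relative insertion rate reduces to the gap factor and scales with delta", {
  params <- ratchet_params(f_tether = 0)
  # state built to have sin(theta) = 0.6 and f = 1 pN
  e <- 0.6 * 150 * 602.2 * 0.0027
  load <- network_state(e * 1, e, 150) # stress = e -> f = 1 pN
  load$stress <- e
  ref <- network_state(0, e, 150)
  expect_equal(
    relative_insertion_rate(load, ref, 2.7, params),
    boltzmann_step_factor(1, 2.7, 0.6),
    tolerance = 1e-10
  )
  # identical states
  expect_equal(relative_insertion_rate(ref, ref, 2.7, params), 1)
  # doubling delta squares the ratio (exponent linearity)
  r1 <- relative_insertion_rate(load, ref, 2.7, params)
  r2 <- relative_insertion_rate(load, ref, 5.4, params)
  expect_equal(r2, r1^2, tolerance = 1e-12)
})

test_that("wt/bulky ratio is 1 for equal gaps and matches the hand oracle", {
  states <- flat_angle_states(c(0, 250, 500, 1000))
  same <- ratchet_params(
    delta_cap_bulky = 2.7, f_tether = 0.2,
    reference_stress = 0
  )
  expect_equal(wt_bulky_ratio(states, same)$ratio, rep(1, 4),
    tolerance = 1e-12
  )
  # normalisation at the reference load
  params <- ratchet_params(f_tether = 0.3, reference_stress = 0)
  expect_equal(wt_bulky_ratio(states, params)$ratio[1L], 1)
  # hand evaluation: f = 1 pN, sin(theta) = 0.6, delta 2.7 vs 5.4,
  # reference at zero force -> exp(1 * 2.7 * 0.6 / 4.114)
  e <- 0.6 * 150 * 602.2 * 0.0027
  st <- network_state(c(0, e), e, 150)
  p0 <- ratchet_params(f_tether = 0, reference_stress = 0)
  expect_equal(wt_bulky_ratio(st, p0)$ratio[2L],
    exp(1 * 2.7 * 0.6 / 4.114),
    tolerance = 1e-10
  )
  expect_equal(wt_bulky_ratio(st, p0)$ratio[2L], 1.4826, tolerance = 1e-4)
  # missing reference load
  expect_error(
    wt_bulky_ratio(network_state(c(100, 200), 150, 150), p0),
    "reference"
  )
  # ratio non-decreasing in stress for bulky > wt with non-decreasing angle
  many <- flat_angle_states(seq(0, 1200, by = 200))
  r <- wt_bulky_ratio(many, params)$ratio
  expect_true(all(r >= 1 - 1e-12))
  expect_true(all(diff(r) >= -1e-12))
})

test_that("tether-force fit recovers the generating value from noise-free ratios", {
  cfg <- generator_config()
  stresses <- c(0, 150, 350, 510, 765, 1020, 1150, 1300)
  states <- network_states(cfg, stresses)
  truth <- ratchet_params(f_tether = 0.3, reference_stress = 0)
  clean <- gen_ratio_dataset(states, truth, noise_sd = 0)
  fit <- fit_tether_force(clean, states, truth, n_boot = 20)
  expect_equal(fit$estimate, 0.3, tolerance = 1e-6)
  # zero tether recovers zero
  z <- ratchet_params(f_tether = 0, reference_stress = 0)
  clean0 <- gen_ratio_dataset(states, z, noise_sd = 0)
  expect_lt(fit_tether_force(clean0, states, z, n_boot = 10)$estimate, 1e-4)
  # degenerate: all loads equal
  flat <- clean[c(1, 1, 1), ]
  expect_error(fit_tether_force(flat, states, truth), "identifiable")
})

test_that("tether-fit bootstrap interval covers the truth on noisy replicates", {
  cfg <- generator_config()
  stresses <- c(0, 150, 350, 510, 765, 1020, 1150, 1300)
  states <- network_states(cfg, stresses)
  truth <- ratchet_params(f_tether = 0.3, reference_stress = 0)
  set.seed(202)
  covered <- vapply(1:25, function(i) {
    d <- gen_ratio_dataset(states, truth, noise_sd = 0.05)
    fit <- fit_tether_force(d, states, truth, n_boot = 150)
    fit$conf_int[1] <= 0.3 && 0.3 <= fit$conf_int[2]
  }, logical(1))
  # nominal coverage 95%; allow binomial noise at 25 replicates
  expect_gte(mean(covered), 0.84)
})

test_that("tether fit objects expose tidy and glance summaries", {
  # states with a load-dependent contact angle (a flat angle would make
  # the tether force cancel out of every ratio)
  states <- network_states(generator_config(), c(0, 300, 600, 900))
  truth <- ratchet_params(f_tether = 0.25, reference_stress = 0)
  d <- gen_ratio_dataset(states, truth, noise_sd = 0)
  fit <- fit_tether_force(d, states, truth, n_boot = 15)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "conf.low", "conf.high"))
  expect_equal(td$estimate, 0.25, tolerance = 1e-5)
  gl <- glance(fit)
  expect_equal(gl$nobs, 4L)
  expect_s3_class(autoplot(fit), "ggplot")
})
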