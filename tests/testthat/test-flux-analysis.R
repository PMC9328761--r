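test_that("steady segments of an exact two-phase trace recover both slopes", {
  tr <- exact_two_step_trace(v1 = 7.3, v2 = 2.0)
  segs <- find_steady_segments(tr, min_duration = 60)
  expect_equal(nrow(segs), 2L)
  expect_equal(segs$velocity, c(7.3, 2.0), tolerance = 1e-9)
  expect_equal(segs$stress, c(25, 500))
  expect_true(all(segs$r_squared >= 0.99))
  # ordered, non-overlapping
  expect_true(segs$t_end[1L] < segs$t_start[2L])
})

test_that("a stalled network at constant stress is one zero-velocity segment", {
  tr <- tibble::tibble(
    time_s = 0:120, height_um = rep(2.5, 121), stress_pa = 800
  )
  segs <- find_steady_segments(tr, min_duration = 60)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$velocity, 0)
})

test_that("no qualifying window yields an empty segment table, not an error", {
  # stress wanders far outside any tolerance band
  tr <- tibble::tibble(
    time_s = 0:50, height_um = (0:50) * 0.1,
    stress_pa = seq(0, 1000, length.out = 51)
  )
  segs <- find_steady_segments(tr, min_duration = 40)
  expect_equal(nrow(segs), 0L)
})

test_that("segment slope survives measurement noise within 2%", {
  cfg <- generator_config(
    seed = 11,
    stress_steps = tibble::tibble(stress_pa = 0, hold_s = 600)
  )
  tr <- gen_afm_trace(cfg)
  segs <- find_steady_segments(tr, min_duration = 120)
  expect_gte(nrow(segs), 1L)
  expect_equal(segs$velocity[1L], 7.3, tolerance = 0.02)
})

test_that("growth velocity is the OLS slope converted to um/min", {
  tr <- tibble::tibble(time_s = 0:59, height_um = 0.1216 * (0:59))
  expect_equal(growth_velocity(tr), 0.1216 * 60, tolerance = 1e-12)
  expect_error(
    growth_velocity(tibble::tibble(time_s = 2:0, height_um = 1:3)),
    "increasing"
  )
  expect_error(
    growth_velocity(tibble::tibble(time_s = 0:1, height_um = 0:1)),
    "Insufficient"
  )
})

test_that("per-network rates are density x velocity, anchored at the reference", {
  d <- tibble::tibble(
    stress = c(25, 600, 1200),
    velocity = c(7.3, 3.6, 1.8),
    channel = "actin",
    mean_density = c(1, 1.5, 2)
  )
  r <- per_network_rate(d, reference_stress = 25)
  expect_equal(r$per_network_rate[1L], 1)
  expect_equal(r$per_network_rate[2L], (1.5 * 3.6) / (1 * 7.3))
  expect_error(per_network_rate(d, reference_stress = 999), "reference")
  zero <- dplyr::mutate(d, velocity = 0)
  expect_error(per_network_rate(zero, 25), "Normalisation")
})

test_that("per-filament rates divide by the relative barbed-end density", {
  rates <- tibble::tibble(
    stress = c(25, 1000), channel = "CP", per_network_rate = c(1, 0.5)
  )
  be <- tibble::tibble(stress = c(25, 1000), e_rel = c(1, 3.3))
  out <- per_filament_rate(rates, be)
  expect_equal(out$per_filament_rate, c(1, 0.5 / 3.3))
  expect_equal(out$per_filament_rate[2L], 0.1515, tolerance = 1e-3)
  # per-network halves while E triples -> per-filament falls 6-fold
  r2 <- tibble::tibble(stress = c(0, 1), channel = "x", per_network_rate = c(1, 0.5))
  b2 <- tibble::tibble(stress = c(0, 1), e_rel = c(1, 3))
  o2 <- per_filament_rate(r2, b2)
  expect_equal(o2$per_filament_rate[1L] / o2$per_filament_rate[2L], 6)
  expect_error(
    per_filament_rate(rates, dplyr::mutate(be, e_rel = c(0, 1))),
    "positive"
  )
})

test_that("flux balance determines the barbed-end density exactly", {
  expect_equal(barbed_end_density_steady_state(1, 10, 0.1), 1)
  expect_equal(barbed_end_density_steady_state(10, 5, 0.1), 20)
  # inverse proportionality in k_cap
  expect_equal(
    barbed_end_density_steady_state(10, 2.5, 0.1),
    2 * barbed_end_density_steady_state(10, 5, 0.1)
  )
  # composition returns the input nucleation rate exactly
  for (r in c(0.5, 3, 42)) {
    e <- barbed_end_density_steady_state(r, 7, 0.2)
    expect_identical(7 * 0.2 * e, r)
  }
  expect_error(barbed_end_density_steady_state(0, 1, 1), "positive")
})

test_that("exponential decay fits invert their generators", {
  x <- seq(0, 1500, length.out = 9)
  f1 <- fit_decay(x, exp(-x / 300), n_components = 1)
  expect_equal(f1$coefficients$tau, 300, tolerance = 1e-6)
  expect_equal(f1$coefficients$amplitude, 1, tolerance = 1e-6)
  # rescaling y leaves the decay constant unchanged
  f1b <- fit_decay(x, 37 * exp(-x / 300), n_components = 1)
  expect_equal(f1b$coefficients$tau, 300, tolerance = 1e-6)
  # two components, ordered ascending
  y2 <- 0.5 * exp(-x / 50) + 0.5 * exp(-x / 500)
  f2 <- fit_decay(x, y2, n_components = 2)
  expect_equal(f2$coefficients$tau, c(50, 500), tolerance = 0.01)
  expect_equal(f2$coefficients$amplitude, c(0.5, 0.5), tolerance = 0.01)
  # degenerate constant response
  expect_error(fit_decay(x, rep(1, 9)), "Degenerate")
  # tidy/glance/predict surface
  expect_equal(nrow(tidy(f2)), 4L)
  expect_gt(glance(f1)$r.squared, 0.999999)
  expect_equal(predict(f1, tibble::tibble(x = 0)), 1, tolerance = 1e-6)
})

test_that("CP:actin ratio is scale-invariant and flat for matched responses", {
  actin <- c(1, 1.4, 2.1)
  cp <- 0.8 * actin
  r <- mean_filament_length_ratio(actin, cp)
  expect_equal(r, rep(0.8, 3))
  expect_equal(
    mean_filament_length_ratio(2 * actin, 2 * cp),
    r
  )
  expect_error(mean_filament_length_ratio(c(0, 1), c(1, 1)), "positive")
})

test_that("monomer consumption fraction reproduces the worked example", {
  expect_equal(monomer_consumption_fraction(150, 0.01, 5, 150), 0.002)
  expect_lte(monomer_consumption_fraction(150, 0.01, 5, 150), 0.003)
  expect_equal(monomer_consumption_fraction(1, 1, 1, 1), 1)
  # doubling the polymer doubles the fraction
  expect_equal(monomer_consumption_fraction(300, 0.01, 5, 150), 0.004)
})

test_that("mesh size follows the inverse-root law", {
  expect_equal(mesh_size(1.47^2), 1)
  expect_equal(mesh_size(1250), 1.47 / sqrt(1250), tolerance = 1e-12)
  expect_equal(mesh_size(1250), 0.0416, tolerance = 1e-3)
  expect_equal(mesh_size(4 * 100), mesh_size(100) / 2)
  expect_error(mesh_size(0), "positive")
  expect_equal(diffusion_threshold(0.045), 0.018)
})

test_that("baseline subtraction removes the pre-nucleation signal per channel", {
  intensity <- tibble::tibble(
    time_s = rep(0:49, 2),
    channel = rep(c("actin", "CP"), each = 50),
    density = c(rep(0.3, 10), rep(1.3, 40), rep(0.1, 10), rep(0.9, 40))
  )
  out <- subtract_baseline(intensity, c(0, 9))
  expect_equal(unique(out$baseline), c(0.3, 0.1))
  expect_equal(
    out$density[out$channel == "actin" & out$time_s > 10][1L], 1
  )
})
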