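test_that("generators are byte-identical under a fixed seed", {
  cfg <- generator_config(seed = 123)
  expect_identical(gen_afm_trace(cfg), gen_afm_trace(cfg))
  expect_identical(gen_intensity_traces(cfg), gen_intensity_traces(cfg))
  st <- network_states(cfg, c(0, 500, 1000))
  pr <- ratchet_params(f_tether = 0.3, reference_stress = 0)
  expect_identical(
    gen_ratio_dataset(st, pr, seed = 4),
    gen_ratio_dataset(st, pr, seed = 4)
  )
  # and the written CSVs checksum identically
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_table_csv(gen_afm_trace(cfg), f1, seed = 123)
  write_table_csv(gen_afm_trace(cfg), f2, seed = 123)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("a noise-free single-step trace is exactly linear at the set velocity", {
  cfg <- generator_config(
    seed = 1, height_noise_sd = 0, stress_noise_sd = 0,
    stress_steps = tibble::tibble(stress_pa = 0, hold_s = 300)
  )
  tr <- gen_afm_trace(cfg)
  # no previous setpoint: no transient at all
  expect_equal(growth_velocity(tr), 7.3, tolerance = 1e-9)
  seg <- find_steady_segments(tr, min_duration = 100)
  expect_equal(seg$velocity[1L], 7.3, tolerance = 1e-9)
})

test_that("the velocity round-trip through segment detection stays within 2%", {
  cfg <- generator_config(
    seed = 42,
    stress_steps = tibble::tibble(stress_pa = 0, hold_s = 600)
  )
  tr <- gen_afm_trace(cfg)
  seg <- find_steady_segments(tr, min_duration = 120)
  expect_equal(seg$velocity[1L], 7.3, tolerance = 0.02)
})

test_that("zero-noise intensity and AFM traces reproduce the configured flux", {
  cfg <- generator_config(
    seed = 1, height_noise_sd = 0, stress_noise_sd = 0,
    density_noise_sd = 0,
    stress_steps = tibble::tibble(
      stress_pa = c(25, 600, 1200), hold_s = c(400, 400, 400)
    )
  )
  tr <- gen_afm_trace(cfg)
  intensity <- gen_intensity_traces(cfg) |> dplyr::filter(network == "loaded")
  segs <- find_steady_segments(tr, min_duration = 60)
  expect_equal(nrow(segs), 3L)
  dens <- segment_densities(intensity, segs)
  rates <- per_network_rate(dens, reference_stress = 25)
  fr <- force_response(cfg, c(25, 600, 1200))
  for (ch in unique(rates$channel)) {
    got <- rates$per_network_rate[rates$channel == ch]
    expect_equal(got, fr$flux_rel / fr$flux_rel[1L], tolerance = 0.02)
  }
})

test_that("the unloaded control network stays flat within noise", {
  cfg <- generator_config(seed = 9)
  ctrl <- gen_intensity_traces(cfg) |>
    dplyr::filter(network == "control", channel == "actin")
  expect_lt(sd(ctrl$density) / mean(ctrl$density), 0.05)
  fit <- lm(density ~ time_s, data = ctrl)
  # trend indistinguishable from zero drift of meaningful size
  expect_lt(abs(coef(fit)[["time_s"]]) * max(ctrl$time_s), 0.05)
})

test_that("matched channel responses give a load-invariant CP:actin ratio", {
  cfg <- generator_config(seed = 13, density_noise_sd = 0)
  traces <- gen_intensity_traces(cfg) |> dplyr::filter(network == "loaded")
  wide <- traces |>
    tidyr::pivot_wider(names_from = channel, values_from = density)
  r <- mean_filament_length_ratio(wide$actin, wide$CP)
  expect_equal(r, rep(r[1L], length(r)), tolerance = 1e-9)
})

test_that("barbed-end series rises monotonically to 3.3x at the anchor load", {
  cfg <- generator_config()
  be <- gen_barbed_end_series(cfg, c(0, 255, 510, 1020))
  expect_equal(be$e_rel[1L], 1)
  expect_equal(be$e_rel[be$stress == 1020], 3.3)
  expect_true(all(diff(be$e_rel) > 0))
  # monotone for an arbitrary config too
  cfg2 <- generator_config(e_rise = 5, e_stress_scale = 400)
  be2 <- gen_barbed_end_series(cfg2, seq(0, 1200, by = 100))
  expect_true(all(diff(be2$e_rel) > 0))
})

test_that("network states are geometrically consistent across the load range", {
  cfg <- generator_config()
  st <- network_states(cfg, seq(0, 1300, by = 50))
  s <- sin_theta_from_network(st$barbed_end_density, st$polymer_conc)
  expect_true(all(s > 0 & s <= 1))
  expect_true(all(st$velocity > 0))
})

test_that("noise-free ratio datasets are exactly the model prediction", {
  cfg <- generator_config()
  st <- network_states(cfg, c(0, 400, 800, 1300))
  pr <- ratchet_params(f_tether = 0.3, reference_stress = 0)
  d <- gen_ratio_dataset(st, pr, noise_sd = 0)
  expect_equal(d$ratio, wt_bulky_ratio(st, pr)$ratio)
  expect_equal(d$error, rep(0, 4))
  # equal gap sizes: every ratio is 1
  same <- ratchet_params(
    delta_cap_bulky = 2.7, f_tether = 0.3,
    reference_stress = 0
  )
  expect_equal(
    gen_ratio_dataset(st, same, noise_sd = 0)$ratio,
    rep(1, 4)
  )
})

test_that("tether recovery from default-noise datasets is essentially unbiased", {
  cfg <- generator_config()
  stresses <- c(0, 150, 350, 510, 765, 1020, 1150, 1300)
  st <- network_states(cfg, stresses)
  truth <- ratchet_params(f_tether = 0.3, reference_stress = 0)
  set.seed(506)
  ests <- vapply(1:60, function(i) {
    d <- gen_ratio_dataset(st, truth, noise_sd = 0.05)
    fit_tether_force(d, st, truth, n_boot = 0)$estimate
  }, numeric(1))
  expect_lt(abs(mean(ests) - 0.3) / 0.3, 0.05)
})
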