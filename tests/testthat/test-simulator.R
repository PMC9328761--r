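test_that("without capping the filament count never decreases", {
  p <- oracle_sim_params(k_cap0 = 0, k_be = 0.001, area = 0.1, seed = 5)
  traj <- simulate_network(p, duration = 20, init_filaments = 0)
  expect_true(all(diff(traj$samples$free_ends) >= 0))
  expect_equal(nrow(traj$capped), 0L)
  expect_equal(traj$n_capped, 0)
})

test_that("capped lengths follow the geometric elongation/capping race", {
  # no nucleation, unloaded, constant angle: each filament adds a
  # geometric number of subunits (mean k_on0/k_cap0) before capping
  p <- oracle_sim_params(
    k_nuc_max = 0, k_cap0 = 0.5, k_on0 = 20, k_be = 1e-4,
    area = 1, seed = 17,
    ratchet = ratchet_params(f_tether = 0)
  )
  traj <- simulate_network(p,
    duration = 60,
    init_lengths = rep(1, 2000)
  )
  expect_true(all(diff(traj$samples$free_ends) <= 0))
  lens <- traj$capped$length_subunits
  expect_gt(length(lens), 1500)
  expected <- 1 + p$k_on0 / p$k_cap0 # start at 1 subunit
  se <- sd(lens) / sqrt(length(lens))
  expect_lt(abs(mean(lens) - expected), 3 * se + 0.5)
})

test_that("steady-state barbed-end density matches the mean-field fixed point", {
  p <- oracle_sim_params(seed = 23)
  e_oracle <- oracle_fixed_point(p, stress = 0)
  traj <- simulate_network(p, duration = 250)
  s <- suppressWarnings(steady_state_summary(traj, c(60, 250)))
  expect_lt(abs(s$e_mean - e_oracle), 3 * s$e_se)
})

test_that("polymer count equals nucleation plus elongation events exactly", {
  p <- sim_params(seed = 31, area = 0.1)
  traj <- simulate_network(p, duration = 50)
  expect_identical(
    traj$total_subunits,
    traj$n_nucleated + traj$n_elongated + traj$init_subunits
  )
  # stoichiometry: every capped filament carries exactly one nucleus and
  # one capping event, so network CP:Arp2/3 approaches 1 at steady state
  expect_equal(nrow(traj$capped), traj$n_capped)
})

test_that("a fixed seed reproduces the trajectory exactly", {
  p <- sim_params(seed = 99, area = 0.1)
  t1 <- simulate_network(p, duration = 30)
  t2 <- simulate_network(p, duration = 30)
  expect_identical(t1$samples, t2$samples)
  expect_identical(t1$capped, t2$capped)
})

test_that("disjoint steady windows at one stress agree within combined error", {
  p <- oracle_sim_params(seed = 41)
  traj <- simulate_network(p, duration = 300)
  s1 <- suppressWarnings(steady_state_summary(traj, c(50, 170)))
  s2 <- suppressWarnings(steady_state_summary(traj, c(180, 300)))
  expect_lt(
    abs(s1$e_mean - s2$e_mean),
    3 * sqrt(s1$e_se^2 + s2$e_se^2)
  )
})

test_that("a window before any event raises an insufficient-events error", {
  p <- oracle_sim_params(
    k_nuc_max = 1e-9, k_cap0 = 0.2, k_be = 1e-4, seed = 3
  )
  traj <- simulate_network(p, duration = 30, init_filaments = 0)
  expect_error(
    suppressWarnings(steady_state_summary(traj, c(0, 20))),
    "Insufficient events"
  )
})

test_that("across a stress ladder velocity falls and end density rises", {
  set.seed(55)
  stresses <- c(0, 300, 600, 1000)
  ls <- suppressWarnings(
    load_series_experiment(sim_params(), stresses,
      hold = 120, equilibration = 40
    )
  )
  # allow one standard error of slack per step
  tol_e <- 3 * sqrt(ls$e_se[-1]^2 + ls$e_se[-4]^2)
  expect_true(all(diff(ls$e_mean) > -tol_e))
  expect_true(all(diff(ls$velocity) < 0.3))
  expect_true(all(ls$balance_residual < 0.05))
})

test_that("matched gap sizes keep capped filament length load-invariant", {
  set.seed(77)
  stresses <- seq(0, 1000, by = 250)
  ls <- suppressWarnings(
    load_series_experiment(sim_params(), stresses,
      hold = 150, equilibration = 50
    )
  )
  fit <- lm(capped_length_mean ~ stress, data = ls)
  ci <- confint(fit)["stress", ]
  expect_true(ci[1] <= 0 && 0 <= ci[2])
})

test_that("a bulkier capping protein makes filaments lengthen under load", {
  set.seed(78)
  stresses <- seq(0, 1000, by = 250)
  p_bulky <- sim_params(
    ratchet = ratchet_params(delta_cap_wt = 5.4, f_tether = 0.3)
  )
  ls <- suppressWarnings(
    load_series_experiment(p_bulky, stresses,
      hold = 150, equilibration = 50
    )
  )
  expect_true(all(diff(ls$capped_length_mean) > 0))
  fit <- lm(capped_length_mean ~ stress, data = ls)
  expect_gt(confint(fit)["stress", 1], 0)
})

test_that("load coupling pauses when no uncapped filament remains", {
  p <- oracle_sim_params(
    k_nuc_max = 1e-5, k_cap0 = 5, k_on0 = 1, k_be = 1e-4,
    stress_schedule = tibble::tibble(time_s = 0, stress_pa = 500),
    seed = 8
  )
  traj <- simulate_network(p, duration = 20, init_filaments = 3)
  expect_gte(traj$paused_episodes, 1)
})

test_that("trajectory plots assemble without error", {
  p <- sim_params(seed = 2, area = 0.1)
  traj <- simulate_network(p, duration = 20)
  expect_s3_class(autoplot(traj), "ggplot")
})
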