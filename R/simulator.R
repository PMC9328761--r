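#' Parameters for the stochastic network-growth simulator
#'
#' The simulator couples three reactions at the growth surface: nucleation
#' of new filaments by surface NPFs (suppressed by WH2 occupancy, the
#' barbed-end-interference feedback), single-subunit elongation of uncapped
#' filaments, and capping. Elongation and capping rates carry
#' Brownian-Ratchet gap factors with the per-filament force obtained by
#' equal sharing of the clamped stress plus the internal tethering force.
#'
#' The contact angle is the cheap closed form
#' `sin(theta) = min(1, E / (C_A * 602.2 * rise_um))` with the local
#' polymer concentration parameterised as
#' `C_A = polymer_conc0 * (E / e_ref)^polymer_exponent`; an exponent above
#' 1 makes the network densify faster than the end density grows, so the
#' effective angle falls under load. Exponent 0 fixes `C_A`.
#'
#' @param k_nuc_max Per-NPF nucleation rate at zero WH2 occupancy, s^-1.
#'   Default 0.037 s^-1 (unloaded single-molecule estimate).
#' @param npf_density NPF surface density, um^-2. Default 1850.
#' @param area Pattern area, um^2. Default 0.25 (desk-scale patch; rates
#'   are per area, so observables are area-intensive).
#' @param k_on0 Unloaded elongation rate per filament, subunits s^-1
#'   (profilin-actin delivery coarse-grained in). Default 50, which at an
#'   effective angle near 1 gives the observed ~7 um/min unloaded growth.
#' @param k_cap0 Unloaded capping rate per filament, s^-1 (k_cap x CP).
#'   Default 0.25, i.e. a mean length of ~200 subunits.
#' @param k_be Barbed-end/NPF association scale, um^2. `NULL` (default)
#'   calibrates it so the unloaded steady-state WH2 occupancy is
#'   `phi_target`.
#' @param phi_target Target unloaded WH2 occupancy used when `k_be` is
#'   calibrated. Default 0.07.
#' @param ratchet A [ratchet_params()] object (gap sizes, tether force,
#'   constants). Default uses the fitted 0.3 pN tether.
#' @param polymer_conc0 Local polymeric actin concentration at `e_ref`, uM.
#' @param polymer_exponent Exponent of the `C_A(E)` coupling (see Details).
#' @param e_ref Barbed-end density scale of the coupling, um^-2.
#' @param stress_schedule Tibble `time_s`, `stress_pa` of setpoints (first
#'   row must start at 0 s).
#' @param abortive_hazard Optional early-failure hazard for newly nucleated
#'   branches, s^-1 (0 = off). Modelled as an increment to the capping
#'   propensity for filaments below `abortive_window` subunits; whether the
#'   failure rate depends on force is an open experimental question, so no
#'   force dependence is assumed.
#' @param abortive_window Age window (in subunits) of the early-failure
#'   hazard.
#' @param seed Optional RNG seed applied by [simulate_network()].
#'
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(k_nuc_max = 0.037,
                       npf_density = 1850,
                       area = 0.25,
                       k_on0 = 50,
                       k_cap0 = 0.25,
                       k_be = NULL,
                       phi_target = 0.07,
                       ratchet = ratchet_params(f_tether = 0.3),
                       polymer_conc0 = 170,
                       polymer_exponent = 1.8,
                       e_ref = 250,
                       stress_schedule = tibble::tibble(time_s = 0, stress_pa = 0),
                       abortive_hazard = 0,
                       abortive_window = 10,
                       seed = NULL) {
  if (k_nuc_max < 0 || npf_density < 0 || k_on0 < 0 || k_cap0 < 0) {
    abort("All rates must be non-negative.")
  }
  if (area <= 0) abort("`area` must be positive (um^2).")
  if (polymer_conc0 <= 0 || e_ref <= 0) {
    abort("`polymer_conc0` and `e_ref` must be positive.")
  }
  stopifnot(inherits(ratchet, "ratchet_params"))
  if (!all(c("time_s", "stress_pa") %in% names(stress_schedule))) {
    abort("`stress_schedule` needs columns `time_s` and `stress_pa`.")
  }
  if (is.unsorted(stress_schedule$time_s, strictly = TRUE)) {
    abort("`stress_schedule$time_s` must be strictly increasing.")
  }
  if (any(stress_schedule$stress_pa < 0)) {
    abort("Stress setpoints must be non-negative.")
  }
  p <- structure(
    list(
      k_nuc_max = k_nuc_max, npf_density = npf_density, area = area,
      k_on0 = k_on0, k_cap0 = k_cap0, k_be = k_be, phi_target = phi_target,
      ratchet = ratchet, polymer_conc0 = polymer_conc0,
      polymer_exponent = polymer_exponent, e_ref = e_ref,
      stress_schedule = stress_schedule,
      abortive_hazard = abortive_hazard, abortive_window = abortive_window,
      seed = seed
    ),
    class = "sim_params"
  )
  if (is.null(p$k_be)) p$k_be <- calibrate_k_be(p, phi_target)
  p
}

sim_sin_theta <- function(E, params) {
  c_a <- params$polymer_conc0 *
    (E / params$e_ref)^params$polymer_exponent
  rise_um <- params$ratchet$constants$subunit_rise * 1e-3
  pmin(1, pmax(
    E / (c_a * params$ratchet$constants$molarity_to_density * rise_um),
    1e-6
  ))
}

sim_cap_factor <- function(E, stress, params) {
  f_eff <- stress / E + params$ratchet$f_tether
  boltzmann_step_factor(
    f_eff, params$ratchet$delta_cap_wt, sim_sin_theta(E, params),
    constants = params$ratchet$constants
  )
}

#' Mean-field steady-state barbed-end density
#'
#' Deterministic fixed point of the simulator's kinetics: solves
#' `k_nuc_max * npf_density * (1 - phi(E)) = k_cap0 * B(E) * E` for `E`,
#' where `phi` is the WH2-occupancy feedback and `B` the capping gap
#' factor at this stress.
#'
#' @param params A [sim_params()] object.
#' @param stress Applied stress, Pa.
#'
#' @return Fixed-point free-barbed-end density, um^-2.
#' @export
mean_field_barbed_ends <- function(params, stress = 0) {
  stopifnot(inherits(params, "sim_params"))
  g <- function(E) {
    phi <- E * params$k_be / (1 + E * params$k_be)
    params$k_nuc_max * params$npf_density * (1 - phi) -
      params$k_cap0 * sim_cap_factor(E, stress, params) * E
  }
  upper <- params$k_nuc_max * params$npf_density / params$k_cap0 * 50 + 10
  uniroot(g, c(1e-8, upper), tol = 1e-10)$root
}

calibrate_k_be <- function(params, phi_target = 0.07) {
  # at the unloaded fixed point with phi clamped to its target,
  # E* = k_nuc*npf*(1-phi)/(k_cap0*B(E*)); then k_be follows from phi
  if (params$k_cap0 <= 0 || params$k_nuc_max <= 0) {
    return(0) # no feedback calibration possible; disable
  }
  g <- function(E) {
    params$k_nuc_max * params$npf_density * (1 - phi_target) -
      params$k_cap0 * sim_cap_factor(E, 0, params) * E
  }
  upper <- params$k_nuc_max * params$npf_density / params$k_cap0 * 50 + 10
  e_star <- uniroot(g, c(1e-8, upper), tol = 1e-10)$root
  phi_target / ((1 - phi_target) * e_star)
}

#' Simulate branched-network growth under a force clamp
#'
#' Exact stochastic simulation (Gillespie) of nucleation, elongation and
#' capping with force-dependent rates; see [sim_params()] for the model.
#' Fully reproducible under a fixed seed. If at some instant no uncapped
#' filament remains while the clamp stress is nonzero, the load is carried
#' by the boundary, force coupling pauses and the episode is logged in
#' `paused_episodes`.
#'
#' @param params A [sim_params()] object.
#' @param duration Simulated time, s (> 0).
#' @param sample_dt Sampling interval of the trajectory, s.
#' @param init_filaments Initial number of uncapped filaments. `NULL`
#'   (default) seeds from the mean-field fixed point at the first setpoint
#'   with geometric lengths, which shortens equilibration; `0` starts from
#'   a bare surface.
#' @param init_lengths Optional integer vector of explicit initial filament
#'   lengths (subunits); overrides `init_filaments`.
#'
#' @return Object of class `sim_trajectory`: `samples` tibble (`time_s`,
#'   `free_ends` (um^-2), `height_um`, `wh2_occupancy`, `stress_pa`,
#'   `sin_theta`, cumulative `polymer_subunits` and event counters),
#'   `capped` tibble (`time_s`, `length_subunits` of each capped filament),
#'   event totals, `paused_episodes`, and the parameters. Supports
#'   [autoplot()].
#' @export
simulate_network <- function(params, duration, sample_dt = 0.5,
                             init_filaments = NULL, init_lengths = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (duration <= 0) abort("`duration` must be positive (s).")
  if (!is.null(params$seed)) set.seed(params$seed)

  if (!is.null(init_lengths)) {
    if (any(init_lengths < 1)) abort("`init_lengths` must be >= 1 subunit.")
    init_sub <- as.integer(init_lengths)
  } else {
    if (is.null(init_filaments)) {
      e0 <- tryCatch(
        mean_field_barbed_ends(params, params$stress_schedule$stress_pa[1L]),
        error = function(e) 0
      )
      init_filaments <- round(e0 * params$area)
    }
    init_sub <- if (init_filaments > 0) {
      mean_len <- max(params$k_on0 / max(params$k_cap0, 1e-12), 1)
      1L + stats::rgeom(init_filaments, prob = min(1 / mean_len, 1))
    } else {
      integer(0)
    }
  }

  raw <- ssa_run_cpp(
    duration = duration, sample_dt = sample_dt,
    k_nuc_max = params$k_nuc_max, npf_density = params$npf_density,
    area = params$area, k_on0 = params$k_on0, k_cap0 = params$k_cap0,
    k_be = params$k_be,
    delta_actin = params$ratchet$delta_actin,
    delta_cap = params$ratchet$delta_cap_wt,
    f_tether = params$ratchet$f_tether,
    kBT = params$ratchet$constants$kBT,
    subunit_rise_nm = params$ratchet$constants$subunit_rise,
    molarity_to_density = params$ratchet$constants$molarity_to_density,
    polymer_conc0 = params$polymer_conc0,
    polymer_exponent = params$polymer_exponent, e_ref = params$e_ref,
    sched_time = params$stress_schedule$time_s,
    sched_stress = params$stress_schedule$stress_pa,
    init_subunits = as.integer(init_sub), max_events = 5e7,
    k_abort = params$abortive_hazard,
    abort_window_subunits = params$abortive_window
  )
  if (isTRUE(raw$truncated)) {
    warn("Simulation stopped early: event budget exceeded.")
  }
  samples <- tibble::tibble(
    time_s = raw$time_s, free_ends = raw$free_ends,
    height_um = raw$height_um, wh2_occupancy = raw$wh2_occupancy,
    stress_pa = raw$stress_pa, sin_theta = raw$sin_theta,
    polymer_subunits = raw$polymer_subunits,
    nucleation_events = raw$nucleation_events,
    capping_events = raw$capping_events,
    elongation_events = raw$elongation_events
  )
  structure(
    list(
      samples = samples,
      capped = tibble::tibble(
        time_s = raw$cap_time, length_subunits = raw$cap_len
      ),
      n_nucleated = raw$n_nucleated, n_capped = raw$n_capped,
      n_elongated = raw$n_elongated, n_aborted = raw$n_aborted,
      total_subunits = raw$total_subunits,
      init_filaments = length(init_sub), init_subunits = sum(init_sub),
      paused_episodes = raw$paused_episodes,
      duration = duration, params = params
    ),
    class = "sim_trajectory"
  )
}

#' @export
print.sim_trajectory <- function(x, ...) {
  cat(sprintf(
    "<sim_trajectory> %.0f s, %d samples; events: %d nucleation, %d elongation, %d capping\n",
    x$duration, nrow(x$samples), x$n_nucleated, x$n_elongated, x$n_capped
  ))
  invisible(x)
}

#' Time-averaged steady-state observables of a simulated trajectory
#'
#' Averages the trajectory over a window, reporting the free-barbed-end
#' density, growth velocity, polymer/nucleation/capping fluxes (per area),
#' mean capped filament length and WH2 occupancy, each with a standard
#' error, plus the flux-balance residual `|R_cap - R_nuc| / R_nuc`. The
#' barbed-end series is checked for a linear trend at the 5% level; a
#' non-stationary window yields `stationary = FALSE` with a warning.
#'
#' @param traj A `sim_trajectory` from [simulate_network()].
#' @param window Length-2 numeric `c(t0, t1)` within the trajectory.
#' @param n_batches Number of batches for the batch-means standard error of
#'   the barbed-end density.
#'
#' @return One-row tibble of summaries.
#' @export
steady_state_summary <- function(traj, window, n_batches = 8) {
  stopifnot(inherits(traj, "sim_trajectory"))
  if (length(window) != 2L || diff(window) <= 0) {
    abort("`window` must be c(t0, t1) with t1 > t0.")
  }
  s <- dplyr::filter(
    traj$samples,
    .data$time_s >= window[1], .data$time_s <= window[2]
  )
  if (nrow(s) < n_batches * 2L) {
    abort("Window too short for the requested batch count.")
  }
  area <- traj$params$area
  dt <- diff(window)
  d_nuc <- tail(s$nucleation_events, 1) - head(s$nucleation_events, 1)
  d_cap <- tail(s$capping_events, 1) - head(s$capping_events, 1)
  d_poly <- tail(s$polymer_subunits, 1) - head(s$polymer_subunits, 1)
  if (d_nuc == 0 && d_cap == 0) {
    abort("Insufficient events: no nucleation or capping in the window.")
  }

  batch <- cut(s$time_s, n_batches, labels = FALSE)
  bm <- tapply(s$free_ends, batch, mean)
  bt <- tapply(s$time_s, batch, mean)
  e_mean <- mean(s$free_ends)
  e_se <- sd(bm) / sqrt(n_batches)

  # trend test on batch means: raw samples are strongly autocorrelated and
  # would make the test wildly anti-conservative
  tr <- summary(lm(bm ~ bt))$coefficients
  p_trend <- if (nrow(tr) > 1L) tr[2L, "Pr(>|t|)"] else NA_real_
  stationary <- is.na(p_trend) || p_trend > 0.05
  if (!stationary) {
    warn(sprintf(
      "Barbed-end density trends over the window (p = %.3g): not stationary.",
      p_trend
    ))
  }

  flux_nuc <- d_nuc / (dt * area)
  flux_cap <- d_cap / (dt * area)
  flux_nuc_se <- sqrt(d_nuc) / (dt * area)
  flux_cap_se <- sqrt(d_cap) / (dt * area)

  capped <- dplyr::filter(
    traj$capped,
    .data$time_s >= window[1], .data$time_s <= window[2]
  )

  tibble::tibble(
    t_start = window[1], t_end = window[2],
    stress = mean(s$stress_pa),
    e_mean = e_mean, e_se = e_se,
    velocity = linfit(s$time_s, s$height_um)$slope * 60,
    flux_poly = d_poly / (dt * area),
    flux_nuc = flux_nuc, flux_nuc_se = flux_nuc_se,
    flux_cap = flux_cap, flux_cap_se = flux_cap_se,
    balance_residual = if (flux_nuc > 0) {
      abs(flux_cap - flux_nuc) / flux_nuc
    } else {
      NA_real_
    },
    capped_length_mean = if (nrow(capped)) mean(capped$length_subunits) else NA_real_,
    capped_length_se = if (nrow(capped) > 1) {
      sd(capped$length_subunits) / sqrt(nrow(capped))
    } else {
      NA_real_
    },
    n_capped = nrow(capped),
    wh2_occupancy = mean(s$wh2_occupancy),
    stationary = stationary
  )
}

#' In-silico load-series experiment
#'
#' Runs the simulator at each stress in turn (independent runs, each seeded
#' from the mean-field fixed point at its own stress so stationarity is
#' reached quickly), discards an equilibration period, and summarises the
#' steady window. This is the simulated analogue of stepping the force
#' clamp through a ladder of setpoints.
#'
#' @param params A [sim_params()] object (its `stress_schedule` is
#'   replaced per run).
#' @param stresses Ordered numeric vector of stresses, Pa.
#' @param hold Time simulated at each stress, s.
#' @param equilibration Initial time excluded from the summary, s.
#' @param sample_dt Sampling interval, s.
#'
#' @return Tibble with one summary row per stress (see
#'   [steady_state_summary()]).
#' @export
load_series_experiment <- function(params, stresses, hold = 200,
                                   equilibration = 50, sample_dt = 0.5) {
  stopifnot(inherits(params, "sim_params"))
  if (is.unsorted(stresses)) abort("`stresses` must be ordered.")
  if (equilibration >= hold) abort("`equilibration` must be < `hold`.")
  purrr::map_dfr(stresses, function(sg) {
    p <- params
    p$stress_schedule <- tibble::tibble(time_s = 0, stress_pa = sg)
    p$seed <- NULL # RNG stream continues across runs
    traj <- simulate_network(p, duration = hold, sample_dt = sample_dt)
    steady_state_summary(traj, c(equilibration, hold))
  })
}
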