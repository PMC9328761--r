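#' Configuration of the synthetic measurement generators
#'
#' Collects the seed, the stress protocol and the parametric force-response
#' curves the generators share. The response shapes are smooth stand-ins
#' with the qualitative structure of force-clamp measurements on branched
#' networks — per-network flux declining linearly to 50% at the stall-scale
#' stress, TIRF component densities rising with load, free-barbed-end
#' density rising to 3.3x at the high-load setpoint, local polymer
#' concentration rising from 150 uM toward the densest-network value —
#' but they are not fits to any figure.
#'
#' @param seed RNG seed used by the generators.
#' @param stress_steps Tibble `stress_pa`, `hold_s`: the force-clamp
#'   protocol.
#' @param unloaded_velocity Unloaded growth velocity, um/min. Default 7.3.
#' @param adaptation_tau Relaxation time of transients between setpoints, s.
#' @param sample_dt Sampling interval of generated traces, s.
#' @param height_noise_sd Gaussian height noise, um. Default 0.01 (10 nm).
#' @param stress_noise_sd Clamp noise around the setpoint, Pa.
#' @param density_noise_sd Multiplicative intensity noise (fractional).
#' @param stall_stress Stress scale of the linear flux decline, Pa.
#' @param flux_drop Fractional flux drop at `stall_stress` (0.5 = falls to
#'   50%).
#' @param intensity_rise Extra fractional rise of TIRF component density at
#'   `stall_stress` (1 = doubles), shared across channels.
#' @param intensity_exponent Shape exponent of the density rise.
#' @param e_rise Extra relative rise of free-barbed-end density at
#'   `e_stress_scale` (2.3 = reaches 3.3x).
#' @param e_stress_scale Stress at which the barbed-end rise is anchored,
#'   Pa (1020, the high-load single-molecule condition).
#' @param e0 Absolute unloaded free-barbed-end density, um^-2.
#' @param polymer_conc0 Unloaded local polymeric actin concentration, uM.
#' @param polymer_rise Extra relative rise of polymer concentration at
#'   `polymer_stress_scale`.
#' @param polymer_shape_exponent Shape exponent of the polymer rise; below
#'   1 the network densifies steeply at low load and saturates, so the
#'   effective filament contact angle drops early and then stays low.
#' @param polymer_stress_scale Stress anchor of the polymer rise, Pa.
#' @param channel_base Named base intensities per channel (arbitrary
#'   units).
#'
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(seed = 1,
                             stress_steps = tibble::tibble(
                               stress_pa = c(0, 255, 510, 1020),
                               hold_s = c(300, 300, 300, 300)
                             ),
                             unloaded_velocity = 7.3,
                             adaptation_tau = 20,
                             sample_dt = 1,
                             height_noise_sd = 0.01,
                             stress_noise_sd = 2,
                             density_noise_sd = 0.02,
                             stall_stress = 1200,
                             flux_drop = 0.5,
                             intensity_rise = 1,
                             intensity_exponent = 0.7,
                             e_rise = 2.3,
                             e_stress_scale = 1020,
                             e0 = 230,
                             polymer_conc0 = 150,
                             polymer_rise = 7.3,
                             polymer_stress_scale = 1300,
                             polymer_shape_exponent = 0.6,
                             channel_base = c(
                               actin = 1, CP = 0.8, `Arp2/3` = 0.6
                             )) {
  if (!all(c("stress_pa", "hold_s") %in% names(stress_steps))) {
    abort("`stress_steps` needs columns `stress_pa` and `hold_s`.")
  }
  if (any(stress_steps$hold_s <= 0)) abort("Hold durations must be positive.")
  if (any(stress_steps$stress_pa < 0)) abort("Stresses must be non-negative.")
  noise <- c(height_noise_sd, stress_noise_sd, density_noise_sd)
  if (any(noise < 0)) abort("Noise levels must be non-negative.")
  if (unloaded_velocity <= 0) abort("`unloaded_velocity` must be positive.")
  structure(
    list(
      seed = seed, stress_steps = stress_steps,
      unloaded_velocity = unloaded_velocity,
      adaptation_tau = adaptation_tau, sample_dt = sample_dt,
      height_noise_sd = height_noise_sd, stress_noise_sd = stress_noise_sd,
      density_noise_sd = density_noise_sd,
      stall_stress = stall_stress, flux_drop = flux_drop,
      intensity_rise = intensity_rise,
      intensity_exponent = intensity_exponent,
      e_rise = e_rise, e_stress_scale = e_stress_scale, e0 = e0,
      polymer_conc0 = polymer_conc0, polymer_rise = polymer_rise,
      polymer_stress_scale = polymer_stress_scale,
      polymer_shape_exponent = polymer_shape_exponent,
      channel_base = channel_base
    ),
    class = "generator_config"
  )
}

# ---- force-response curves (ground truth of the generators) ----

#' Ground-truth force-response curves of the generator
#'
#' Evaluates the parametric response curves of a [generator_config()] at
#' given stresses. These are the quantities the analysis stages should
#' recover from generated data.
#'
#' @param config A [generator_config()].
#' @param stress Stresses, Pa.
#'
#' @return Tibble `stress`, `flux_rel` (per-network flux relative to 0 Pa),
#'   `intensity_rel`, `velocity` (um/min), `e_rel` (relative to 0 Pa),
#'   `polymer_conc` (uM).
#' @export
force_response <- function(config, stress) {
  stopifnot(inherits(config, "generator_config"))
  tibble::tibble(
    stress = stress,
    flux_rel = gen_flux_rel(config, stress),
    intensity_rel = gen_intensity_rel(config, stress),
    velocity = gen_velocity(config, stress),
    e_rel = gen_e_rel(config, stress),
    polymer_conc = gen_polymer_conc(config, stress)
  )
}

gen_flux_rel <- function(config, stress) {
  pmax(1 - config$flux_drop * stress / config$stall_stress, 0.05)
}

gen_intensity_rel <- function(config, stress) {
  1 + config$intensity_rise *
    (stress / config$stall_stress)^config$intensity_exponent
}

# velocity defined so density x velocity reproduces the linear flux decline
gen_velocity <- function(config, stress) {
  config$unloaded_velocity * gen_flux_rel(config, stress) /
    gen_intensity_rel(config, stress)
}

gen_e_rel <- function(config, stress) {
  1 + config$e_rise * stress / config$e_stress_scale
}

gen_polymer_conc <- function(config, stress) {
  config$polymer_conc0 *
    (1 + config$polymer_rise *
      (stress / config$polymer_stress_scale)^config$polymer_shape_exponent)
}

# ---- generators ----

#' Generate a synthetic force-clamp (AFM) trace
#'
#' Height and stress versus time for the configured setpoint protocol: at
#' each setpoint the growth velocity relaxes exponentially (time constant
#' `adaptation_tau`) from the previous steady velocity to the new one, so
#' height shows a transient followed by linear steady growth. Gaussian
#' noise is added to height and stress.
#'
#' @param config A [generator_config()].
#'
#' @return Tibble `time_s`, `height_um`, `stress_pa` (seed recorded in the
#'   `"seed"` attribute).
#' @export
gen_afm_trace <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  dt <- config$sample_dt
  tau <- config$adaptation_tau
  steps <- config$stress_steps
  out <- vector("list", nrow(steps))
  t0 <- 0
  h0 <- 0
  v_prev <- gen_velocity(config, steps$stress_pa[1L]) / 60 # um/s; no initial transient
  for (k in seq_len(nrow(steps))) {
    v_k <- gen_velocity(config, steps$stress_pa[k]) / 60
    tt <- seq(0, steps$hold_s[k] - dt, by = dt)
    h <- h0 + v_k * tt + (v_prev - v_k) * tau * (1 - exp(-tt / tau))
    out[[k]] <- tibble::tibble(
      time_s = t0 + tt,
      height_um = h,
      stress_pa = steps$stress_pa[k]
    )
    t0 <- t0 + steps$hold_s[k]
    h0 <- h[length(h)] + v_k * dt
    v_prev <- v_k + (v_prev - v_k) * exp(-tail(tt, 1L) / tau)
  }
  tr <- dplyr::bind_rows(out)
  tr$height_um <- tr$height_um + rnorm(nrow(tr), 0, config$height_noise_sd)
  tr$stress_pa <- pmax(
    tr$stress_pa + rnorm(nrow(tr), 0, config$stress_noise_sd), 0
  )
  attr(tr, "seed") <- config$seed
  tr
}

#' Generate synthetic TIRF intensity traces aligned to the AFM protocol
#'
#' Per-channel component densities with per-setpoint plateaus at the
#' configured force response, shared relaxation transients, and
#' channel-specific multiplicative noise. An unloaded control network held
#' at constant density over the whole protocol is included
#' (`network = "control"`).
#'
#' @param config A [generator_config()].
#'
#' @return Tibble `time_s`, `channel`, `density`, `network`
#'   (`"loaded"`/`"control"`).
#' @export
gen_intensity_traces <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed + 1L)
  dt <- config$sample_dt
  tau <- config$adaptation_tau
  steps <- config$stress_steps
  grid <- vector("list", nrow(steps))
  t0 <- 0
  d_prev <- gen_intensity_rel(config, steps$stress_pa[1L])
  for (k in seq_len(nrow(steps))) {
    d_k <- gen_intensity_rel(config, steps$stress_pa[k])
    tt <- seq(0, steps$hold_s[k] - dt, by = dt)
    grid[[k]] <- tibble::tibble(
      time_s = t0 + tt,
      rel = d_k + (d_prev - d_k) * exp(-tt / tau)
    )
    t0 <- t0 + steps$hold_s[k]
    d_prev <- d_k + (d_prev - d_k) * exp(-tail(tt, 1L) / tau)
  }
  grid <- dplyr::bind_rows(grid)
  channels <- names(config$channel_base)
  loaded <- purrr::map_dfr(channels, function(ch) {
    base <- config$channel_base[[ch]]
    n <- nrow(grid)
    tibble::tibble(
      time_s = grid$time_s, channel = ch,
      density = base * grid$rel *
        (1 + rnorm(n, 0, config$density_noise_sd)),
      network = "loaded"
    )
  })
  control <- purrr::map_dfr(channels, function(ch) {
    base <- config$channel_base[[ch]]
    n <- nrow(grid)
    tibble::tibble(
      time_s = grid$time_s, channel = ch,
      density = base * (1 + rnorm(n, 0, config$density_noise_sd)),
      network = "control"
    )
  })
  out <- dplyr::bind_rows(loaded, control)
  out$density <- pmax(out$density, 0)
  attr(out, "seed") <- config$seed + 1L
  out
}

#' Generate a relative free-barbed-end density series
#'
#' Monotone increasing relative barbed-end density versus stress,
#' normalised to the unloaded network and reaching 1 + `e_rise` (default
#' 3.3x) at the high-load anchor stress.
#'
#' @param config A [generator_config()].
#' @param stresses Stresses, Pa; default the configured setpoints.
#'
#' @return Tibble `stress`, `e_rel`.
#' @export
gen_barbed_end_series <- function(config, stresses = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(stresses)) stresses <- config$stress_steps$stress_pa
  tibble::tibble(stress = stresses, e_rel = gen_e_rel(config, stresses))
}

#' Network states (absolute composition) per load
#'
#' Absolute barbed-end densities and local polymer concentrations implied
#' by the configured force response, as consumed by the ratchet model
#' ([wt_bulky_ratio()], [fit_tether_force()]).
#'
#' @param config A [generator_config()].
#' @param stresses Stresses, Pa.
#'
#' @return A [network_state()] tibble.
#' @export
network_states <- function(config, stresses) {
  stopifnot(inherits(config, "generator_config"))
  network_state(
    stress = stresses,
    barbed_end_density = config$e0 * gen_e_rel(config, stresses),
    polymer_conc = gen_polymer_conc(config, stresses),
    velocity = gen_velocity(config, stresses)
  )
}

#' Generate a synthetic wildtype/bulky incorporation-ratio dataset
#'
#' Emulates the spiked-in two-colour capping-protein measurement: the
#' ground-truth ratio at each load comes from the Brownian-Ratchet model
#' ([wt_bulky_ratio()]) with the supplied tether force, and each load is
#' measured as the mean of `n_replicates` independent observations carrying
#' multiplicative log-normal noise.
#'
#' @param states A [network_state()] tibble (see [network_states()]);
#'   must include the reference load of `params`.
#' @param params A [ratchet_params()] object; its `f_tether` is the
#'   generating ground truth.
#' @param noise_sd Log-normal noise per replicate (sdlog). Default 0.05.
#' @param n_replicates Replicates per load. Default 4.
#' @param seed Optional RNG seed.
#'
#' @return Tibble `stress`, `ratio` (replicate mean), `error` (SEM),
#'   `true_ratio`.
#' @export
gen_ratio_dataset <- function(states, params, noise_sd = 0.05,
                              n_replicates = 4, seed = NULL) {
  stopifnot(inherits(params, "ratchet_params"))
  if (!is.null(seed)) set.seed(seed)
  truth <- wt_bulky_ratio(states, params)
  purrr::map_dfr(seq_len(nrow(truth)), function(i) {
    if (noise_sd > 0) {
      reps <- truth$ratio[i] * exp(rnorm(n_replicates, 0, noise_sd))
      tibble::tibble(
        stress = truth$stress[i],
        ratio = mean(reps),
        error = sd(reps) / sqrt(n_replicates),
        true_ratio = truth$ratio[i]
      )
    } else {
      tibble::tibble(
        stress = truth$stress[i], ratio = truth$ratio[i],
        error = 0, true_ratio = truth$ratio[i]
      )
    }
  })
}
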