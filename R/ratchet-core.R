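#' Brownian-Ratchet gap-opening factor
#'
#' Probability factor by which an insertion reaction (monomer addition or
#' capping) is slowed when a filament pushes against a loaded surface:
#' thermal fluctuations must open a gap of size `delta` against the effective
#' force, so the rate is scaled by `exp(-f_eff * delta * sin_theta / kBT)`.
#'
#' @param f_eff Effective force per filament, pN (>= 0). Includes any
#'   internal tethering contribution.
#' @param delta Gap size required for insertion, nm (> 0).
#' @param sin_theta Sine of the filament contact angle with the surface,
#'   in (0, 1].
#' @param constants A [physical_constants()] object.
#'
#' @return Dimensionless factor in (0, 1]; exactly 1 iff `f_eff == 0`.
#'   Vectorised over `f_eff`, `delta` and `sin_theta`.
#' @export
#'
#' @examples
#' boltzmann_step_factor(0, 2.7, 0.5)         # 1: no force, no slowdown
#' boltzmann_step_factor(1, 2.7, 0.6)         # ~0.67 at 1 pN
boltzmann_step_factor <- function(f_eff, delta, sin_theta,
                                  constants = physical_constants()) {
  if (any(!is.finite(f_eff)) || any(f_eff < 0)) {
    abort("`f_eff` must be finite and non-negative (pN).")
  }
  if (any(!is.finite(delta)) || any(delta <= 0)) {
    abort("`delta` must be finite and positive (nm).")
  }
  if (any(!is.finite(sin_theta)) || any(sin_theta <= 0) || any(sin_theta > 1)) {
    abort("`sin_theta` must lie in (0, 1].")
  }
  exp(-f_eff * delta * sin_theta / constants$kBT)
}

#' Effective filament contact angle from network composition
#'
#' A single effective angle estimated from the density of free barbed ends
#' and the polymeric actin concentration: the filament length per unit
#' volume is `L_v = polymer_conc * molarity_to_density * subunit_rise` (in
#' um of filament per um^3), and geometry bounds the areal density of ends
#' that length density can present at the surface by `L_v * sin(theta)`.
#'
#' @param barbed_end_density Free barbed ends per area, um^-2 (> 0).
#' @param polymer_conc Polymeric actin concentration, uM (> 0).
#' @param constants A [physical_constants()] object.
#' @param tol Relative slack above 1 tolerated before erroring (guards
#'   floating-point noise only; values within `tol` are clamped to 1).
#'
#' @return sin(theta) in (0, 1], vectorised. A ratio materially above 1
#'   (more ends per area than the filament length density allows) is a
#'   geometric inconsistency and raises an error rather than being clamped.
#' @export
#'
#' @examples
#' sin_theta_from_network(150, 150)  # ~0.615
sin_theta_from_network <- function(barbed_end_density, polymer_conc,
                                   constants = physical_constants(),
                                   tol = 1e-9) {
  if (any(!is.finite(barbed_end_density)) || any(barbed_end_density <= 0)) {
    abort("`barbed_end_density` must be finite and positive (um^-2).")
  }
  if (any(!is.finite(polymer_conc)) || any(polymer_conc <= 0)) {
    abort("`polymer_conc` must be finite and positive (uM).")
  }
  rise_um <- constants$subunit_rise * 1e-3
  l_v <- polymer_conc * constants$molarity_to_density * rise_um # um^-2
  ratio <- barbed_end_density / l_v
  if (any(ratio > 1 + tol)) {
    abort(paste0(
      "Geometric inconsistency: barbed_end_density / filament length density = ",
      sprintf("%.4g", max(ratio)),
      " exceeds 1; more free ends per area than the polymer density allows."
    ))
  }
  pmin(ratio, 1)
}

#' Force carried by a single filament
#'
#' The external growth stress divided equally over the free barbed ends:
#' with stress in Pa (= pN/um^2) and ends in um^-2 the quotient is directly
#' the force per filament in pN.
#'
#' @param stress Applied growth stress, Pa (>= 0).
#' @param barbed_end_density Free barbed ends per area, um^-2 (> 0).
#'
#' @return Force per filament, pN. Vectorised.
#' @export
#'
#' @examples
#' force_per_filament(1276, 400)  # 3.19 pN
force_per_filament <- function(stress, barbed_end_density) {
  if (any(!is.finite(stress)) || any(stress < 0)) {
    abort("`stress` must be finite and non-negative (Pa).")
  }
  if (any(!is.finite(barbed_end_density)) || any(barbed_end_density <= 0)) {
    abort("`barbed_end_density` must be finite and positive (um^-2).")
  }
  stress / barbed_end_density
}

#' Per-load network state table
#'
#' Convenience constructor validating the per-load snapshot used by the
#' ratchet model: applied stress, free-barbed-end density and polymeric
#' actin concentration (optionally velocity and per-channel densities).
#'
#' @param stress Stress, Pa (>= 0).
#' @param barbed_end_density Free barbed ends, um^-2 (> 0).
#' @param polymer_conc Polymeric actin, uM (> 0).
#' @param ... Further per-load columns (e.g. `velocity`), recycled by
#'   [tibble::tibble()].
#'
#' @return A tibble with one row per load.
#' @export
network_state <- function(stress, barbed_end_density, polymer_conc, ...) {
  if (any(stress < 0)) abort("`stress` must be non-negative (Pa).")
  if (any(barbed_end_density <= 0)) {
    abort("`barbed_end_density` must be positive (um^-2).")
  }
  if (any(polymer_conc <= 0)) abort("`polymer_conc` must be positive (uM).")
  tibble::tibble(
    stress = stress,
    barbed_end_density = barbed_end_density,
    polymer_conc = polymer_conc,
    ...
  )
}

state_ratchet_factor <- function(states, delta, params) {
  f_ext <- force_per_filament(states$stress, states$barbed_end_density)
  s <- sin_theta_from_network(
    states$barbed_end_density, states$polymer_conc,
    constants = params$constants
  )
  boltzmann_step_factor(f_ext + params$f_tether, delta, s,
    constants = params$constants
  )
}

#' Insertion rate at load relative to a reference state
#'
#' Ratio of the Brownian-Ratchet gap factors between a loaded and a
#' reference network state, for a given gap size. The effective force in
#' each state is the equally-shared external force per filament plus the
#' internal tethering force; the contact angle is recomputed per state from
#' its composition.
#'
#' @param state_load,state_ref Single-row network-state tibbles (see
#'   [network_state()]) with columns `stress`, `barbed_end_density`,
#'   `polymer_conc`.
#' @param delta Gap size, nm.
#' @param params A [ratchet_params()] object (supplies `f_tether` and
#'   constants).
#'
#' @return Dimensionless normalised rate constant; 1 for identical states.
#' @export
relative_insertion_rate <- function(state_load, state_ref, delta, params) {
  stopifnot(inherits(params, "ratchet_params"))
  state_ratchet_factor(state_load, delta, params) /
    state_ratchet_factor(state_ref, delta, params)
}

#' Predicted wildtype/bulky capping-protein incorporation ratio
#'
#' For each load, the ratio of the normalised wildtype insertion rate to the
#' normalised bulky-variant insertion rate, each normalised to the reference
#' load. Because the bulky variant needs a larger gap, its capping rate
#' falls faster with force and the ratio grows with stress.
#'
#' @param states Network-state tibble (one row per load) containing the
#'   reference load `params$reference_stress`.
#' @param params A [ratchet_params()] object.
#'
#' @return A tibble `stress`, `ratio` with `ratio == 1` at the reference
#'   load.
#' @export
wt_bulky_ratio <- function(states, params) {
  stopifnot(inherits(params, "ratchet_params"))
  ref_idx <- which(abs(states$stress - params$reference_stress) < 1e-9)
  if (length(ref_idx) == 0L) {
    abort(sprintf(
      "`states` must include the reference load (%g Pa).",
      params$reference_stress
    ))
  }
  ref <- states[ref_idx[1L], ]
  wt <- relative_insertion_rate(states, ref, params$delta_cap_wt, params)
  bulky <- relative_insertion_rate(states, ref, params$delta_cap_bulky, params)
  tibble::tibble(stress = states$stress, ratio = wt / bulky)
}

#' Fit the internal tethering force to wt/bulky ratio data
#'
#' One-parameter least-squares fit of the Brownian-Ratchet prediction
#' ([wt_bulky_ratio()]) to a measured (or synthetic) table of
#' wildtype/bulky incorporation ratios versus stress. Gap sizes, contact
#' angles and per-filament forces are fixed by `params` and `states`; only
#' the tethering force is free. The misfit is evaluated on log ratios —
#' unweighted by default, since multiplicative measurement noise is
#' homoscedastic on that scale and inverse-variance weights estimated from
#' a handful of replicates are noisy enough to inflate the estimator
#' variance — and a residual bootstrap provides a confidence interval.
#'
#' @param ratio_data Tibble with columns `stress`, `ratio`, and optionally
#'   `error` (same units as `ratio`).
#' @param states Network-state tibble covering the same stresses (matched by
#'   value) plus the reference load.
#' @param params A [ratchet_params()] object; its `f_tether` is ignored
#'   (that is the parameter being estimated).
#' @param upper Upper bound of the search interval, pN.
#' @param n_boot Number of residual-bootstrap replicates.
#' @param conf_level Confidence level for the bootstrap interval.
#' @param weighted Weight log-ratio residuals by inverse squared relative
#'   error (requires an `error` column). Default `FALSE`.
#'
#' @return An object of class `tether_fit` with elements `estimate` (pN),
#'   `conf_int`, `boot` (bootstrap draws), `fitted` (data plus model
#'   ratios), `n`. Supports [tidy()], [glance()] and [autoplot()].
#' @export
fit_tether_force <- function(ratio_data, states, params,
                             upper = 10, n_boot = 200, conf_level = 0.95,
                             weighted = FALSE) {
  stopifnot(inherits(params, "ratchet_params"))
  req <- c("stress", "ratio")
  if (!all(req %in% names(ratio_data))) {
    abort("`ratio_data` needs columns `stress` and `ratio`.")
  }
  if (length(unique(ratio_data$stress)) < 3L) {
    abort("Tether force is not identifiable: need >= 3 distinct loads.")
  }
  if (diff(range(ratio_data$stress)) <= 0) {
    abort("Tether force is not identifiable: all loads are equal.")
  }

  # model ratios at the data stresses for a trial tether force
  model_at <- function(f_t) {
    p <- params
    p$f_tether <- f_t
    pred <- wt_bulky_ratio(states, p)
    pred$ratio[match(ratio_data$stress, pred$stress)]
  }
  if (anyNA(model_at(0))) {
    abort("Every stress in `ratio_data` must appear in `states`.")
  }

  w <- rep(1, nrow(ratio_data))
  if (weighted) {
    if (!"error" %in% names(ratio_data)) {
      abort("`weighted = TRUE` requires an `error` column.")
    }
    rel <- ratio_data$error / ratio_data$ratio
    w <- ifelse(rel > 0, 1 / rel^2, max(1 / rel[rel > 0]^2, 1))
  }
  obj <- function(f_t, y) sum(w * (log(y) - log(model_at(f_t)))^2)

  fit_once <- function(y) {
    optimize(obj, c(0, upper), y = y)$minimum
  }
  est <- fit_once(ratio_data$ratio)
  fitted_ratio <- model_at(est)
  n <- nrow(ratio_data)
  # inflate residuals for the one fitted parameter, and use a t-interval on
  # the bootstrap spread: with few loads the plain percentile interval of a
  # residual bootstrap undercovers
  resid_log <- (log(ratio_data$ratio) - log(fitted_ratio)) * sqrt(n / (n - 1))

  boot <- vapply(seq_len(n_boot), function(i) {
    y_star <- exp(log(fitted_ratio) + sample(resid_log, replace = TRUE))
    fit_once(y_star)
  }, numeric(1))
  alpha <- (1 - conf_level) / 2
  ci <- if (n_boot > 1) {
    pmax(est + stats::qt(c(alpha, 1 - alpha), df = n - 1) * sd(boot), 0)
  } else {
    c(NA_real_, NA_real_)
  }

  structure(
    list(
      estimate = est,
      conf_int = ci,
      conf_level = conf_level,
      boot = boot,
      fitted = dplyr::mutate(ratio_data, model_ratio = fitted_ratio),
      residual_ss = obj(est, ratio_data$ratio),
      n = nrow(ratio_data),
      params = params
    ),
    class = "tether_fit"
  )
}

#' @export
print.tether_fit <- function(x, ...) {
  cat("<tether_fit>\n")
  cat(sprintf(
    "  f_tether = %.3f pN  [%0.f%% CI %.3f, %.3f]  (n = %d loads)\n",
    x$estimate, 100 * x$conf_level, x$conf_int[1], x$conf_int[2], x$n
  ))
  invisible(x)
}

#' @export
tidy.tether_fit <- function(x, ...) {
  tibble::tibble(
    term = "f_tether",
    estimate = x$estimate,
    conf.low = x$conf_int[1],
    conf.high = x$conf_int[2]
  )
}

#' @export
glance.tether_fit <- function(x, ...) {
  tibble::tibble(
    nobs = x$n,
    residual.ss = x$residual_ss,
    conf.level = x$conf_level,
    n.boot = length(x$boot)
  )
}
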