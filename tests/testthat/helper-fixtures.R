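# Shared fixtures: small exact traces and default parameter bundles used
# across test files. Everything is built in code; no stored data.

# exact two-phase force-clamp trace: linear growth at v1 then v2 (um/min),
# joined by a short stress ramp
exact_two_step_trace <- function(v1 = 7.3, v2 = 2.0,
                                 s1 = 25, s2 = 500,
                                 hold = 120, dt = 1) {
  t1 <- seq(0, hold - dt, by = dt)
  ramp_t <- seq(hold, hold + 4, by = dt)
  t2 <- seq(hold + 5, 2 * hold, by = dt)
  h1 <- v1 / 60 * t1
  h_ramp <- max(h1) + v1 / 60 * (ramp_t - max(t1))
  h2 <- max(h_ramp) + v2 / 60 * (t2 - max(ramp_t))
  tibble::tibble(
    time_s = c(t1, ramp_t, t2),
    height_um = c(h1, h_ramp, h2),
    stress_pa = c(
      rep(s1, length(t1)),
      seq(s1, s2, length.out = length(ramp_t)),
      rep(s2, length(t2))
    )
  )
}

# network states with constant contact angle (polymer proportional to E)
# so only the external force varies between loads
flat_angle_states <- function(stresses, e0 = 150, conc0 = 150) {
  network_state(
    stress = stresses,
    barbed_end_density = e0 * (1 + stresses / 500),
    polymer_conc = conc0 * (1 + stresses / 500)
  )
}

# fast desk-scale simulator parameters for oracle comparisons: constant
# polymer concentration decouples the contact angle from E
oracle_sim_params <- function(..., polymer_conc0 = 400,
                              polymer_exponent = 0, k_on0 = 5) {
  sim_params(
    k_on0 = k_on0, polymer_conc0 = polymer_conc0,
    polymer_exponent = polymer_exponent, ...
  )
}

# independent mean-field oracle: scalar fixed point solved from the rate
# laws written out directly (no package internals)
oracle_fixed_point <- function(p, stress = 0) {
  rise_um <- p$ratchet$constants$subunit_rise * 1e-3
  g <- function(E) {
    c_a <- p$polymer_conc0 * (E / p$e_ref)^p$polymer_exponent
    s <- min(1, max(E / (c_a * 602.2 * rise_um), 1e-6))
    f <- stress / E + p$ratchet$f_tether
    b_cap <- exp(-f * p$ratchet$delta_cap_wt * s / p$ratchet$constants$kBT)
    phi <- E * p$k_be / (1 + E * p$k_be)
    p$k_nuc_max * p$npf_density * (1 - phi) - p$k_cap0 * b_cap * E
  }
  stats::uniroot(g, c(1e-6, 1e6), tol = 1e-10)$root
}
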