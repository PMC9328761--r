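#' Detect steady-growth segments in a force-clamp trace
#'
#' A growing network responds to each new stress setpoint with a transient
#' before settling into linear, steady-state height growth. This finds the
#' maximal windows in which (i) the stress stays within a tolerance of its
#' window median, (ii) height versus time is linear (r-squared at least
#' `r2_min`), and (iii) the window lasts at least `min_duration`. The
#' transient head of each constant-stress epoch is trimmed until the linear
#' fit qualifies.
#'
#' @param trace Tibble/data frame with columns `time_s`, `height_um`,
#'   `stress_pa`; `time_s` strictly increasing.
#' @param min_duration Minimum segment duration, s.
#' @param stress_tol Allowed deviation of stress from the window median, Pa.
#'   `NULL` (default) uses 2% of the window median, floored at 10 Pa so
#'   clamp noise around low setpoints (including the zero-load clamp) does
#'   not shred epochs.
#' @param r2_min Minimum r-squared of the height-time linear fit. A segment
#'   with (numerically) zero height variance counts as perfectly linear,
#'   so a stalled network at constant stress is still one segment with
#'   velocity 0.
#'
#' @return Tibble of segments, ordered and non-overlapping: `t_start`,
#'   `t_end`, `stress` (window median, Pa), `velocity` (um/min),
#'   `r_squared`, `n_points`. Zero rows when nothing qualifies.
#' @export
find_steady_segments <- function(trace, min_duration = 60,
                                 stress_tol = NULL, r2_min = 0.99) {
  validate_afm_trace(trace)
  if (min_duration <= 0) abort("`min_duration` must be positive (s).")
  if (!is.null(stress_tol) && stress_tol <= 0) {
    abort("`stress_tol` must be positive (Pa) or NULL.")
  }
  if (r2_min < 0 || r2_min > 1) abort("`r2_min` must lie in [0, 1].")

  tol_for <- function(setpoint) {
    if (!is.null(stress_tol)) stress_tol else max(0.02 * abs(setpoint), 10)
  }

  # split into epochs of near-constant stress (greedy, running median)
  n <- nrow(trace)
  epoch <- integer(n)
  cur <- 1L
  start <- 1L
  epoch[1L] <- cur
  for (i in 2L:max(n, 2L)) {
    if (i > n) break
    med <- median(trace$stress_pa[start:(i - 1L)])
    if (abs(trace$stress_pa[i] - med) > tol_for(med)) {
      cur <- cur + 1L
      start <- i
    }
    epoch[i] <- cur
  }

  segs <- lapply(split(seq_len(n), epoch), function(idx) {
    steady_tail(trace[idx, , drop = FALSE], min_duration, tol_for, r2_min)
  })
  out <- dplyr::bind_rows(segs)
  if (nrow(out) == 0L) {
    return(tibble::tibble(
      t_start = numeric(), t_end = numeric(), stress = numeric(),
      velocity = numeric(), r_squared = numeric(), n_points = integer()
    ))
  }
  dplyr::arrange(out, .data$t_start)
}

# trim the transient head of one constant-stress epoch until linear
steady_tail <- function(piece, min_duration, tol_for, r2_min) {
  n <- nrow(piece)
  if (n < 3L) return(NULL)
  med <- median(piece$stress_pa)
  if (any(abs(piece$stress_pa - med) > tol_for(med))) return(NULL)
  t <- piece$time_s
  h <- piece$height_um
  for (k in seq_len(n - 2L)) {
    tt <- t[k:n]
    if (tt[length(tt)] - tt[1L] < min_duration) return(NULL)
    fit <- linfit(tt, h[k:n])
    if (fit$r_squared >= r2_min) {
      return(tibble::tibble(
        t_start = tt[1L], t_end = tt[length(tt)], stress = med,
        velocity = fit$slope * 60, r_squared = fit$r_squared,
        n_points = n - k + 1L
      ))
    }
  }
  NULL
}

linfit <- function(t, y) {
  tc <- t - mean(t)
  yc <- y - mean(y)
  sxx <- sum(tc^2)
  slope <- sum(tc * yc) / sxx
  sst <- sum(yc^2)
  sse <- sst - slope^2 * sxx
  r2 <- if (sst < 1e-18) 1 else max(0, 1 - sse / sst)
  list(slope = slope, r_squared = r2)
}

#' Growth velocity from a steady trace window
#'
#' Ordinary least-squares slope of height versus time over a window already
#' judged steady, converted to um/min.
#'
#' @param trace Tibble with `time_s` (strictly increasing) and `height_um`;
#'   at least 3 rows.
#'
#' @return Velocity in um/min (scalar).
#' @export
#'
#' @examples
#' tr <- tibble::tibble(time_s = 0:59, height_um = 0.1216 * (0:59))
#' growth_velocity(tr)  # 7.3 um/min
growth_velocity <- function(trace) {
  if (!all(c("time_s", "height_um") %in% names(trace))) {
    abort("`trace` needs columns `time_s` and `height_um`.")
  }
  if (nrow(trace) < 3L) {
    abort("Insufficient data: need at least 3 samples for a slope.")
  }
  if (any(diff(trace$time_s) <= 0)) {
    abort("`time_s` must be strictly increasing.")
  }
  linfit(trace$time_s, trace$height_um)$slope * 60
}

#' Subtract a pre-nucleation baseline from intensity traces
#'
#' A constant per-channel baseline (NPF-bound signal) quantified during the
#' lag phase preceding network nucleation is subtracted from each channel.
#'
#' @param intensity Tibble with `time_s`, `channel`, `density`.
#' @param lag_window Length-2 numeric `c(t0, t1)` delimiting the lag phase.
#'
#' @return The intensity tibble with baseline-corrected `density` (floored
#'   at 0) and a `baseline` column.
#' @export
subtract_baseline <- function(intensity, lag_window) {
  validate_intensity_trace(intensity)
  if (length(lag_window) != 2L || diff(lag_window) <= 0) {
    abort("`lag_window` must be c(t0, t1) with t1 > t0.")
  }
  intensity |>
    dplyr::group_by(.data$channel) |>
    dplyr::mutate(
      baseline = mean(.data$density[.data$time_s >= lag_window[1] &
        .data$time_s <= lag_window[2]]),
      density = pmax(.data$density - .data$baseline, 0)
    ) |>
    dplyr::ungroup()
}

#' Mean component densities over steady segments
#'
#' Averages each intensity channel over every steady segment, yielding the
#' per-load density table the flux pipeline consumes.
#'
#' @param intensity Tibble `time_s`, `channel`, `density` (background
#'   subtracted, see [subtract_baseline()]).
#' @param segments Segment tibble from [find_steady_segments()].
#'
#' @return Tibble `stress`, `velocity`, `channel`, `mean_density`.
#' @export
segment_densities <- function(intensity, segments) {
  validate_intensity_trace(intensity)
  purrr::pmap_dfr(
    segments[, c("t_start", "t_end", "stress", "velocity")],
    function(t_start, t_end, stress, velocity) {
      intensity |>
        dplyr::filter(.data$time_s >= t_start, .data$time_s <= t_end) |>
        dplyr::group_by(.data$channel) |>
        dplyr::summarise(mean_density = mean(.data$density), .groups = "drop") |>
        dplyr::mutate(stress = stress, velocity = velocity, .before = 1L)
    }
  )
}

#' Per-network incorporation rates, normalised to the reference load
#'
#' The network-level rate (flux) of a component is the product of its
#' steady-state density and the network growth velocity; each channel is
#' normalised to its flux at the reference load, which therefore maps to
#' exactly 1.
#'
#' @param densities Tibble `stress`, `velocity`, `channel`, `mean_density`
#'   (from [segment_densities()] or equivalent).
#' @param reference_stress Reference load, Pa (default 25).
#'
#' @return Tibble `stress`, `channel`, `per_network_rate`.
#' @export
per_network_rate <- function(densities, reference_stress = 25) {
  req <- c("stress", "velocity", "channel", "mean_density")
  if (!all(req %in% names(densities))) {
    abort(paste0(
      "`densities` needs columns ",
      paste0("`", req, "`", collapse = ", "), "."
    ))
  }
  if (min(abs(densities$stress - reference_stress)) >
    max(0.05 * reference_stress, 5)) {
    abort(sprintf("No entry at the reference load (%g Pa).", reference_stress))
  }
  out <- densities |>
    dplyr::mutate(flux = .data$mean_density * .data$velocity) |>
    dplyr::group_by(.data$channel) |>
    dplyr::mutate(ref_flux = .data$flux[closest_idx(.data$stress, reference_stress)]) |>
    dplyr::ungroup()
  if (any(out$ref_flux <= 0)) {
    abort("Normalisation error: zero flux at the reference load.")
  }
  out |>
    dplyr::transmute(.data$stress, .data$channel,
      per_network_rate = .data$flux / .data$ref_flux
    )
}

closest_idx <- function(x, target) which.min(abs(x - target))[1L]

#' Per-filament rates from per-network rates
#'
#' Per-network capping/elongation rates divided by the relative density of
#' free barbed ends under the same load, giving the rate per growing end
#' (normalised so the reference load is 1).
#'
#' @param rates Tibble `stress`, `channel`, `per_network_rate`.
#' @param barbed_ends Tibble `stress`, `e_rel` (relative free-barbed-end
#'   density, 1 at the reference load, > 0). Stresses are matched to the
#'   nearest entry (segment stresses are noisy-trace medians), within 5%
#'   or 5 Pa.
#'
#' @return `rates` with an added `per_filament_rate` column.
#' @export
per_filament_rate <- function(rates, barbed_ends) {
  if (!all(c("stress", "e_rel") %in% names(barbed_ends))) {
    abort("`barbed_ends` needs columns `stress` and `e_rel`.")
  }
  if (any(barbed_ends$e_rel <= 0)) {
    abort("`e_rel` must be positive.")
  }
  idx <- vapply(rates$stress, function(s) {
    closest_idx(barbed_ends$stress, s)
  }, integer(1))
  gap <- abs(barbed_ends$stress[idx] - rates$stress)
  if (any(gap > pmax(0.05 * rates$stress, 5))) {
    abort("Every stress in `rates` must appear in `barbed_ends`.")
  }
  dplyr::mutate(rates,
    e_rel = barbed_ends$e_rel[idx],
    per_filament_rate = .data$per_network_rate / .data$e_rel
  )
}

#' Steady-state free-barbed-end density from flux balance
#'
#' At steady state the network-wide capping and nucleation rates balance,
#' `R_cap = k_cap * [CP] * E = R_nucleate`, which rearranges to the density
#' of free barbed ends `E = R_nucleate / (k_cap * [CP])`.
#'
#' @param r_nucleate Network nucleation rate, s^-1 um^-2 (> 0).
#' @param k_cap Capping rate constant, uM^-1 s^-1 (> 0).
#' @param cp_conc Capping-protein concentration, uM (> 0).
#'
#' @return E in um^-2. Vectorised.
#' @export
#'
#' @examples
#' barbed_end_density_steady_state(10, 5, 0.1)  # 20 um^-2
barbed_end_density_steady_state <- function(r_nucleate, k_cap, cp_conc) {
  if (any(r_nucleate <= 0) || any(k_cap <= 0) || any(cp_conc <= 0)) {
    abort("All of `r_nucleate`, `k_cap`, `cp_conc` must be positive.")
  }
  r_nucleate / (k_cap * cp_conc)
}

#' Capping-protein : actin ratio per load
#'
#' The CP:actin fluorescence ratio is inversely proportional to the mean
#' filament length; a flat ratio across loads means filament length is
#' load-invariant.
#'
#' @param actin_density,cp_density Positive numeric vectors per load.
#' @param normalize Normalise to the first (unloaded) entry.
#'
#' @return Numeric vector of ratios.
#' @export
mean_filament_length_ratio <- function(actin_density, cp_density,
                                       normalize = FALSE) {
  if (any(actin_density <= 0)) abort("`actin_density` must be positive.")
  if (any(cp_density <= 0)) abort("`cp_density` must be positive.")
  r <- cp_density / actin_density
  if (normalize) r <- r / r[1L]
  r
}

#' Fraction of the soluble actin pool consumed by network growth
#'
#' @param polymer_conc Polymeric actin concentration inside the networks, uM.
#' @param network_volume Total network volume, ul.
#' @param total_conc Actin concentration of the reaction, uM.
#' @param total_volume Reaction volume, ul.
#'
#' @return Dimensionless fraction.
#' @export
#'
#' @examples
#' monomer_consumption_fraction(150, 0.01, 5, 150)  # 0.002, i.e. 0.2%
monomer_consumption_fraction <- function(polymer_conc, network_volume,
                                         total_conc, total_volume) {
  args <- c(polymer_conc, network_volume, total_conc, total_volume)
  if (any(args <= 0)) abort("All inputs must be positive.")
  (polymer_conc * network_volume) / (total_conc * total_volume)
}

#' Network mesh size from polymer concentration
#'
#' `zeta = 1.47 / sqrt(C_A)` with `C_A` in uM and `zeta` in um.
#'
#' @param polymer_conc Polymeric actin concentration, uM (> 0).
#'
#' @return Mesh size, um. Vectorised.
#' @export
#'
#' @examples
#' mesh_size(1.47^2)  # 1 um
mesh_size <- function(polymer_conc) {
  if (any(polymer_conc <= 0)) abort("`polymer_conc` must be positive (uM).")
  1.47 / sqrt(polymer_conc)
}

#' Diffusion-hindrance threshold of a network
#'
#' Particles with Stokes radius above roughly 0.4 times the mesh size start
#' to interact strongly with the network and diffuse anomalously.
#'
#' @param zeta Mesh size, um (see [mesh_size()]).
#' @param factor Threshold prefactor (default 0.4).
#'
#' @return Threshold radius in um.
#' @export
diffusion_threshold <- function(zeta, factor = 0.4) {
  if (any(zeta <= 0)) abort("`zeta` must be positive (um).")
  factor * zeta
}
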