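#' Simulate single-molecule incorporation tracks
#'
#' Synthetic TIRF tracks of fluorescent Arp2/3 complexes incorporating into
#' a growing network. A productive molecule moves away from the coverslip
#' with the network, so its intensity decays exponentially with time
#' constant `tau = evanescent_depth / velocity`. An abortive molecule
#' detaches after an exponentially distributed failure time, truncating the
#' decay; an unproductive molecule is stuck at roughly constant intensity
#' with blinking gaps. Tracks end when the intensity falls below 2% of the
#' initial value or `max_duration` is reached.
#'
#' @param n Number of tracks.
#' @param velocity Network growth velocity, um/min (> 0).
#' @param evanescent_depth TIRF evanescent-field depth, um. Default 0.15.
#' @param abortive_fraction Fraction of productive tracks that truncate
#'   early, in `[0, 1]`.
#' @param abortive_hazard Detachment hazard of abortive tracks, s^-1.
#' @param unproductive_fraction Fraction of tracks that are stuck/blinking
#'   molecules.
#' @param noise_sd Gaussian intensity noise (fraction of initial
#'   intensity).
#' @param frame_dt Frame interval, s. Default 0.1 (10 frames/s).
#' @param max_duration Maximum track duration, s.
#' @param seed Optional RNG seed.
#'
#' @return Tibble with columns `track_id`, `frame`, `time_s`, `x_um`,
#'   `y_um`, `intensity`, `true_class` (generator ground truth:
#'   `"productive-continuous"`, `"productive-abortive"`, `"unproductive"`).
#' @export
simulate_tracks <- function(n, velocity, evanescent_depth = 0.15,
                            abortive_fraction = 0, abortive_hazard = 1,
                            unproductive_fraction = 0,
                            noise_sd = 0, frame_dt = 0.1,
                            max_duration = NULL, seed = NULL) {
  if (velocity <= 0) abort("`velocity` must be positive (um/min).")
  if (evanescent_depth <= 0) abort("`evanescent_depth` must be positive (um).")
  if (abortive_fraction < 0 || abortive_fraction > 1) {
    abort("`abortive_fraction` must lie in [0, 1].")
  }
  if (unproductive_fraction < 0 || unproductive_fraction > 1) {
    abort("`unproductive_fraction` must lie in [0, 1].")
  }
  if (!is.null(seed)) set.seed(seed)
  v_um_s <- velocity / 60
  tau <- evanescent_depth / v_um_s
  if (is.null(max_duration)) max_duration <- 6 * tau

  purrr::map_dfr(seq_len(n), function(id) {
    u <- runif(1)
    cls <- if (u < unproductive_fraction) {
      "unproductive"
    } else if (runif(1) < abortive_fraction) {
      "productive-abortive"
    } else {
      "productive-continuous"
    }
    x0 <- runif(1, 0, 10)
    y0 <- runif(1, 0, 10)
    if (cls == "unproductive") {
      t_end <- max_duration
      tt <- seq(0, t_end, by = frame_dt)
      base <- 1 + rnorm(length(tt), 0, noise_sd)
      blink <- runif(length(tt)) < 0.15 # dark frames
      inten <- pmax(ifelse(blink, 0.05, base), 0)
    } else {
      t_end <- max_duration
      if (cls == "productive-abortive") {
        # condition the failure time on the window in which a truncated
        # decay is observable (final intensity still >= 20% of I0): later
        # detachments are indistinguishable from completed transits
        t_cut <- min(tau * log(5), max_duration)
        u_f <- runif(1)
        t_end <- -log(1 - u_f * (1 - exp(-abortive_hazard * t_cut))) /
          abortive_hazard
        t_end <- max(t_end, 5 * frame_dt) # keep classification eligibility
      }
      tt <- seq(0, t_end, by = frame_dt)
      inten <- exp(-tt / tau) + rnorm(length(tt), 0, noise_sd)
      keep <- cumsum(exp(-tt / tau) < 0.02) < 1 # stop once signal is gone
      tt <- tt[keep]
      inten <- pmax(inten[keep], 0)
    }
    if (length(tt) < 2L) {
      tt <- seq(0, frame_dt * 4, by = frame_dt)
      inten <- rep(pmax(exp(-tt / tau), 0.02), length.out = length(tt))
    }
    tibble::tibble(
      track_id = id,
      frame = seq_along(tt),
      time_s = tt,
      x_um = x0 + rnorm(length(tt), 0, 0.01),
      y_um = y0 + rnorm(length(tt), 0, 0.01),
      intensity = inten,
      true_class = cls
    )
  })
}

#' Fit a single-exponential decay to one molecule track
#'
#' Least-squares fit of `I(t) = I0 * exp(-t / tau)` to a track's intensity
#' trace. The decay constant is the fluorescence transit time of the
#' molecule through the evanescent field. The fit is rejected (with a
#' reason code) for non-decaying or poorly fitting tracks; a track whose
#' final observed intensity is still a sizeable fraction of `I0` is marked
#' `truncated` (premature loss, the abortive signature).
#'
#' @param track Tibble with `time_s` and `intensity` (one track, >= 5
#'   frames).
#' @param truncate_threshold Final-intensity fraction of fitted `I0` above
#'   which the track counts as truncated. Default 0.1.
#' @param dwell_threshold Intensity fraction of fitted `I0` defining the
#'   dwell endpoint. Default 0.05.
#' @param r2_min Minimum r-squared for an accepted fit.
#'
#' @return One-row tibble: `i0`, `tau` (s), `dwell` (s), `r_squared`,
#'   `truncated`, `status` (`"ok"`, `"non-decaying"`, `"poor-fit"`,
#'   `"too-short"`).
#' @export
fit_track_decay <- function(track, truncate_threshold = 0.1,
                            dwell_threshold = 0.05, r2_min = 0.9) {
  empty <- tibble::tibble(
    i0 = NA_real_, tau = NA_real_, dwell = NA_real_,
    r_squared = NA_real_, truncated = NA, status = NA_character_
  )
  if (nrow(track) < 5L) {
    empty$status <- "too-short"
    return(empty)
  }
  t <- track$time_s - track$time_s[1L]
  y <- track$intensity

  # slope of log-intensity on positive frames as a decay screen and start
  pos <- y > 0.01 * max(y)
  if (sum(pos) < 3L || linfit(t[pos], log(y[pos]))$slope >= -1e-6) {
    empty$status <- "non-decaying"
    return(empty)
  }
  lf <- linfit(t[pos], log(y[pos]))
  dat <- data.frame(t = t, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ i0 * exp(-t / tau),
      data = dat,
      start = list(i0 = max(y), tau = -1 / lf$slope),
      lower = c(i0 = 0, tau = 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 100)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    empty$status <- "poor-fit"
    return(empty)
  }
  cf <- coef(fit)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst < 1e-18) 1 else 1 - sum(stats::resid(fit)^2) / sst
  if (r2 < r2_min) {
    out <- empty
    out$i0 <- cf[["i0"]]
    out$tau <- cf[["tau"]]
    out$r_squared <- r2
    out$status <- "poor-fit"
    return(out)
  }
  below <- which(y < dwell_threshold * cf[["i0"]])
  dwell <- if (length(below)) t[below[1L]] else t[length(t)]
  truncated <- tail(y, 1L) > truncate_threshold * cf[["i0"]]
  tibble::tibble(
    i0 = cf[["i0"]], tau = cf[["tau"]], dwell = dwell,
    r_squared = r2, truncated = truncated, status = "ok"
  )
}

#' Classify molecule tracks by deterministic feature rules
#'
#' Replaces image-level expert/classifier workflows with transparent
#' thresholds on track-table features: decay-fit quality, fractional
#' intensity drop, and positional drift. Tracks with a good exponential
#' decay are productive; among those, a truncated decay (premature loss)
#' is abortive, otherwise continuous. Tracks at roughly constant intensity
#' (or blinking) are unproductive. Anything else is unclassified, as are
#' tracks shorter than `min_frames`.
#'
#' @param tracks Track tibble (`track_id`, `time_s`, `intensity`,
#'   optionally `x_um`, `y_um`), e.g. from [simulate_tracks()].
#' @param min_frames Minimum frames for classification eligibility (5).
#' @param r2_min Minimum decay-fit r-squared for a productive call.
#' @param drop_min Minimum fractional intensity drop for a continuous
#'   productive call. Default 0.8.
#' @param drift_max Maximum positional drift (um) for the stuck-molecule
#'   rule.
#'
#' @return Per-track tibble: fit columns from [fit_track_decay()] plus
#'   `label` and `n_frames` (and `true_class` carried through when
#'   present).
#' @export
classify_tracks <- function(tracks, min_frames = 5, r2_min = 0.9,
                            drop_min = 0.8, drift_max = 0.2) {
  stopifnot("track_id" %in% names(tracks))
  tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::group_modify(function(tr, key) {
      fit <- fit_track_decay(tr, r2_min = r2_min)
      n_fr <- nrow(tr)
      # upper quartiles over the first/last few frames: a stuck molecule
      # stays bright in most frames even with blinking gaps, while a
      # departed one is dim in all of them
      k <- min(7L, n_fr)
      drop_frac <- 1 - quantile(tail(tr$intensity, k), 0.75, names = FALSE) /
        max(quantile(head(tr$intensity, k), 0.75, names = FALSE), 1e-12)
      drift <- if (all(c("x_um", "y_um") %in% names(tr))) {
        sqrt(
          (tail(tr$x_um, 1L) - tr$x_um[1L])^2 +
            (tail(tr$y_um, 1L) - tr$y_um[1L])^2
        )
      } else {
        0
      }
      label <- if (n_fr < min_frames) {
        "unclassified"
      } else if (identical(fit$status, "ok")) {
        if (isTRUE(fit$truncated)) "productive-abortive" else "productive-continuous"
      } else if (identical(fit$status, "non-decaying") ||
        (drop_frac < 1 - drop_min && drift <= drift_max)) {
        "unproductive"
      } else {
        "unclassified"
      }
      out <- dplyr::mutate(fit,
        label = label, n_frames = n_fr,
        duration = tail(tr$time_s, 1L) - tr$time_s[1L]
      )
      if ("true_class" %in% names(tr)) out$true_class <- tr$true_class[1L]
      out
    }) |>
    dplyr::ungroup()
}

#' Transit-time statistics across velocity conditions
#'
#' Summarises fitted transit times per velocity condition (mean and SD of
#' the approximately Gaussian tau distribution) and regresses log mean tau
#' on log velocity. Perfect reciprocity (tau = depth / v) gives slope -1.
#'
#' @param fits Tibble with columns `velocity` (um/min) and `tau` (s), e.g.
#'   classified productive tracks joined with their condition.
#'
#' @return List with `per_condition` (tibble `velocity`, `n`, `tau_mean`,
#'   `tau_sd`) and `loglog_slope` (tibble `estimate`, `conf.low`,
#'   `conf.high`, or NULL with a single condition).
#' @export
transit_statistics <- function(fits) {
  if (!all(c("velocity", "tau") %in% names(fits))) {
    abort("`fits` needs columns `velocity` and `tau`.")
  }
  fits <- dplyr::filter(fits, !is.na(.data$tau))
  per <- fits |>
    dplyr::group_by(.data$velocity) |>
    dplyr::summarise(
      n = dplyr::n(),
      tau_mean = mean(.data$tau),
      tau_sd = sd(.data$tau),
      .groups = "drop"
    )
  slope <- NULL
  if (nrow(per) >= 2L) {
    fit <- lm(log(tau_mean) ~ log(velocity), data = per)
    ci <- suppressWarnings(confint(fit)["log(velocity)", ])
    slope <- tibble::tibble(
      estimate = coef(fit)[["log(velocity)"]],
      conf.low = ci[[1L]], conf.high = ci[[2L]]
    )
  }
  list(per_condition = per, loglog_slope = slope)
}

#' Per-NPF nucleation rate from an incorporation event rate
#'
#' Converts an observed areal rate of productive incorporation events into
#' a nucleation rate per NPF molecule: the observed rate is first corrected
#' for the labelled fraction (divided by `labeling_ratio`), then divided by
#' the NPF surface density.
#'
#' @param event_rate_density Observed productive event rate, s^-1 um^-2.
#' @param npf_density NPF surface density, um^-2 (default 1850).
#' @param labeling_ratio Labelled fraction of the pool, in (0, 1].
#'
#' @return Nucleation rate per NPF, s^-1.
#' @export
#'
#' @examples
#' nucleation_rate_per_npf(68.45, 1850, 1)  # 0.037
nucleation_rate_per_npf <- function(event_rate_density, npf_density = 1850,
                                    labeling_ratio = 1) {
  if (any(event_rate_density <= 0)) {
    abort("`event_rate_density` must be positive.")
  }
  if (any(npf_density <= 0)) abort("`npf_density` must be positive.")
  if (any(labeling_ratio <= 0)) {
    abort("`labeling_ratio` must be positive (the labelled fraction).")
  }
  (event_rate_density / labeling_ratio) / npf_density
}

#' Excess of early-loss (short-dwell) events over a control
#'
#' Compares the dwell-time distribution of molecules in a loaded network
#' with a bleaching/tracking-loss control on shared histogram bins and
#' reports the excess short-dwell probability mass
#' `sum(max(0, p_loaded - p_control))` over the short-dwell region, with a
#' bootstrap confidence interval.
#'
#' @param loaded_dwells,control_dwells Numeric dwell-time samples, s.
#' @param breaks Shared bin edges; `NULL` builds them from the pooled range
#'   (`n_bins` equal bins).
#' @param n_bins Number of bins when `breaks` is NULL.
#' @param short_cutoff Upper edge of the short-dwell region, s; `NULL`
#'   uses the median of the control sample.
#' @param n_boot Bootstrap replicates.
#' @param conf_level Confidence level.
#'
#' @return List `excess`, `conf_int`, `breaks`, `short_cutoff`.
#' @export
dwell_excess <- function(loaded_dwells, control_dwells, breaks = NULL,
                         n_bins = 20, short_cutoff = NULL,
                         n_boot = 500, conf_level = 0.95) {
  if (!length(loaded_dwells) || !length(control_dwells)) {
    abort("Both dwell samples must be non-empty.")
  }
  if (is.null(breaks)) {
    rng <- range(c(loaded_dwells, control_dwells))
    breaks <- seq(rng[1L] - 1e-9, rng[2L] + 1e-9, length.out = n_bins + 1L)
  }
  if (min(c(loaded_dwells, control_dwells)) < breaks[1L] ||
    max(c(loaded_dwells, control_dwells)) > breaks[length(breaks)]) {
    abort("Incompatible binning: `breaks` do not cover both samples.")
  }
  if (is.null(short_cutoff)) short_cutoff <- median(control_dwells)
  short_bins <- breaks[-1L] <= short_cutoff + 1e-12

  one_excess <- function(ld, cd) {
    p_l <- graphics::hist(ld, breaks = breaks, plot = FALSE)$counts / length(ld)
    p_c <- graphics::hist(cd, breaks = breaks, plot = FALSE)$counts / length(cd)
    sum(pmax(0, (p_l - p_c)[short_bins]))
  }
  excess <- one_excess(loaded_dwells, control_dwells)
  boot <- vapply(seq_len(n_boot), function(i) {
    one_excess(
      sample(loaded_dwells, replace = TRUE),
      sample(control_dwells, replace = TRUE)
    )
  }, numeric(1))
  alpha <- (1 - conf_level) / 2
  list(
    excess = excess,
    conf_int = unname(quantile(boot, c(alpha, 1 - alpha))),
    breaks = breaks,
    short_cutoff = short_cutoff
  )
}
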