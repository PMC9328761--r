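#' Fit exponential decay(s) to a rate-versus-load curve
#'
#' Nonlinear least squares for `y = sum_i a_i * exp(-x / tau_i)` with one or
#' two components. Per-filament rates versus external load need two decay
#' constants, whereas the same rates replotted against force per filament
#' collapse onto a single exponential. Two-component fits use multi-start
#' initialisation (log-spaced decay constants) to avoid the label-swap
#' degeneracy, and decay constants are returned in ascending order.
#'
#' @param x Predictor (stress in Pa or force per filament in pN).
#' @param y Positive response (normalised rate).
#' @param n_components 1 or 2.
#' @param n_starts Number of log-spaced multi-start initialisations (>= 5
#'   used for two components).
#'
#' @return An object of class `decay_fit`: `coefficients` tibble
#'   (`amplitude`, `tau` per component, ascending `tau`), `r_squared`,
#'   `fitted`, `residuals`, `n`, `n_components`. Supports [tidy()],
#'   [glance()], [autoplot()] and [predict()].
#' @export
#'
#' @examples
#' x <- seq(0, 1200, length.out = 7)
#' fit <- fit_decay(x, exp(-x / 300))
#' tidy(fit)
fit_decay <- function(x, y, n_components = 1, n_starts = 6) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (any(y <= 0)) abort("`y` must be positive.")
  if (!n_components %in% c(1, 2)) abort("`n_components` must be 1 or 2.")
  if (length(x) < 2 * n_components + 1) {
    abort(sprintf(
      "Need at least %d points for %d component(s).",
      2 * n_components + 1, n_components
    ))
  }
  if (stats::sd(y) / mean(y) < 1e-10) {
    abort(paste(
      "Degenerate fit: `y` is constant;",
      "the decay constant is unbounded."
    ))
  }

  span <- diff(range(x))
  if (span <= 0) abort("`x` must span a nonzero range.")
  tau_grid <- exp(seq(log(span / 20), log(span * 20),
    length.out = max(n_starts, if (n_components == 2) 5 else 1)
  ))

  dat <- data.frame(x = x, y = y)
  best <- NULL
  best_rss <- Inf
  try_fit <- function(start, lower) {
    tryCatch(
      minpack.lm::nlsLM(formula_for(n_components),
        data = dat, start = start, lower = lower,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
  }

  if (n_components == 1) {
    # log-linear start, then refine over the grid
    lf <- linfit(x, log(y))
    tau0 <- if (lf$slope < 0) -1 / lf$slope else span
    starts <- lapply(unique(c(tau0, tau_grid)), function(tau) {
      list(a1 = max(y), t1 = tau)
    })
    lower <- c(a1 = 0, t1 = span * 1e-6)
  } else {
    starts <- list()
    for (t1 in tau_grid) {
      for (mult in c(5, 20)) {
        starts[[length(starts) + 1L]] <-
          list(a1 = max(y) / 2, t1 = t1, a2 = max(y) / 2, t2 = t1 * mult)
      }
    }
    lower <- c(a1 = 0, t1 = span * 1e-6, a2 = 0, t2 = span * 1e-6)
  }

  for (st in starts) {
    f <- try_fit(st, lower)
    if (is.null(f)) next
    rss <- sum(stats::resid(f)^2)
    if (rss < best_rss) {
      best <- f
      best_rss <- rss
    }
  }
  if (is.null(best)) {
    abort("Exponential fit failed to converge from any initialisation.")
  }

  cf <- coef(best)
  if (n_components == 1) {
    co <- tibble::tibble(amplitude = cf[["a1"]], tau = cf[["t1"]])
  } else {
    co <- tibble::tibble(
      amplitude = c(cf[["a1"]], cf[["a2"]]),
      tau = c(cf[["t1"]], cf[["t2"]])
    )
    co <- co[order(co$tau), ]
  }
  sst <- sum((y - mean(y))^2)
  structure(
    list(
      coefficients = co,
      r_squared = 1 - best_rss / sst,
      residual_ss = best_rss,
      fitted = stats::fitted(best),
      residuals = stats::resid(best),
      data = tibble::tibble(x = x, y = y),
      n = length(x),
      n_components = n_components
    ),
    class = "decay_fit"
  )
}

formula_for <- function(n_components) {
  if (n_components == 1) {
    y ~ a1 * exp(-x / t1)
  } else {
    y ~ a1 * exp(-x / t1) + a2 * exp(-x / t2)
  }
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "<decay_fit> %d component(s), r^2 = %.4f, n = %d\n",
    x$n_components, x$r_squared, x$n
  ))
  print(x$coefficients)
  invisible(x)
}

#' @export
predict.decay_fit <- function(object, newdata = NULL, ...) {
  xs <- if (is.null(newdata)) object$data$x else newdata$x
  co <- object$coefficients
  as.vector(exp(-outer(xs, 1 / co$tau)) %*% co$amplitude)
}

#' @export
tidy.decay_fit <- function(x, ...) {
  co <- x$coefficients
  tibble::tibble(
    term = paste0(
      rep(c("amplitude", "tau"), each = nrow(co)),
      rep(seq_len(nrow(co)), 2L)
    ),
    estimate = c(co$amplitude, co$tau)
  )
}

#' @export
glance.decay_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared,
    residual.ss = x$residual_ss,
    nobs = x$n,
    n.components = x$n_components
  )
}
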