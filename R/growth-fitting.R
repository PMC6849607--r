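# Estimation of specific growth rates from density time series using the
# Buchanan three-phase linear growth model, fitted by multi-start
# Levenberg-Marquardt least squares with AICc-based start selection.

#' Buchanan three-phase linear growth model
#'
#' Piecewise-linear log-density model of a batch growth curve: flat at
#' `N0_log` during the lag phase (`t <= t_lag`), rising linearly at slope
#' `mu` during the exponential phase, and flat at `Nmax_log` in stationary
#' phase (`t >= t_max`). With consistent parameters
#' (`Nmax_log = N0_log + mu * (t_max - t_lag)`) the function is continuous.
#'
#' @param t time(s) in days, >= 0.
#' @param t_lag lag duration (days), `0 <= t_lag <= t_max`.
#' @param t_max time at which the maximum density is reached (days).
#' @param N0_log log density at inoculation.
#' @param Nmax_log log density of the stationary plateau.
#' @param mu specific growth rate (per day on the same log scale as the
#'   densities; natural log gives mu in d^-1).
#' @return log density at `t`.
#' @export
buchanan_model <- function(t, t_lag, t_max, N0_log, Nmax_log, mu) {
  if (t_lag > t_max) stopf("t_lag (%g) must not exceed t_max (%g)", t_lag, t_max)
  if (any(t < 0)) stopf("t must be >= 0")
  ifelse(t <= t_lag, N0_log,
         ifelse(t >= t_max, Nmax_log, N0_log + mu * (t - t_lag)))
}

#' Small-sample corrected Akaike information criterion from a residual sum
#' of squares
#'
#' `AICc = n * ln(rss / n) + 2p + 2p(p + 1)/(n - p - 1)`, the Gaussian
#' least-squares form used to rank multi-start fits; lower is better.
#'
#' @param rss residual sum of squares (> 0).
#' @param n number of observations.
#' @param p number of fitted parameters; requires `n > p + 1`.
#' @return the AICc score (finite), or an error when `n <= p + 1`.
#' @export
aicc <- function(rss, n, p) {
  if (n <= p + 1) stopf("AICc undefined: need n > p + 1 (n = %d, p = %d)", n, p)
  if (rss <= 0) stopf("rss must be > 0")
  n * log(rss / n) + 2 * p + 2 * p * (p + 1) / (n - p - 1)
}

# Internal parameterisation used by the optimiser: (t_lag, dt, N0_log, dN, mu)
# with dt = t_max - t_lag >= 0 and dN = Nmax_log - N0_log >= 0, so every
# evaluated parameter set satisfies the model's ordering constraints.
buchanan_residuals <- function(par, t, y) {
  t_lag <- par[1]; t_max <- par[1] + par[2]
  pred <- ifelse(t <= t_lag, par[3],
                 ifelse(t >= t_max, par[3] + par[4], par[3] + par[5] * (t - t_lag)))
  pred - y
}

buchanan_jacobian <- function(par, t, y) {
  t_lag <- par[1]; t_max <- par[1] + par[2]
  A <- t <= t_lag; C <- t >= t_max; B <- !A & !C
  J <- matrix(0, length(t), 5)
  J[, 3] <- 1
  J[B, 1] <- -par[5]
  J[B, 5] <- t[B] - t_lag
  J[C, 4] <- 1
  J
}

# Data-driven start: enumerate assignments of the observations to the three
# phases (lag points 1..ia, ramp points ia+1..ic-1, plateau points ic..n),
# solve each assignment in closed form (phase means and an OLS line through
# the ramp), and return the assignment with the lowest residual sum of
# squares. The optimiser is seeded from this candidate in addition to the
# random starts, which keeps small multi-starts from stalling in the kinked
# residual surface.
buchanan_profile_start <- function(t, y) {
  n <- length(t)
  best <- NULL; best_rss <- Inf
  for (ia in 1:(n - 2)) {
    for (ic in (ia + 3):(n + 1)) {  # >= 2 ramp points
      A <- 1:ia
      B <- (ia + 1):(ic - 1)
      C <- if (ic <= n) ic:n else integer(0)
      N0 <- mean(y[A])
      tb <- t[B]; yb <- y[B]
      mu <- sum((tb - mean(tb)) * (yb - mean(yb))) / sum((tb - mean(tb))^2)
      if (!is.finite(mu) || mu <= 0) next
      alpha <- mean(yb) - mu * mean(tb)
      t_lag <- (N0 - alpha) / mu
      t_lag <- min(max(t_lag, t[ia]), if (ia < n) t[ia + 1] else max(t))
      t_lag <- max(t_lag, 0)
      Nmax <- if (length(C) > 0) mean(y[C]) else max(y)
      t_max <- (Nmax - alpha) / mu
      lo <- t[ic - 1]; hi <- if (ic <= n) t[ic] else max(t)
      t_max <- min(max(t_max, lo, t_lag), hi)
      par <- c(t_lag, t_max - t_lag, N0, max(Nmax - N0, 0), mu)
      rss <- sum(buchanan_residuals(par, t, y)^2)
      if (rss < best_rss) { best <- par; best_rss <- rss }
    }
  }
  if (is.null(best)) {
    N0 <- min(y); Nmax <- max(y)
    best <- c(0, diff(range(t)), N0, max(Nmax - N0, 1e-3),
              max(diff(y) / diff(t), 1e-3))
  }
  best
}

#' Fit the Buchanan model to one growth curve
#'
#' Fits [buchanan_model()] to log-transformed densities by bounded
#' Levenberg-Marquardt least squares ([minpack.lm::nls.lm]), restarted from
#' `n_starts` random starting-parameter combinations drawn from uniform
#' distributions (lag and plateau knots over the observed time window, growth
#' rate over 0-3 d^-1, log densities over the observed range widened by one
#' unit), plus one data-driven start. Among all converged starts the
#' parameter set with the lowest AICc is returned. Deterministic for a fixed
#' `seed`.
#'
#' Densities are fitted on the natural-log scale by default, so the fitted
#' slope is directly the specific growth rate in d^-1 used by the
#' exponential-growth competition theory; `scale = "log10"` fits decadic
#' logs and reports `mu` multiplied by `ln 10` so it remains a specific rate.
#'
#' @param curve data frame with columns `day` and `density_cells_per_mL`
#'   (extra columns are carried through untouched): one monoculture time
#'   series at fixed species, temperature, phosphate and replicate.
#' @param n_starts number of random starting-parameter combinations
#'   (default 1000).
#' @param seed integer seed for the random starts; `NULL` uses the current
#'   RNG state.
#' @param scale `"ln"` (default) or `"log10"`: the log scale on which the
#'   residuals are computed.
#' @return an object of class `buchanan_fit`: a list with `t_lag`, `t_max`,
#'   `N0_log`, `Nmax_log`, `mu` (always d^-1, natural-log scale), `rss`,
#'   `n_obs`, `aicc`, `converged` and `scale`. Curves with fewer than 6
#'   observations (5 parameters + 1) or non-increasing days are rejected.
#'   An all-constant curve returns the exact flat fit with `mu = 0`.
#' @examples
#' tr <- metabolic_traits(0.8, 0.6, 0.3, 0.4)
#' d <- data.frame(day = seq(0, 30, 2))
#' d$density_cells_per_mL <- 10^pmin(2 + 0.4 * pmax(d$day - 2, 0), 6)
#' fit_buchanan(d, n_starts = 20, seed = 1)
#' @export
fit_buchanan <- function(curve, n_starts = 1000, seed = NULL,
                         scale = c("ln", "log10")) {
  scale <- match.arg(scale)
  check_columns(curve, c("day", "density_cells_per_mL"), "growth curve")
  t <- as.numeric(curve$day)
  dens <- as.numeric(curve$density_cells_per_mL)
  if (any(diff(t) <= 0)) stopf("days must be strictly increasing")
  if (any(dens <= 0)) stopf("densities must be > 0")
  if (n_starts < 1) stopf("n_starts must be >= 1")
  n <- length(t)
  if (n < 5) stopf("need at least 5 observations to fit 5 parameters")

  y <- if (scale == "ln") log(dens) else log10(dens)
  mu_unit <- if (scale == "ln") 1 else log(10)
  # AICc needs n > p + 1; on shorter series starts are ranked by rss instead
  # and the score is reported as NA.
  use_aicc <- n > 6
  score_of <- function(rss) {
    if (!use_aicc) rss else if (rss > 0) aicc(rss, n, 5L) else -Inf
  }

  out <- function(par, rss, converged) {
    par <- unname(par)
    structure(list(t_lag = par[1], t_max = par[1] + par[2], N0_log = par[3],
                   Nmax_log = par[3] + par[4], mu = par[5] * mu_unit,
                   rss = rss, n_obs = n,
                   aicc = if (!use_aicc) NA_real_
                          else if (rss > 0) aicc(rss, n, 5L) else -Inf,
                   converged = converged, scale = scale),
              class = "buchanan_fit")
  }

  # Degenerate input: a perfectly flat series has the exact solution mu = 0.
  if (max(y) - min(y) < .Machine$double.eps * 10 * max(abs(y), 1))
    return(out(c(0, max(t), y[1], 0, 0), rss = sum((y - y[1])^2),
               converged = TRUE))

  t_span <- max(t)
  y_lo <- min(y) - 1; y_hi <- max(y) + 1
  mu_hi <- if (scale == "ln") 3 else 3 / log(10)

  starts <- with_seed(seed, {
    # Uniform draws for (t_lag, t_max), rejecting t_lag > t_max by sorting.
    k1 <- runif(n_starts, 0, t_span); k2 <- runif(n_starts, 0, t_span)
    t_lag <- pmin(k1, k2); t_max <- pmax(k1, k2)
    N0 <- runif(n_starts, y_lo, y_hi)
    Nmax <- runif(n_starts, y_lo, y_hi)
    cbind(t_lag, t_max - t_lag, pmin(N0, Nmax), abs(Nmax - N0),
          runif(n_starts, 0, mu_hi))
  })
  starts <- rbind(starts, buchanan_profile_start(t, y))

  lower <- c(0, 0, -Inf, 0, 0)
  upper <- c(t_span, t_span, Inf, Inf, Inf)
  best <- NULL; best_aicc <- Inf
  best_any <- NULL; best_any_rss <- Inf
  ctrl <- minpack.lm::nls.lm.control(maxiter = 100)
  for (i in seq_len(nrow(starts))) {
    # individual starts may fail or hit maxiter; that is expected in a
    # multi-start and reported through the converged flag, not warnings
    fit <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = starts[i, ], lower = lower, upper = upper,
                           fn = buchanan_residuals, jac = buchanan_jacobian,
                           t = t, y = y, control = ctrl)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (rss < best_any_rss) { best_any <- fit$par; best_any_rss <- rss }
    if (fit$info %in% 1:4) {
      score <- score_of(rss)
      if (score < best_aicc) { best <- fit$par; best_aicc <- score }
    }
  }
  if (!is.null(best)) {
    rss <- sum(buchanan_residuals(best, t, y)^2)
    out(best, rss, converged = TRUE)
  } else if (!is.null(best_any)) {
    out(best_any, best_any_rss, converged = FALSE)
  } else {
    stopf("all %d starts failed", nrow(starts))
  }
}

#' @export
print.buchanan_fit <- function(x, ...) {
  cat(sprintf(
    "Buchanan fit (%s scale): mu = %.4g d^-1, t_lag = %.3g d, t_max = %.3g d\n  N0_log = %.4g, Nmax_log = %.4g, rss = %.4g, AICc = %.4g, converged: %s\n",
    x$scale, x$mu, x$t_lag, x$t_max, x$N0_log, x$Nmax_log, x$rss, x$aicc,
    x$converged))
  invisible(x)
}

#' Fit growth rates for every curve in a monoculture dataset
#'
#' Splits a `growth_curves` table by species x temperature x phosphate x
#' replicate, fits each curve with [fit_buchanan()], and flags failed growth:
#' curves whose fitted rise `Nmax_log - N0_log` is below
#' `fail_threshold_decades` decades are marked `failed = TRUE` and are
#' excluded from downstream trait fitting.
#'
#' @param growth_curves data frame in the `growth_curves.csv` schema
#'   (`species`, `temperature_C`, `phosphate_umol_L`, `replicate`, `day`,
#'   `density_cells_per_mL`).
#' @param n_starts,seed passed to [fit_buchanan()]; each curve gets a
#'   deterministic sub-seed.
#' @param fail_threshold_decades minimum decades of growth for a curve to
#'   count as grown (default 1). The fitted rise `Nmax_log - N0_log` is
#'   used; when the fitted plateau lies beyond the observation window (the
#'   plateau level is then unconstrained by data) the observed log-density
#'   range stands in for it.
#' @return data frame with one row per curve: provenance columns plus the
#'   `buchanan_fit` fields and `failed`.
#' @export
fit_growth_rates <- function(growth_curves, n_starts = 1000, seed = NULL,
                             fail_threshold_decades = 1) {
  check_columns(growth_curves,
                c("species", "temperature_C", "phosphate_umol_L", "replicate",
                  "day", "density_cells_per_mL"), "growth_curves")
  key <- interaction(growth_curves$species, growth_curves$temperature_C,
                     growth_curves$phosphate_umol_L, growth_curves$replicate,
                     drop = TRUE)
  groups <- split(growth_curves, key)
  res <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    g <- groups[[i]][order(groups[[i]]$day), ]
    fit <- fit_buchanan(g, n_starts = n_starts,
                        seed = substream_seed(seed, i))
    rise <- if (fit$t_max >= max(g$day)) {
      diff(range(log(g$density_cells_per_mL)))
    } else fit$Nmax_log - fit$N0_log
    res[[i]] <- data.frame(
      species = g$species[1], temperature_C = g$temperature_C[1],
      phosphate_umol_L = g$phosphate_umol_L[1], replicate = g$replicate[1],
      t_lag = fit$t_lag, t_max = fit$t_max, N0_log = fit$N0_log,
      Nmax_log = fit$Nmax_log, mu = fit$mu, rss = fit$rss,
      n_obs = fit$n_obs, aicc = fit$aicc, converged = fit$converged,
      failed = rise < fail_threshold_decades * log(10),
      stringsAsFactors = FALSE)
  }
  fits <- do.call(rbind, res)
  rownames(fits) <- NULL
  fits
}
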