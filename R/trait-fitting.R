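# Conversion of per-condition growth rates into Monod parameters per
# temperature, then into per-species metabolic traits via Boltzmann-Arrhenius
# fits within the operational temperature range (OTR).

#' Fit the Monod model to (S, mu) points
#'
#' Multi-start bounded Levenberg-Marquardt least squares for
#' `mu = mu_max * S / (K_S + S)` from growth-rate estimates at several
#' nutrient concentrations (one species x temperature x replicate). Random
#' starts draw `mu_max` uniformly over (0, 3 * max(mu)] and `K_S`
#' log-uniformly over the observed concentration range widened tenfold;
#' the lowest-AICc converged start wins, as in [fit_buchanan()].
#'
#' Standard errors come from the Gauss-Newton approximation at the optimum;
#' a `K_S` standard error exceeding the estimate flags an unidentifiable
#' half-saturation constant (all concentrations saturating).
#'
#' @param S nutrient concentrations, umol L^-1 (>= 3 values).
#' @param mu growth-rate estimates, d^-1, same length as `S`.
#' @param n_starts number of random starts (default 200).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return object of class `monod_fit`: `mu_max`, `K_S`, `se_mu_max`,
#'   `se_K_S`, `rss`, `n_obs`, `converged`, `flagged` (non-growing input or
#'   unidentifiable `K_S`).
#' @export
fit_monod <- function(S, mu, n_starts = 200, seed = NULL) {
  if (length(S) != length(mu)) stopf("S and mu must have equal length")
  if (any(S < 0)) stopf("S must be >= 0")
  n <- length(S)
  if (n < 3) stopf("need at least 3 (S, mu) points to fit the Monod model")

  out <- function(mu_max, K_S, se, rss, converged, flagged) {
    structure(list(mu_max = mu_max, K_S = K_S, se_mu_max = se[1],
                   se_K_S = se[2], rss = rss, n_obs = n,
                   converged = converged, flagged = flagged),
              class = "monod_fit")
  }
  if (all(mu <= 1e-10))
    return(out(NA_real_, NA_real_, c(NA_real_, NA_real_), NA_real_,
               converged = FALSE, flagged = TRUE))

  resid_fn <- function(p, S, mu) p[1] * S / (p[2] + S) - mu
  jac_fn <- function(p, S, mu)
    cbind(S / (p[2] + S), -p[1] * S / (p[2] + S)^2)

  mu_hi <- 3 * max(mu)
  lS <- log(range(S[S > 0]))
  starts <- with_seed(seed, {
    cbind(runif(n_starts, 1e-6, mu_hi),
          exp(runif(n_starts, lS[1] - log(10), lS[2] + log(10))))
  })
  starts <- rbind(starts, c(max(mu), max(min(S[S > 0]), 1e-6)))

  use_aicc <- n > 3  # AICc with p = 2 needs n > 3
  best <- NULL; best_score <- Inf
  ctrl <- minpack.lm::nls.lm.control(maxiter = 100)
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = starts[i, ], lower = c(1e-12, 1e-12),
                           fn = resid_fn, jac = jac_fn, S = S, mu = mu,
                           control = ctrl)),
      error = function(e) NULL)
    if (is.null(fit) || !(fit$info %in% 1:4)) next
    rss <- sum(fit$fvec^2)
    score <- if (!use_aicc) rss else if (rss > 0) aicc(rss, n, 2L) else -Inf
    if (score < best_score) { best <- fit; best_score <- score }
  }
  if (is.null(best))
    return(out(NA_real_, NA_real_, c(NA_real_, NA_real_), NA_real_,
               converged = FALSE, flagged = TRUE))

  p <- best$par
  rss <- sum(best$fvec^2)
  se <- c(NA_real_, NA_real_)
  if (n > 2) {
    J <- jac_fn(p, S, mu)
    JtJ <- crossprod(J)
    cov <- tryCatch(solve(JtJ) * rss / (n - 2), error = function(e) NULL)
    if (!is.null(cov)) se <- sqrt(pmax(diag(cov), 0))
  }
  flagged <- is.finite(se[2]) && se[2] > p[2]
  out(p[1], p[2], se, rss, converged = TRUE, flagged = flagged)
}

#' @export
print.monod_fit <- function(x, ...) {
  cat(sprintf(
    "Monod fit: mu_max = %.4g (se %.3g) d^-1, K_S = %.4g (se %.3g) umol/L\n  rss = %.4g, n = %d, converged: %s, flagged: %s\n",
    x$mu_max, x$se_mu_max, x$K_S, x$se_K_S, x$rss, x$n_obs, x$converged,
    x$flagged))
  invisible(x)
}

#' Monod fits for every species x temperature x replicate
#'
#' Groups a growth-fit table (from [fit_growth_rates()]) by species,
#' temperature and replicate and fits the Monod model to the (phosphate, mu)
#' points of each group. Curves flagged as failed growth are excluded first.
#'
#' @param growth_fits data frame from [fit_growth_rates()].
#' @param n_starts,seed passed to [fit_monod()] with per-group sub-seeds.
#' @param min_points groups with fewer usable points are skipped (default 3).
#' @return data frame with one row per group: `species`, `temperature_C`,
#'   `replicate`, `mu_max`, `K_S`, standard errors, `rss`, `n_obs`,
#'   `converged`, `flagged`.
#' @export
fit_monod_curves <- function(growth_fits, n_starts = 200, seed = NULL,
                             min_points = 3) {
  check_columns(growth_fits,
                c("species", "temperature_C", "phosphate_umol_L", "replicate",
                  "mu", "failed"), "growth_fits")
  usable <- growth_fits[!growth_fits$failed, ]
  key <- interaction(usable$species, usable$temperature_C, usable$replicate,
                     drop = TRUE)
  groups <- split(usable, key)
  res <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    if (nrow(g) < min_points) next
    fit <- fit_monod(g$phosphate_umol_L, g$mu, n_starts = n_starts,
                     seed = substream_seed(seed, i))
    res[[i]] <- data.frame(
      species = g$species[1], temperature_C = g$temperature_C[1],
      replicate = g$replicate[1], mu_max = fit$mu_max, K_S = fit$K_S,
      se_mu_max = fit$se_mu_max, se_K_S = fit$se_K_S, rss = fit$rss,
      n_obs = fit$n_obs, converged = fit$converged, flagged = fit$flagged,
      stringsAsFactors = FALSE)
  }
  fits <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  rownames(fits) <- NULL
  fits
}

#' Fit the Boltzmann-Arrhenius model to trait-temperature estimates
#'
#' Fits `ln(value) = ln(normalisation) - E * (1/(k T) - 1/(k T_ref))` to
#' positive trait values (here `mu_max` or `K_S`) observed at several
#' temperatures inside the operational temperature range. The default
#' method is ordinary linear regression of `ln(value)` on the Boltzmann
#' factor `x = 1/(k T) - 1/(k T_ref)` (slope `= -E`), which coincides with
#' the nonlinear least-squares optimum under lognormal error and is more
#' stable; `method = "nonlinear"` refits on the natural scale by
#' Levenberg-Marquardt for parity with nls-based workflows.
#'
#' @param temperature_C temperatures in Celsius (>= 2 distinct values; >= 4
#'   points for standard errors to be meaningful).
#' @param value positive trait values at those temperatures.
#' @param T_ref_C reference temperature in Celsius (default 15).
#' @param method `"linear"` (default) or `"nonlinear"`.
#' @return object of class `arrhenius_fit`: `normalisation` (trait value at
#'   `T_ref`), `activation_energy` (eV), `se_normalisation` (delta-method,
#'   on the natural scale), `se_activation`, `T_ref_K`, `n_points`,
#'   `method`.
#' @export
fit_arrhenius <- function(temperature_C, value, T_ref_C = 15,
                          method = c("linear", "nonlinear")) {
  method <- match.arg(method)
  keep <- is.finite(temperature_C) & is.finite(value)
  temperature_C <- temperature_C[keep]; value <- value[keep]
  if (length(value) < 2) stopf("need at least 2 finite (temperature, value) points")
  if (any(value <= 0)) stopf("trait values must be > 0 for a log-scale fit")
  if (length(unique(temperature_C)) < 2)
    stopf("all temperatures identical: activation energy undefined")

  T_K <- celsius_to_kelvin(temperature_C)
  T_ref_K <- celsius_to_kelvin(T_ref_C)
  x <- 1 / (boltzmann_eV_K * T_K) - 1 / (boltzmann_eV_K * T_ref_K)
  fit <- lm(log(value) ~ x)
  est_int <- coef(fit)[[1]]; est_slope <- coef(fit)[[2]]
  # vcov warns on noiseless data ("essentially perfect fit"); the zero
  # standard errors it returns are exactly what we want there.
  se <- sqrt(diag(suppressWarnings(vcov(fit))))
  norm <- exp(est_int); E <- -est_slope

  if (method == "nonlinear") {
    resid_fn <- function(p, x, v) p[1] * exp(-p[2] * x) - v
    nl <- tryCatch(
      minpack.lm::nls.lm(par = c(norm, E), lower = c(1e-12, -Inf),
                         fn = resid_fn, x = x, v = value,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(nl) && nl$info %in% 1:4) {
      norm <- nl$par[1]; E <- nl$par[2]
      n <- length(value)
      J <- cbind(exp(-E * x), -norm * x * exp(-E * x))
      cov <- tryCatch(solve(crossprod(J)) * sum(nl$fvec^2) / max(n - 2, 1),
                      error = function(e) NULL)
      se <- if (!is.null(cov)) sqrt(pmax(diag(cov), 0)) else c(NA_real_, NA_real_)
      return(structure(list(normalisation = norm, activation_energy = E,
                            se_normalisation = se[1], se_activation = se[2],
                            T_ref_K = T_ref_K, n_points = n, method = method),
                       class = "arrhenius_fit"))
    }
  }
  structure(list(normalisation = norm, activation_energy = E,
                 se_normalisation = norm * se[1],  # delta method for exp()
                 se_activation = se[2], T_ref_K = T_ref_K,
                 n_points = length(value), method = "linear"),
            class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf(
    "Boltzmann-Arrhenius fit (%s): normalisation = %.4g (se %.3g), E = %.4g eV (se %.3g)\n  T_ref = %.2f K, n = %d\n",
    x$method, x$normalisation, x$se_normalisation, x$activation_energy,
    x$se_activation, x$T_ref_K, x$n_points))
  invisible(x)
}

#' Metabolic traits for every species from Monod fits
#'
#' Restricts Monod fits to the operational temperature range, then fits one
#' Boltzmann-Arrhenius regression per species for `mu_max` (giving `B0`,
#' `E_mu`) and one for `K_S` (giving `K0`, `E_K`). Per-replicate estimates
#' at each OTR temperature are pooled into a single regression by default;
#' `replicates = "mean"` averages replicates per temperature first.
#'
#' @param monod_fits data frame from [fit_monod_curves()].
#' @param otr_C lower and upper bound of the operational temperature range
#'   in Celsius (default `c(15, 25)`).
#' @param T_ref_C reference temperature, must lie inside the OTR
#'   (default 15).
#' @param replicates `"pooled"` (default) or `"mean"`.
#' @param method passed to [fit_arrhenius()].
#' @return data frame in the `metabolic_traits.csv` schema: `species`,
#'   `B0_per_day`, `E_mu_eV`, `K0_umol_L`, `E_K_eV`, `T_ref_C` plus
#'   standard-error and point-count columns.
#' @export
fit_metabolic_traits <- function(monod_fits, otr_C = c(15, 25), T_ref_C = 15,
                                 replicates = c("pooled", "mean"),
                                 method = c("linear", "nonlinear")) {
  replicates <- match.arg(replicates)
  method <- match.arg(method)
  check_columns(monod_fits,
                c("species", "temperature_C", "replicate", "mu_max", "K_S",
                  "converged", "flagged"), "monod_fits")
  if (T_ref_C < otr_C[1] || T_ref_C > otr_C[2])
    stopf("T_ref_C must lie inside the operational temperature range")
  ok <- monod_fits$converged & !monod_fits$flagged &
    monod_fits$temperature_C >= otr_C[1] & monod_fits$temperature_C <= otr_C[2]
  d <- monod_fits[ok, ]
  if (nrow(d) == 0) stopf("no usable Monod fits inside the OTR")

  res <- lapply(split(d, d$species, drop = TRUE), function(g) {
    if (replicates == "mean") {
      agg <- function(v) tapply(v, g$temperature_C, mean)
      g <- data.frame(temperature_C = as.numeric(names(agg(g$mu_max))),
                      mu_max = as.numeric(agg(g$mu_max)),
                      K_S = as.numeric(agg(g$K_S)))
    }
    fmu <- fit_arrhenius(g$temperature_C, g$mu_max, T_ref_C, method)
    fK <- fit_arrhenius(g$temperature_C, g$K_S, T_ref_C, method)
    data.frame(species = NA_character_,  # filled from the split keys below
               B0_per_day = fmu$normalisation, E_mu_eV = fmu$activation_energy,
               K0_umol_L = fK$normalisation, E_K_eV = fK$activation_energy,
               T_ref_C = T_ref_C,
               se_B0 = fmu$se_normalisation, se_E_mu = fmu$se_activation,
               se_K0 = fK$se_normalisation, se_E_K = fK$se_activation,
               n_points = fmu$n_points, stringsAsFactors = FALSE)
  })
  species_names <- names(res)
  traits <- do.call(rbind, res)
  traits$species <- species_names
  rownames(traits) <- NULL
  traits
}
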