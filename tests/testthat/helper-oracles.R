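# Independent oracle implementations used to cross-check the package.
# These transcribe the model formulas step by step and share no code with
# the package internals.

K_EV <- 8.617333e-5  # Boltzmann constant, eV / K

# Step-by-step evaluation of the Arrhenius-Monod growth-rate composition.
oracle_mu_max <- function(B0, E_mu, T_K, T_ref_K) {
  boltz <- (1 / T_K - 1 / T_ref_K) / K_EV
  B0 * exp(-E_mu * boltz)
}

oracle_K_S <- function(K0, E_K, T_K, T_ref_K) {
  boltz <- (1 / T_K - 1 / T_ref_K) / K_EV
  K0 * exp(-E_K * boltz)
}

oracle_mu <- function(B0, E_mu, K0, E_K, T_K, S, T_ref_K) {
  mm <- oracle_mu_max(B0, E_mu, T_K, T_ref_K)
  ks <- oracle_K_S(K0, E_K, T_K, T_ref_K)
  mm * S / (ks + S)
}

oracle_R <- function(a, b, T_K, S, t) {
  mu_a <- oracle_mu(a$B0, a$E_mu, a$K0, a$E_K, T_K, S, a$T_ref_K)
  mu_b <- oracle_mu(b$B0, b$E_mu, b$K0, b$E_K, T_K, S, b$T_ref_K)
  (mu_a - mu_b) * t
}

oracle_Rinf <- function(a, b, T_K, t) {
  (oracle_mu_max(a$B0, a$E_mu, T_K, a$T_ref_K) -
     oracle_mu_max(b$B0, b$E_mu, T_K, b$T_ref_K)) * t
}

# Random but valid metabolic traits for property-style tests.
random_traits <- function(n = 1) {
  lapply(seq_len(n), function(i)
    metabolic_traits(B0 = runif(1, 0.1, 2), E_mu = runif(1, -0.5, 1.5),
                     K0 = runif(1, 0.01, 5), E_K = runif(1, -0.5, 1.5)))
}

# Coarse grid search oracle for the Buchanan fit: exhaustive grid over
# (t_lag, t_max, mu) with N0 and Nmax profiled analytically per assignment
# (phase means / ramp-adjusted mean), Nmax clamped to stay >= N0.
oracle_buchanan_grid_rss <- function(t, y, t_step = 0.5, mu_grid = seq(0.05, 3, by = 0.05)) {
  knots <- seq(0, max(t), by = t_step)
  best <- Inf
  for (t_lag in knots) {
    for (t_max in knots[knots >= t_lag]) {
      A <- t <= t_lag; C <- t >= t_max; B <- !A & !C
      ramp <- ifelse(B, t - t_lag, 0)
      for (mu in mu_grid) {
        # N0 minimises the A+B residuals at fixed mu; Nmax the C residuals.
        N0 <- mean((y - mu * ramp)[A | B])
        if (!is.finite(N0)) next
        Nmax <- if (any(C)) max(mean(y[C]), N0) else N0
        pred <- ifelse(A, N0, ifelse(C, Nmax, N0 + mu * (t - t_lag)))
        rss <- sum((pred - y)^2)
        if (rss < best) best <- rss
      }
    }
  }
  best
}

# Noiseless three-phase curve in the growth_curves.csv schema, built directly
# from its defining parameters (independent of the package generator).
make_buchanan_curve <- function(days, t_lag, mu, N0_log, Nmax_log,
                                sigma = 0, species = "sp", T_C = 20,
                                S = 1, replicate = 1) {
  ln_N <- pmin(N0_log + mu * pmax(days - t_lag, 0), Nmax_log)
  if (sigma > 0) ln_N <- ln_N + rnorm(length(days), 0, sigma) * log(10)
  data.frame(species = species, temperature_C = T_C, phosphate_umol_L = S,
             replicate = replicate, day = days,
             density_cells_per_mL = exp(ln_N), stringsAsFactors = FALSE)
}
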