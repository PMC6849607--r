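# Synthetic monoculture and competition experiments with known ground-truth
# traits. The defaults emulate a factorial phytoplankton study: monocultures
# across 5 temperatures x 13 phosphate concentrations x 3 replicates sampled
# every 2 days for a month, and pairwise competition trials at 2 temperatures
# x 3 phosphate levels x 6 replicates sampled at days 5, 14 and 23, all
# inoculated at 100 cells per mL.

#' Factorial experiment design
#'
#' @param temperatures_C incubation temperatures in Celsius (nonempty,
#'   finite).
#' @param phosphate_umol_L phosphate concentrations in umol L^-1 (all > 0).
#' @param n_replicates replicates per condition (>= 1).
#' @param sampling_days census days, strictly increasing, >= 0.
#' @param inoculum_cells_per_mL starting density of each species (> 0).
#' @param volume_mL culture volume (documentation only).
#' @return object of class `experiment_design`.
#' @seealso [monoculture_design()], [competition_design()] for the default
#'   grids.
#' @export
experiment_design <- function(temperatures_C, phosphate_umol_L, n_replicates,
                              sampling_days, inoculum_cells_per_mL = 100,
                              volume_mL = NA_real_) {
  # accept list-shaped numeric input (e.g. from YAML configs)
  temperatures_C <- as.numeric(unlist(temperatures_C))
  phosphate_umol_L <- as.numeric(unlist(phosphate_umol_L))
  sampling_days <- as.numeric(unlist(sampling_days))
  if (length(temperatures_C) == 0 || any(!is.finite(temperatures_C)))
    stopf("temperatures_C must be nonempty and finite")
  if (any(phosphate_umol_L <= 0)) stopf("all phosphate values must be > 0")
  if (n_replicates < 1) stopf("n_replicates must be >= 1")
  if (any(sampling_days < 0) || any(diff(sampling_days) <= 0))
    stopf("sampling_days must be strictly increasing and >= 0")
  if (inoculum_cells_per_mL <= 0) stopf("inoculum must be > 0")
  structure(list(temperatures_C = temperatures_C,
                 phosphate_umol_L = phosphate_umol_L,
                 n_replicates = as.integer(n_replicates),
                 sampling_days = sampling_days,
                 inoculum_cells_per_mL = inoculum_cells_per_mL,
                 volume_mL = volume_mL),
            class = "experiment_design")
}

#' Default experiment designs
#'
#' `monoculture_design()` is the trait-measurement design: 15-35 C in 5 C
#' steps, 13 log-spaced phosphate levels spanning 0.01-50 umol L^-1
#' (log-spacing concentrates resolution near typical half-saturation
#' constants), 3 replicates, sampled every 2 days for 30 days, 100 cells
#' mL^-1 inocula in 40 mL flasks. `competition_design()` is the pairwise
#' competition design: 15 and 25 C, phosphate at 0.1, 1 and 30 umol L^-1,
#' 6 replicates, sampled at days 5, 14 and 23, 100 cells mL^-1 of each
#' species in 2 mL wells.
#'
#' @return an [experiment_design()] object.
#' @export
monoculture_design <- function() {
  experiment_design(
    temperatures_C = c(15, 20, 25, 30, 35),
    phosphate_umol_L = exp(seq(log(0.01), log(50), length.out = 13)),
    n_replicates = 3,
    sampling_days = seq(0, 30, by = 2),
    inoculum_cells_per_mL = 100,
    volume_mL = 40)
}

#' @rdname monoculture_design
#' @export
competition_design <- function() {
  experiment_design(
    temperatures_C = c(15, 25),
    phosphate_umol_L = c(0.1, 1, 30),
    n_replicates = 6,
    sampling_days = c(5, 14, 23),
    inoculum_cells_per_mL = 100,
    volume_mL = 2)
}

#' Observation noise model for synthetic experiments
#'
#' @param sigma_log10 standard deviation of additive Gaussian noise on
#'   log10 density (multiplicative on density); >= 0. Default 0.05.
#' @param misclassification_rate probability that a counted cell in a
#'   competition trial is assigned to the wrong species, in `[0, 0.5)`.
#' @param seed default seed used by simulators when no explicit seed is
#'   passed.
#' @return object of class `noise_model`.
#' @export
noise_model <- function(sigma_log10 = 0.05, misclassification_rate = 0,
                        seed = NULL) {
  if (sigma_log10 < 0) stopf("sigma_log10 must be >= 0")
  if (misclassification_rate < 0 || misclassification_rate >= 0.5)
    stopf("misclassification_rate must be in [0, 0.5)")
  structure(list(sigma_log10 = sigma_log10,
                 misclassification_rate = misclassification_rate,
                 seed = seed),
            class = "noise_model")
}

#' Default trait ranges for sampling synthetic species panels
#'
#' Uniform sampling bounds for each generative trait, sized to the spread of
#' metabolic traits reported for small freshwater green algae: maximum
#' growth rates of a fraction of a day^-1 at 15 C, activation energies
#' bracketing the canonical ~0.6 eV, sub-micromolar half-saturation
#' constants, lags of a few days, stationary plateaus of 1-3 million cells
#' mL^-1 and femtomole-scale per-cell phosphorus quotas. The ranges keep
#' realised growth rates at or below ~2 d^-1 at 25 C, so the exponential
#' phase always spans several 2-day censuses of the default monoculture
#' design.
#'
#' @return named list of `c(low, high)` bounds for `B0_per_day`, `E_mu_eV`,
#'   `K0_umol_L`, `E_K_eV`, `t_lag_days`, `Nmax_log10`,
#'   `quota_umolP_per_cell`.
#' @export
default_trait_ranges <- function() {
  list(B0_per_day = c(0.3, 0.8),
       E_mu_eV = c(0.2, 0.75),
       K0_umol_L = c(0.05, 0.5),
       E_K_eV = c(0.1, 0.9),
       t_lag_days = c(0, 3),
       Nmax_log10 = c(6.0, 6.5),
       quota_umolP_per_cell = c(5e-9, 2e-8))
}

#' Sample a panel of synthetic species with known metabolic traits
#'
#' Draws each trait independently and uniformly within its range. The
#' resulting table doubles as the ground-truth `true_traits.csv` artifact.
#'
#' @param n_species number of species (>= 2).
#' @param trait_ranges named list of `c(low, high)` bounds; see
#'   [default_trait_ranges()]. Degenerate ranges with `low == high` are
#'   allowed (all species identical in that trait); `low > high` is
#'   rejected.
#' @param seed integer seed; the panel is deterministic given the seed.
#' @param T_ref_C reference temperature attached to the traits (default 15).
#' @return data frame with columns `species`, `B0_per_day`, `E_mu_eV`,
#'   `K0_umol_L`, `E_K_eV`, `T_ref_C`, `t_lag_days`, `Nmax_log10`,
#'   `quota_umolP_per_cell`.
#' @export
sample_species_panel <- function(n_species, trait_ranges = default_trait_ranges(),
                                 seed = NULL, T_ref_C = 15) {
  if (n_species < 2) stopf("n_species must be >= 2")
  trait_ranges <- modifyList(default_trait_ranges(), trait_ranges)
  for (nm in names(trait_ranges)) {
    r <- trait_ranges[[nm]]
    if (length(r) != 2 || any(!is.finite(r)) || r[1] > r[2])
      stopf("invalid range for trait '%s': need finite low <= high", nm)
  }
  draws <- with_seed(seed, {
    vapply(trait_ranges, function(r) runif(n_species, r[1], r[2]),
           numeric(n_species))
  })
  draws <- matrix(draws, nrow = n_species,
                  dimnames = list(NULL, names(trait_ranges)))
  panel <- data.frame(species = sprintf("sp%02d", seq_len(n_species)),
                      draws, T_ref_C = T_ref_C, stringsAsFactors = FALSE)
  panel[, c("species", "B0_per_day", "E_mu_eV", "K0_umol_L", "E_K_eV",
            "T_ref_C", "t_lag_days", "Nmax_log10", "quota_umolP_per_cell")]
}

#' Metabolic traits of one panel row
#'
#' @param panel a species panel from [sample_species_panel()] (or any data
#'   frame in the `true_traits.csv` schema).
#' @param species species identifier (defaults to the first row).
#' @return a [metabolic_traits()] object.
#' @export
panel_traits <- function(panel, species = panel$species[1]) {
  row <- panel[panel$species == species, , drop = FALSE]
  if (nrow(row) != 1) stopf("species '%s' not found uniquely in panel", species)
  metabolic_traits(row$B0_per_day, row$E_mu_eV, row$K0_umol_L, row$E_K_eV,
                   celsius_to_kelvin(row$T_ref_C))
}

# Noiseless log10 density of one species on the three-phase trajectory:
# flat at the inoculum through the lag, exponential at the realised Monod-
# Arrhenius rate, capped at the species' stationary plateau.
three_phase_log10 <- function(days, mu, t_lag, log10_N0, Nmax_log10) {
  ln_N0 <- log10_N0 * log(10)
  ln_Nmax <- Nmax_log10 * log(10)
  ln_N <- pmin(ln_N0 + mu * pmax(days - t_lag, 0), ln_Nmax)
  ln_N / log(10)
}

#' Simulate one monoculture growth curve
#'
#' Generates a density time series on the sampling grid of `design` for one
#' species at one temperature x phosphate condition. The noiseless log
#' density is flat at the inoculum until `t_lag_days`, rises linearly in
#' natural-log space at the realised growth rate `mu(T, S)` (Monod in `S`,
#' Boltzmann-Arrhenius in `T`), and is capped at the species' stationary
#' plateau `Nmax_log10`. Gaussian noise of sd `sigma_log10` is added on the
#' log10 scale, keeping densities strictly positive.
#'
#' @param sp one-row species panel entry (see [sample_species_panel()]).
#' @param T_C temperature in Celsius.
#' @param S phosphate concentration in umol L^-1 (> 0).
#' @param design an [experiment_design()].
#' @param noise a [noise_model()].
#' @param replicate replicate index recorded in the output.
#' @param seed integer seed (default: the noise model's seed).
#' @return data frame in the `growth_curves.csv` schema with attribute
#'   `flagged = TRUE` when the realised growth rate is not positive (flat
#'   no-growth curve).
#' @export
simulate_growth_curve <- function(sp, T_C, S, design, noise = noise_model(),
                                  replicate = 1L, seed = noise$seed) {
  if (S <= 0) stopf("S must be > 0")
  stopifnot(inherits(design, "experiment_design"), inherits(noise, "noise_model"))
  traits <- metabolic_traits(sp$B0_per_day, sp$E_mu_eV, sp$K0_umol_L,
                             sp$E_K_eV, celsius_to_kelvin(sp$T_ref_C))
  mu <- realised_growth_rate(traits, celsius_to_kelvin(T_C), S)
  days <- design$sampling_days
  log10_N0 <- log10(design$inoculum_cells_per_mL)
  flagged <- mu <= 0
  l10 <- if (flagged) rep(log10_N0, length(days))
         else three_phase_log10(days, mu, sp$t_lag_days, log10_N0, sp$Nmax_log10)
  if (noise$sigma_log10 > 0)
    l10 <- l10 + with_seed(seed, rnorm(length(days), 0, noise$sigma_log10))
  out <- data.frame(species = sp$species, temperature_C = T_C,
                    phosphate_umol_L = S, replicate = as.integer(replicate),
                    day = days, density_cells_per_mL = 10^l10,
                    stringsAsFactors = FALSE)
  attr(out, "flagged") <- flagged
  out
}

#' Simulate a full monoculture trait experiment
#'
#' Runs [simulate_growth_curve()] over every species x temperature x
#' phosphate x replicate cell of `design`, with deterministic per-curve
#' sub-seeds derived from `seed`.
#'
#' @param panel species panel from [sample_species_panel()].
#' @param design an [experiment_design()]; default [monoculture_design()].
#' @param noise a [noise_model()].
#' @param seed integer seed for the whole experiment.
#' @return data frame in the `growth_curves.csv` schema.
#' @export
simulate_monoculture_experiment <- function(panel,
                                            design = monoculture_design(),
                                            noise = noise_model(),
                                            seed = noise$seed) {
  grid <- expand.grid(sp = seq_len(nrow(panel)),
                      T_C = design$temperatures_C,
                      S = design$phosphate_umol_L,
                      rep = seq_len(design$n_replicates),
                      KEEP.OUT.ATTRS = FALSE)
  res <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    res[[i]] <- simulate_growth_curve(panel[g$sp, ], g$T_C, g$S, design,
                                      noise, replicate = g$rep,
                                      seed = substream_seed(seed, i))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# Per-record binomial species swap: each counted cell keeps its label with
# probability 1 - m and defects to the other species with probability m.
misclassify_counts <- function(na, nb, m) {
  if (m <= 0) return(cbind(na, nb))
  na_int <- round(na); nb_int <- round(nb)
  keep_a <- rbinom(length(na_int), na_int, 1 - m)
  move_b <- rbinom(length(nb_int), nb_int, m)
  cbind(keep_a + move_b, (na_int - keep_a) + (nb_int - move_b))
}

#' Simulate one pairwise competition trial
#'
#' Both species start at the design inoculum. Without nutrient depletion
#' each grows exponentially at its realised rate `mu_i(T, S0)` (no lag, the
#' co-invasion assumption of the competition theory), capped at its own
#' stationary plateau. With `depletion = TRUE` the trial integrates the
#' batch-culture system `dN_i/dt = mu_i(T, S(t)) N_i` (capped at the
#' plateau), `dS/dt = -sum_i quota_i mu_i N_i` with `S(t) >= 0`, using a
#' fixed per-cell phosphorus quota. Observed counts then pass through the
#' binomial misclassification swap and multiplicative log10 noise of the
#' noise model.
#'
#' @param a,b one-row species panel entries (may be the same species).
#' @param T_C temperature in Celsius.
#' @param S0 initial phosphate concentration, umol L^-1 (> 0).
#' @param design an [experiment_design()]; default [competition_design()].
#' @param noise a [noise_model()].
#' @param depletion simulate nutrient drawdown (default `FALSE`).
#' @param seed integer seed; the trial is deterministic given the seed.
#' @return data frame in the `competition_counts.csv` schema (`species_a`,
#'   `species_b`, `temperature_C`, `phosphate_umol_L`, `replicate`, `day`,
#'   `density_a`, `density_b`), one row per replicate x sampling day.
#' @export
simulate_competition_trial <- function(a, b, T_C, S0,
                                       design = competition_design(),
                                       noise = noise_model(),
                                       depletion = FALSE, seed = noise$seed) {
  if (S0 <= 0) stopf("S0 must be > 0")
  stopifnot(inherits(design, "experiment_design"), inherits(noise, "noise_model"))
  T_K <- celsius_to_kelvin(T_C)
  tr_a <- metabolic_traits(a$B0_per_day, a$E_mu_eV, a$K0_umol_L, a$E_K_eV,
                           celsius_to_kelvin(a$T_ref_C))
  tr_b <- metabolic_traits(b$B0_per_day, b$E_mu_eV, b$K0_umol_L, b$E_K_eV,
                           celsius_to_kelvin(b$T_ref_C))
  days <- design$sampling_days
  N0 <- design$inoculum_cells_per_mL
  cap_a <- 10^a$Nmax_log10; cap_b <- 10^b$Nmax_log10

  if (!depletion) {
    mu_a <- realised_growth_rate(tr_a, T_K, S0)
    mu_b <- realised_growth_rate(tr_b, T_K, S0)
    Na <- pmin(N0 * exp(mu_a * days), cap_a)
    Nb <- pmin(N0 * exp(mu_b * days), cap_b)
    traj <- cbind(Na, Nb)
  } else {
    # Monod-Arrhenius parameters are fixed at T; only S evolves.
    mm_a <- arrhenius_value(tr_a$B0, tr_a$E_mu, T_K, tr_a$T_ref_K)
    KS_a <- arrhenius_value(tr_a$K0, tr_a$E_K, T_K, tr_a$T_ref_K)
    mm_b <- arrhenius_value(tr_b$B0, tr_b$E_mu, T_K, tr_b$T_ref_K)
    KS_b <- arrhenius_value(tr_b$K0, tr_b$E_K, T_K, tr_b$T_ref_K)
    rhs <- function(t, y, p) {
      S <- max(y[3], 0)
      mu_a <- mm_a * S / (KS_a + S) * (y[1] < cap_a)
      mu_b <- mm_b * S / (KS_b + S) * (y[2] < cap_b)
      dNa <- mu_a * y[1]
      dNb <- mu_b * y[2]
      list(c(dNa, dNb, -(a$quota_umolP_per_cell * dNa +
                           b$quota_umolP_per_cell * dNb) * 1000))
    }
    # quota is umol P per cell, densities are cells mL^-1, S is umol L^-1:
    # the factor 1000 converts per-mL drawdown to per-L.
    times <- sort(unique(c(0, days)))
    sol <- deSolve::ode(y = c(N0, N0, S0), times = times, func = rhs,
                        parms = NULL, rtol = 1e-8, atol = 1e-8)
    traj <- sol[match(days, times), 2:3, drop = FALSE]
  }

  grid <- expand.grid(rep = seq_len(design$n_replicates),
                      di = seq_along(days), KEEP.OUT.ATTRS = FALSE)
  with_seed(seed, {
    Na <- traj[grid$di, 1]; Nb <- traj[grid$di, 2]
    obs <- misclassify_counts(Na, Nb, noise$misclassification_rate)
    if (noise$sigma_log10 > 0) {
      jitter <- function(v) ifelse(v > 0,
        10^(log10(pmax(v, .Machine$double.xmin)) +
              rnorm(length(v), 0, noise$sigma_log10)), 0)
      obs <- cbind(jitter(obs[, 1]), jitter(obs[, 2]))
    }
    data.frame(species_a = a$species, species_b = b$species,
               temperature_C = T_C, phosphate_umol_L = S0,
               replicate = as.integer(grid$rep), day = days[grid$di],
               density_a = obs[, 1], density_b = obs[, 2],
               stringsAsFactors = FALSE)
  })
}

#' Simulate the full pairwise competition experiment
#'
#' All unordered species pairs of the panel, crossed with the temperatures
#' and phosphate levels of `design`, each via
#' [simulate_competition_trial()] with deterministic sub-seeds.
#'
#' @inheritParams simulate_competition_trial
#' @param panel species panel from [sample_species_panel()].
#' @return data frame in the `competition_counts.csv` schema.
#' @export
simulate_competition_experiment <- function(panel,
                                            design = competition_design(),
                                            noise = noise_model(),
                                            depletion = FALSE,
                                            seed = noise$seed) {
  pairs <- utils::combn(sort(panel$species), 2)
  grid <- expand.grid(pair = seq_len(ncol(pairs)),
                      T_C = design$temperatures_C,
                      S0 = design$phosphate_umol_L, KEEP.OUT.ATTRS = FALSE)
  res <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    a <- panel[panel$species == pairs[1, g$pair], ]
    b <- panel[panel$species == pairs[2, g$pair], ]
    res[[i]] <- simulate_competition_trial(a, b, g$T_C, g$S0, design, noise,
                                           depletion = depletion,
                                           seed = substream_seed(seed, i))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Write or read a pipeline table
#'
#' Thin CSV wrappers that keep every artifact round-trippable: plain
#' comma-separated files with a header row and no row names.
#'
#' @param records data frame to write.
#' @param path file path.
#' @return `write_dataset()` returns `path` invisibly; `read_dataset()`
#'   returns a data frame.
#' @export
write_dataset <- function(records, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  read.csv(path, stringsAsFactors = FALSE)
}
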