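# Theory core: competitive advantage of two exponentially growing phytoplankton
# species whose Monod parameters carry Boltzmann-Arrhenius temperature
# dependence. Temperatures are Kelvin at this level; Celsius belongs to the
# file/CLI boundary.

#' Metabolic traits of one species
#'
#' Bundles the four metabolic traits that parameterise the competition model:
#' the normalisation constants `B0` (maximum growth rate at the reference
#' temperature, d^-1) and `K0` (half-saturation constant at the reference
#' temperature, umol L^-1), and the activation energies `E_mu` and `E_K` (eV)
#' that set the thermal sensitivity of each. Together with the reference
#' temperature they determine the realised growth rate at any temperature and
#' nutrient concentration.
#'
#' @param B0 maximum specific growth rate at `T_ref_K` (d^-1), > 0.
#' @param E_mu activation energy of the maximum growth rate (eV).
#' @param K0 half-saturation constant at `T_ref_K` (umol L^-1), > 0.
#' @param E_K activation energy of the half-saturation constant (eV).
#' @param T_ref_K reference temperature in Kelvin (default 15 degrees C).
#' @return an object of class `metabolic_traits`.
#' @examples
#' tr <- metabolic_traits(B0 = 0.8, E_mu = 0.6, K0 = 0.3, E_K = 0.4)
#' realised_growth_rate(tr, celsius_to_kelvin(25), S = 1)
#' @export
metabolic_traits <- function(B0, E_mu, K0, E_K,
                             T_ref_K = celsius_to_kelvin(15)) {
  if (!is.finite(B0) || B0 <= 0) stopf("B0 must be finite and > 0, got %s", B0)
  if (!is.finite(K0) || K0 <= 0) stopf("K0 must be finite and > 0, got %s", K0)
  if (!is.finite(T_ref_K) || T_ref_K <= 0) stopf("T_ref_K must be > 0")
  if (!is.finite(E_mu) || !is.finite(E_K)) stopf("activation energies must be finite")
  structure(list(B0 = B0, E_mu = E_mu, K0 = K0, E_K = E_K, T_ref_K = T_ref_K),
            class = "metabolic_traits")
}

#' @export
print.metabolic_traits <- function(x, ...) {
  cat(sprintf(
    "Metabolic traits (T_ref = %.2f K / %.1f C):\n  B0 = %.4g d^-1, E_mu = %.4g eV\n  K0 = %.4g umol L^-1, E_K = %.4g eV\n",
    x$T_ref_K, kelvin_to_celsius(x$T_ref_K), x$B0, x$E_mu, x$K0, x$E_K))
  invisible(x)
}

#' Boltzmann-Arrhenius trait value at a temperature
#'
#' Evaluates `normalisation * exp(-E/k * (1/T - 1/T_ref))`, the
#' Boltzmann-Arrhenius model of exponential trait-temperature dependence
#' within an operational temperature range. `k` is the Boltzmann constant in
#' eV K^-1.
#'
#' @param normalisation trait value at the reference temperature (> 0).
#' @param activation_energy thermal sensitivity in eV.
#' @param T_K temperature(s) in Kelvin.
#' @param T_ref_K reference temperature in Kelvin.
#' @return trait value(s) at `T_K`; equals `normalisation` at `T_ref_K`.
#' @export
arrhenius_value <- function(normalisation, activation_energy, T_K, T_ref_K) {
  if (any(T_K <= 0) || any(T_ref_K <= 0))
    stopf("temperatures must be positive Kelvin values")
  normalisation * exp(-activation_energy / boltzmann_eV_K * (1 / T_K - 1 / T_ref_K))
}

#' Monod nutrient-limited growth rate
#'
#' The Monod model `mu = mu_max * S / (K_S + S)`: growth saturates towards
#' `mu_max` as nutrient concentration `S` rises and is half-maximal at
#' `S = K_S`.
#'
#' @param S nutrient (phosphate) concentration, umol L^-1, >= 0.
#' @param mu_max maximum specific growth rate (d^-1), > 0.
#' @param K_S half-saturation constant (umol L^-1), > 0.
#' @return growth rate(s) in d^-1, in `[0, mu_max)`.
#' @export
monod_mu <- function(S, mu_max, K_S) {
  if (any(S < 0)) stopf("nutrient concentration S must be >= 0")
  if (any(mu_max <= 0) || any(K_S <= 0)) stopf("mu_max and K_S must be > 0")
  mu_max * S / (K_S + S)
}

#' Realised growth rate at a temperature and nutrient concentration
#'
#' Composes the Monod model with the Boltzmann-Arrhenius temperature
#' dependence of both `mu_max` and `K_S`:
#' `mu(T, S) = mu_max(T) * S / (K_S(T) + S)`.
#'
#' @param traits a [metabolic_traits()] object.
#' @param T_K temperature in Kelvin (vectorised).
#' @param S nutrient concentration in umol L^-1 (vectorised), >= 0.
#' @return realised specific growth rate(s), d^-1.
#' @export
realised_growth_rate <- function(traits, T_K, S) {
  stopifnot(inherits(traits, "metabolic_traits"))
  mu_max <- arrhenius_value(traits$B0, traits$E_mu, T_K, traits$T_ref_K)
  K_S <- arrhenius_value(traits$K0, traits$E_K, T_K, traits$T_ref_K)
  monod_mu(S, mu_max, K_S)
}

# |R| below this is treated as a numerical tie; real ties only arise from
# identical traits.
TIE_TOLERANCE <- 1e-12

winner_from_R <- function(R) {
  ifelse(abs(R) < TIE_TOLERANCE, "tie", ifelse(R > 0, "a", "b"))
}

#' Competitive advantage of species a over species b
#'
#' For two species co-invading a fresh environment at equal inocula and
#' growing exponentially at constant nutrient concentration `S`, the log
#' abundance ratio after `t_days` is
#' `R = ln(N_a(t)/N_b(t)) = (mu_a(T, S) - mu_b(T, S)) * t`, written with the
#' common nutrient factor outside the bracket of per-species Monod terms:
#' `R = S * (mu_max_a(T)/(K_a(T)+S) - mu_max_b(T)/(K_b(T)+S)) * t`.
#' Species a wins when `R > 0`, species b when `R < 0`; `R = 0` is a tie.
#'
#' `competitive_advantage_Rinf()` is the nutrient-saturated limit
#' `R_inf = (mu_max_a(T) - mu_max_b(T)) * t`, which depends only on the
#' `B0` and `E_mu` traits.
#'
#' @param a,b [metabolic_traits()] objects for the two species.
#' @param T_K temperature in Kelvin.
#' @param S nutrient concentration, umol L^-1.
#' @param t_days time horizon in days (> 0); default 14, a typical
#'   mid-experiment census day.
#' @return a list of class `competition_prediction` with elements `R`,
#'   `winner` ("a", "b" or "tie"), `temperature_K`, `phosphate_umol_L`
#'   (`NA` in the saturated variant), `t_days` and `mode`.
#' @examples
#' a <- metabolic_traits(0.8, 0.9, 0.3, 0.4)
#' b <- metabolic_traits(1.0, 0.3, 0.3, 0.4)
#' competitive_advantage_R(a, b, celsius_to_kelvin(25), S = 1)
#' competitive_advantage_Rinf(a, b, celsius_to_kelvin(25))
#' @export
competitive_advantage_R <- function(a, b, T_K, S, t_days = 14) {
  stopifnot(inherits(a, "metabolic_traits"), inherits(b, "metabolic_traits"))
  if (any(t_days <= 0)) stopf("t_days must be > 0")
  if (any(S < 0)) stopf("S must be >= 0")
  term <- function(tr) {
    arrhenius_value(tr$B0, tr$E_mu, T_K, tr$T_ref_K) /
      (arrhenius_value(tr$K0, tr$E_K, T_K, tr$T_ref_K) + S)
  }
  R <- S * (term(a) - term(b)) * t_days
  structure(list(R = R, winner = winner_from_R(R), temperature_K = T_K,
                 phosphate_umol_L = S, t_days = t_days, mode = "R"),
            class = "competition_prediction")
}

#' @rdname competitive_advantage_R
#' @export
competitive_advantage_Rinf <- function(a, b, T_K, t_days = 14) {
  stopifnot(inherits(a, "metabolic_traits"), inherits(b, "metabolic_traits"))
  if (any(t_days <= 0)) stopf("t_days must be > 0")
  R <- (arrhenius_value(a$B0, a$E_mu, T_K, a$T_ref_K) -
          arrhenius_value(b$B0, b$E_mu, T_K, b$T_ref_K)) * t_days
  structure(list(R = R, winner = winner_from_R(R), temperature_K = T_K,
                 phosphate_umol_L = NA_real_, t_days = t_days, mode = "Rinf"),
            class = "competition_prediction")
}

#' @export
print.competition_prediction <- function(x, ...) {
  cat(sprintf("Competitive advantage (%s): R = %.4g at T = %.2f K", x$mode,
              x$R[1], x$temperature_K[1]))
  if (x$mode == "R") cat(sprintf(", S = %.3g umol/L", x$phosphate_umol_L[1]))
  cat(sprintf(", t = %g d -> winner: %s\n", x$t_days, x$winner[1]))
  invisible(x)
}

#' Temperature at which the nutrient-saturated advantage changes sign
#'
#' Under nutrient saturation the winner flips at the unique temperature
#' `T*` where the two maximum-growth-rate curves cross:
#' `1/T* = 1/T_ref + k * ln(B0_a/B0_b) / (E_mu_a - E_mu_b)`.
#' This makes the trade-off between normalisation constants and activation
#' energies explicit: at `T_ref` the larger `B0` wins, far above `T_ref` the
#' larger `E_mu` wins.
#'
#' @param a,b [metabolic_traits()] objects. Must share `T_ref_K`.
#' @return a list with `T_K` (crossing temperature in Kelvin, or `NA` when no
#'   positive finite crossing exists) and `status`: `"crossing"`, `"none"`
#'   (equal `E_mu` with unequal `B0`, or `T* <= 0`), or `"degenerate"`
#'   (identical `B0` and `E_mu`: every temperature is a crossing).
#' @export
crossing_temperature <- function(a, b) {
  stopifnot(inherits(a, "metabolic_traits"), inherits(b, "metabolic_traits"))
  if (a$T_ref_K != b$T_ref_K)
    stopf("species must share a reference temperature")
  dE <- a$E_mu - b$E_mu
  lnB <- log(a$B0 / b$B0)
  if (dE == 0) {
    if (lnB == 0)
      return(list(T_K = NA_real_, status = "degenerate"))
    return(list(T_K = NA_real_, status = "none"))
  }
  inv_T <- 1 / a$T_ref_K + boltzmann_eV_K * lnB / dE
  if (inv_T <= 0) return(list(T_K = NA_real_, status = "none"))
  list(T_K = 1 / inv_T, status = "crossing")
}

#' Predict a competitive reversal between two temperatures
#'
#' A reversal means the sign of the competitive advantage (and hence the
#' winning species) differs between two temperatures.
#'
#' @param a,b [metabolic_traits()] objects.
#' @param T1_K,T2_K the two temperatures in Kelvin (must differ).
#' @param S nutrient concentration for the full model, or `NULL` for the
#'   nutrient-saturated variant.
#' @param t_days horizon in days (the outcome is t-invariant).
#' @return a list with `reversal` (logical, `NA` when indeterminate),
#'   `R1`, `R2` and `status` (`"determinate"` or `"indeterminate"` when
#'   either advantage is exactly zero).
#' @export
predict_reversal <- function(a, b, T1_K, T2_K, S = NULL, t_days = 14) {
  if (T1_K == T2_K) stopf("T1_K and T2_K must differ")
  adv <- function(T_K) {
    if (is.null(S)) competitive_advantage_Rinf(a, b, T_K, t_days)$R
    else competitive_advantage_R(a, b, T_K, S, t_days)$R
  }
  R1 <- adv(T1_K); R2 <- adv(T2_K)
  if (abs(R1) < TIE_TOLERANCE || abs(R2) < TIE_TOLERANCE)
    return(list(reversal = NA, R1 = R1, R2 = R2, status = "indeterminate"))
  list(reversal = sign(R1) != sign(R2), R1 = R1, R2 = R2,
       status = "determinate")
}

#' Predicted advantage for every unordered pair over a condition grid
#'
#' Materialises model predictions for all `C(n, 2)` species pairs across a
#' temperature-by-nutrient grid. In `"Rinf"` mode the nutrient axis is
#' ignored and `phosphate_umol_L` is `NA`.
#'
#' @param traits_table data frame of per-species traits with columns
#'   `species`, `B0_per_day`, `E_mu_eV`, `K0_umol_L`, `E_K_eV`, `T_ref_C`
#'   (the `metabolic_traits.csv` schema).
#' @param temperatures_C temperatures in Celsius.
#' @param phosphate_umol_L nutrient concentrations (ignored in `"Rinf"` mode).
#' @param t_days prediction horizon in days.
#' @param mode `"R"` (nutrient-explicit) or `"Rinf"` (saturated).
#' @return data frame with columns `species_a`, `species_b`,
#'   `temperature_C`, `phosphate_umol_L`, `t_days`, `mode`, `R`, `winner`;
#'   pairs are ordered so `species_a < species_b` alphabetically, and the
#'   antisymmetric orientation is fixed by that ordering.
#' @export
prediction_grid <- function(traits_table, temperatures_C,
                            phosphate_umol_L = NA_real_, t_days = 14,
                            mode = c("R", "Rinf")) {
  mode <- match.arg(mode)
  check_columns(traits_table,
                c("species", "B0_per_day", "E_mu_eV", "K0_umol_L", "E_K_eV",
                  "T_ref_C"), "traits_table")
  if (nrow(traits_table) < 2) stopf("need at least two species to form pairs")
  sp <- sort(as.character(traits_table$species))
  tr <- lapply(seq_len(nrow(traits_table)), function(i) {
    with(traits_table[i, ],
         metabolic_traits(B0_per_day, E_mu_eV, K0_umol_L, E_K_eV,
                          celsius_to_kelvin(T_ref_C)))
  })
  names(tr) <- as.character(traits_table$species)

  pairs <- utils::combn(sp, 2)
  S_levels <- if (mode == "Rinf") NA_real_ else phosphate_umol_L
  grid <- expand.grid(pair = seq_len(ncol(pairs)),
                      temperature_C = temperatures_C,
                      phosphate_umol_L = S_levels,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    a <- pairs[1, g$pair]; b <- pairs[2, g$pair]
    T_K <- celsius_to_kelvin(g$temperature_C)
    pred <- if (mode == "Rinf")
      competitive_advantage_Rinf(tr[[a]], tr[[b]], T_K, t_days)
    else
      competitive_advantage_R(tr[[a]], tr[[b]], T_K, g$phosphate_umol_L, t_days)
    data.frame(species_a = a, species_b = b,
               temperature_C = g$temperature_C,
               phosphate_umol_L = g$phosphate_umol_L,
               t_days = t_days, mode = mode, R = pred$R,
               winner = pred$winner, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
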