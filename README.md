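# thermocompete

Predicting the outcome of pairwise phytoplankton competition from
metabolic traits.

Temperature and nutrient availability jointly set which of two
phytoplankton species outgrows the other. `thermocompete` implements a
trait-based pipeline for that question, aimed at quantitative ecologists
working with factorial temperature × nutrient growth experiments:

1. **Growth fitting** — specific growth rates µ (d⁻¹) are estimated from
   monoculture density time series with the Buchanan three-phase linear
   model (lag / exponential / stationary), fitted by multi-start
   Levenberg–Marquardt least squares with AICc start selection.
2. **Trait fitting** — per-temperature Monod parameters
   µ = µ_max·S/(K_S + S) are reduced to four *metabolic traits* per
   species via Boltzmann–Arrhenius fits within an operational temperature
   range (OTR, 15–25 °C): the normalisation constants B₀ (µ_max at
   T_ref = 15 °C) and K₀ (K_S at T_ref), and the activation energies
   E_µ and E_K (eV).
3. **Competition theory** — under equal inocula and exponential
   co-invasion, the competitive advantage of species *a* over *b* is the
   log abundance ratio

       R = ln(N_a(t)/N_b(t)) = (µ_a(T, S) − µ_b(T, S))·t,

   with nutrient-saturated limit R_∞ = (µ_max,a(T) − µ_max,b(T))·t.
   The sign of R names the winner; the closed-form crossing temperature
   1/T* = 1/T_ref + k·ln(B₀,a/B₀,b)/(E_µ,a − E_µ,b) locates
   temperature-driven *reversals* of competitive advantage.
4. **Synthetic experiments** — a generator emulates the full factorial
   design (5 temperatures × 13 phosphate levels × 3 replicates of
   monocultures; 15 pairs × 2 temperatures × 3 phosphate levels × 6
   replicates of competition trials) with known ground-truth traits,
   multiplicative log-scale density noise, optional species
   misclassification and optional nutrient drawdown.
5. **Evaluation** — observed advantages ln((N_a+1)/(N_b+1)), binary
   winners, low-density replicate dropping, bootstrap proportion tests
   against chance, reversal counting via median sign change, and
   predicted–observed correlation.

## Worked example

Two species that trade off a higher rate at cold temperature (B₀) against
a higher thermal sensitivity (E_µ) reverse their competitive ranking
between 15 and 25 °C:

```r
library(thermocompete)

a <- metabolic_traits(B0 = 0.60, E_mu = 0.30, K0 = 0.10, E_K = 0.40)
b <- metabolic_traits(B0 = 0.45, E_mu = 0.70, K0 = 0.30, E_K = 0.20)

competitive_advantage_R(a, b, celsius_to_kelvin(15), S = 1)
#> Competitive advantage (R): R = 2.79 at T = 288.15 K, S = 1 umol/L, t = 14 d -> winner: a
competitive_advantage_R(a, b, celsius_to_kelvin(25), S = 1)
#> Competitive advantage (R): R = -0.8901 at T = 298.15 K, S = 1 umol/L, t = 14 d -> winner: b

cr <- crossing_temperature(a, b)
kelvin_to_celsius(cr$T_K)
#> [1] 20.24113
predict_reversal(a, b, celsius_to_kelvin(15), celsius_to_kelvin(25), S = 1)$reversal
#> [1] TRUE
```

R = 2.79 at 15 °C means species *a* is predicted to be e^2.79 ≈ 16 times
more abundant after 14 days; by 25 °C the sign has flipped and *b* leads.
The crossing sits at 20.2 °C, inside the probed interval, so a reversal is
predicted.

Recovering traits from (synthetic) experiments end to end:

```r
panel  <- sample_species_panel(4, seed = 1)       # ground truth
curves <- simulate_monoculture_experiment(panel,
  experiment_design(c(15, 20, 25),
                    exp(seq(log(0.01), log(50), length.out = 13)),
                    3, seq(0, 30, 2)),
  noise_model(sigma_log10 = 0.05), seed = 2)
fits   <- fit_growth_rates(curves, n_starts = 20, seed = 3)
monod  <- fit_monod_curves(fits, n_starts = 50, seed = 4)
traits <- fit_metabolic_traits(monod)
traits[, c("species", "B0_per_day", "E_mu_eV", "K0_umol_L", "E_K_eV")]
#>   species B0_per_day E_mu_eV K0_umol_L E_K_eV
#> 1    sp01      0.432   0.312    0.3316  0.644
#> 2    sp02      0.486   0.693    0.0774  0.412
#> 3    sp03      0.588   0.715    0.1457  0.693
#> 4    sp04      0.749   0.577    0.1277  0.537
```

compared with the generating panel (`panel[, 2:5]`: B₀ 0.433/0.486/0.586/
0.754, E_µ 0.311/0.694/0.720/0.563, …) — estimates land within a few
percent under realistic observation noise. `run_pipeline(pipeline_config())`
chains all five stages, writes every artifact as CSV plus a run manifest,
and is bit-identical on rerun; `prediction_grid()`, `evaluation_table()`,
`count_reversals()` and `correlate_pred_obs()` score predictions against
competition counts.

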