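---
title: "Predicting pairwise phytoplankton competition from metabolic traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting pairwise phytoplankton competition from metabolic traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermocompete)
```

## The model

`thermocompete` implements a metabolic-trait framework for predicting which
of two phytoplankton species outgrows the other as a function of temperature
and nutrient (phosphate) availability. The framework rests on three nested
assumptions:

1. **Exponential co-invasion.** Two species inoculated at equal, low
   densities into fresh medium grow exponentially at constant rates,
   $N_i(t) = N_i(0)\,e^{\mu_i t}$, while nutrient drawdown is negligible.
2. **Monod nutrient limitation.** The realised growth rate saturates with
   the limiting nutrient,
   $\mu_i = \mu_{\max,i}\, S / (K_{S,i} + S)$, where $K_S$ is the
   concentration at which growth is half-maximal.
3. **Boltzmann–Arrhenius temperature dependence.** Within an operational
   temperature range (OTR; here 15–25 °C) both Monod parameters respond
   exponentially to temperature,
   $\mu_{\max,i}(T) = B_{0,i}\, e^{-E_{\mu,i}/k\,(1/T - 1/T_{\mathrm{ref}})}$
   and analogously $K_{S,i}(T) = K_{0,i}\, e^{-E_{K,i}/k\,(1/T -
   1/T_{\mathrm{ref}})}$, with $k = 8.617\times 10^{-5}$ eV K$^{-1}$.

The four quantities $(B_0, E_\mu, K_0, E_K)$ are a species' *metabolic
traits*. Under equal inocula, the competitive advantage of species $a$ over
$b$ after $t$ days is the log abundance ratio

$$R = \ln\frac{N_a(t)}{N_b(t)} = (\mu_a(T, S) - \mu_b(T, S))\,t
    = S\left(\frac{\mu_{\max,a}(T)}{K_{S,a}(T)+S} -
             \frac{\mu_{\max,b}(T)}{K_{S,b}(T)+S}\right) t ,$$

with the nutrient-saturated limit
$R_\infty = (\mu_{\max,a}(T) - \mu_{\max,b}(T))\,t$ depending only on
$(B_0, E_\mu)$. The sign of $R$ names the winner; its magnitude is the
log-scale margin. Because $R_\infty$ is a difference of two exponentials in
$1/T$, the winner can flip at the unique crossing temperature

$$\frac{1}{T^*} = \frac{1}{T_{\mathrm{ref}}} +
  \frac{k \ln(B_{0,a}/B_{0,b})}{E_{\mu,a}-E_{\mu,b}},$$

which `crossing_temperature()` returns in closed form: at
$T_{\mathrm{ref}}$ the species with the larger normalisation constant wins,
far above it the species with the larger activation energy. A *reversal*
between two temperatures means the sign of $R$ differs between them.

Temperatures are Kelvin inside the theory core and Celsius at every file
and function boundary that touches data, because the Arrhenius algebra is
Kelvin-based while measurements are recorded in Celsius.

## From density time series to traits

The estimation chain mirrors how such trait experiments are analysed:

**Growth rates.** Each monoculture density time series is fitted with the
Buchanan three-phase linear model — flat at $N_0$ through a lag of
$t_{\mathrm{lag}}$ days, linear in log density at slope $\mu$, flat again
at $N_{\max}$ from $t_{\max}$ — by bounded Levenberg–Marquardt least
squares (`minpack.lm::nls.lm`) restarted from `n_starts` random
starting-parameter combinations drawn from uniform distributions, keeping
the converged start with the lowest small-sample-corrected AIC (AICc).
Two implementation choices matter:

* *Fitting scale.* The piecewise model is fitted on natural-log densities,
  so the fitted slope **is** the specific growth rate $\mu$ (d$^{-1}$) used
  by the exponential competition theory; a `log10` mode (slope rescaled by
  $\ln 10$) is provided for cross-checks against decadic-log conventions.
* *Start quality.* The residual surface of a piecewise-linear model is
  kinked wherever a knot crosses an observation time, and gradient-based
  starts can stall there. Alongside the random starts, the optimiser is
  therefore always seeded once from the best *phase-assignment* candidate:
  every assignment of the observations to lag/exponential/stationary
  segments is solved in closed form (phase means plus an OLS line through
  the ramp) and the lowest-rss assignment becomes a deterministic start.
  With it, noiseless curves are recovered to optimizer precision with as
  few as ten random starts; the default remains `n_starts = 1000` for
  parity with heavyweight multi-start practice.

AICc, $n\ln(\mathrm{rss}/n) + 2p + 2p(p+1)/(n-p-1)$, is undefined for
$n \le p+1$; for series of six or fewer points the winner is chosen by rss
and the score reported as `NA`. Curves showing less than one decade of
growth are flagged as failed and excluded from trait fitting (threshold
configurable). When the fitted plateau lies beyond the last observation the
fitted rise is unconstrained by data, so the observed log-density range
stands in for it in that flag.

**Monod parameters.** Per species × temperature × replicate, the
$(S, \hat\mu)$ points are fitted with the same multi-start scheme
(`fit_monod()`). A $K_S$ standard error exceeding the estimate flags an
unidentifiable half-saturation constant (all concentrations saturating) —
such fits are excluded from the Arrhenius stage.

**Metabolic traits.** `fit_arrhenius()` regresses $\ln(\text{trait})$ on
the Boltzmann factor $x = 1/(kT) - 1/(kT_{\mathrm{ref}})$ within the OTR;
the slope is $-E$ and the back-transformed intercept the normalisation.
For lognormal errors this linear regression *is* the nonlinear
least-squares optimum and is numerically stabler; a `nonlinear` mode
refits on the natural scale for parity with `nls`-style workflows.
Per-replicate Monod estimates at the OTR temperatures are pooled into one
regression per species and trait by default (up to 9 points from
3 temperatures × 3 replicates); a replicate-mean mode is provided because
published analyses are often ambiguous on this point — on clean data the
two coincide. $T_{\mathrm{ref}} = 15$ °C, inside the OTR, so $B_0$ and
$K_0$ are trait values at the coldest OTR temperature.

## What the synthetic generator emulates — and what it does not

The generator reproduces the geometry of a factorial trait-and-competition
study: monocultures at 15/20/25/30/35 °C × 13 phosphate levels × 3
replicates sampled every 2 days for a month, and all pairwise competition
trials at 15/25 °C × {0.1, 1, 30} µmol L$^{-1}$ × 6 replicates censused at
days 5, 14 and 23, with 100 cells mL$^{-1}$ inocula. The 13 phosphate
levels are log-spaced over 0.01–50 µmol L$^{-1}$, concentrating resolution
near typical half-saturation constants.

Default trait ranges (uniform sampling bounds, chosen once as realistic for
small freshwater green algae): $B_0 \in [0.3, 0.8]$ d$^{-1}$,
$E_\mu \in [0.2, 0.75]$ eV (bracketing the canonical ~0.6 eV),
$K_0 \in [0.05, 0.5]$ µmol L$^{-1}$, $E_K \in [0.1, 0.9]$ eV, lags of 0–3
days, stationary plateaus of $10^{6}$–$10^{6.5}$ cells mL$^{-1}$, and
per-cell phosphorus quotas of 5–20 fmol. These bounds keep realised growth
rates at or below ≈2 d$^{-1}$ at 25 °C, which is both biologically sensible
for these taxa and what makes a 2-day census able to resolve the
exponential phase — a faster grower would leave at most one sample on the
ramp and its slope would be unidentifiable from any fitting method.

Noise enters in two places: additive Gaussian noise on log10 density
(multiplicative on density; default sd 0.05, matching how growth data
scatter on a log scale) and, in competition trials, a binomial
species-misclassification swap in which each counted cell defects to the
other species with a configurable probability — a scalar stand-in for an
imperfect cytometric discriminator (a rate of 0.22 mimics a 78%-accurate
classifier). The generator does **not** simulate cytometry channels, light
or CO$_2$ limitation, trait evolution, or the unimodal decline of
$\mu_{\max}$ above ≈25–30 °C: growth is exponential in the Boltzmann factor
at *all* temperatures, so the generator must not be used to emulate fitting
of a full unimodal thermal performance curve at 30–35 °C. Trait fitting
correspondingly restricts itself to the OTR.

Two deliberate assumption-violators are built in:

* **Stationary caps.** In competition trials each species grows
  exponentially at $\mu_i(T, S_0)$ but is capped at its own plateau. Batch
  cultures really do leave exponential phase within one to two weeks, and
  the cap reproduces that — *independently per species*, which is the
  simplest choice but means a trial in which both species are capped has
  its observed winner set by the plateau ranking rather than by growth
  rates. Consequently even a zero-noise replication does not score 100%
  at day 14: replicates still in exponential phase are predicted exactly,
  while both-capped replicates at the warm, nutrient-rich corner of the
  design are not, which is precisely the caveat attached to evaluating an
  exponential-phase theory at a late census day. The package's evaluation
  reports both the overall and the exponential-phase-only proportions so
  the two regimes can be told apart.
* **Nutrient drawdown.** An optional batch-culture simulator integrates
  $dN_i/dt = \mu_i(T, S(t))N_i$, $dS/dt = -\sum_i q_i \mu_i N_i$
  (`deSolve::ode`, tolerances $10^{-8}$) with a fixed per-cell phosphorus
  quota $q_i$ — a minimal closure with no internal stores (no Droop
  kinetics). Since quotas are µmol per cell, densities cells mL$^{-1}$ and
  $S$ µmol L$^{-1}$, the drawdown term carries a factor 1000 (mL → L).
  Mass is conserved exactly in the right-hand side, so
  $1000\,\sum_i q_i (N_i - N_i(0)) + S(t) = S_0$ to integration tolerance
  while no cap has triggered.

Passing tests on these synthetic data demonstrate that the estimation
chain inverts the generative model correctly and degrades gracefully under
the modelled noise sources; they cannot certify performance on real data,
whose departures (unimodal TPCs, interference competition, discriminator
structure, demographic stochasticity) the generator intentionally omits.

## Evaluation decisions

* **Observed advantage.** $R_{\mathrm{obs}} = \ln((N_a + 1)/(N_b + 1))$;
  the +1 keeps locally extinct species finite and makes double extinction
  a tie. Exact ties are indeterminate and excluded from scoring rather
  than randomly assigned, so headline counts never depend on a seed.
* **Low-density drops.** Replicates with total density below 500 cells
  mL$^{-1}$ (five times the inoculum — near-stasis carries no usable
  signal) are dropped and logged; conditions losing all replicates are
  reported untestable. The threshold is configurable; whether the cutoff
  should apply per species or to the total is a judgement call — the total
  is used here.
* **Bootstrap p-values.** The proportion of correctly predicted replicates
  is tested against chance by resampling the replicate-level 0/1
  indicators with replacement ($B = 10{,}000$ by default), one-sided
  against $H_0{:}\ p \le 0.5$, with the add-one $(B+1)$ convention. For
  exchangeable 0/1 indicators the resampled proportion is exactly
  $\mathrm{Binomial}(n, \hat p)/n$, so the resample is drawn directly from
  that distribution — identical in law to index resampling at a fraction
  of the cost. The suite checks the test's size empirically under
  coin-flip outcomes.
* **Reversal counting.** A pair × nutrient cell shows an observed reversal
  when the median $R_{\mathrm{obs}}$ across replicates changes sign
  between the two temperatures (a median of exactly zero is
  indeterminate); the model's prediction uses the sign of predicted $R$
  at the same two temperatures. Summaries report, per nutrient level and
  overall, how many observed reversals the model also predicted.
* **Evaluation day.** Day 14 by default, with days 5 and 23 available for
  robustness; `day_persistence()` quantifies how strongly the
  replicate-level advantage at one census day carries to another (Pearson
  $r$ with a Fisher-z interval).

## Numerical choices

Ties in predicted advantage are declared at $|R| < 10^{-12}$ (a
floating-point guard; genuine ties only arise from identical traits).
Random starting values for knots are drawn over the observed time window,
growth rates over 0–3 d$^{-1}$, and log densities over the observed range
widened by one unit. Parameter transformations
($t_{\max} = t_{\mathrm{lag}} + \Delta t$,
$N_{\max} = N_0 + \Delta N$ with $\Delta t, \Delta N, \mu \ge 0$) keep
every evaluated parameter set inside the model's validity region. Flat
series short-circuit to the exact $\mu = 0$ solution. All simulation and
fitting functions accept seeds; a pipeline-level seed is expanded into
per-stage substreams so stages can be rerun independently and reruns are
bit-identical.

The test suite scales its Monte-Carlo studies to sizes chosen to give
stable medians at reasonable cost: 200 simulated species for the noisy
recovery study (three OTR temperatures × 13 phosphate levels × 3
replicates each, about 23,000 curve fits with a reduced multi-start of 5
random draws plus the phase-assignment start), 200 curves for growth-rate
recovery, 500 replicates for activation-energy unbiasedness, 1000
datasets of 361 replicates for bootstrap calibration, and 50 paired seeds
for the misclassification sweep.

## Known limitations

* The Arrhenius stage assumes $K_S$ follows the same exponential form as
  $\mu_{\max}$; within a 10 °C OTR this is an assumption of convenience,
  not a law.
* The competition theory needs constant $S$ and exponential growth over
  the horizon; both are violated late in batch culture, and the package
  quantifies rather than removes that violation (persistence
  correlations, exponential-phase subsetting, the drawdown simulator).
* Each species caps independently; a joint carrying capacity or
  resource-based stationary phase in the exponential simulator is out of
  scope (the drawdown simulator covers the shared-resource case).
* No multispecies (>2) dynamics, resident–invader analysis or $R^*$
  coexistence criteria: the framework addresses pairwise co-invasion from
  rarity only.
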