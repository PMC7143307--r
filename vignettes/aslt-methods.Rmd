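---
title: "Accelerated shelf-life modelling of olive oil quality indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Accelerated shelf-life modelling of olive oil quality indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oliveASLT)
```

## The problem

Extra-virgin olive oil (EVOO) loses its regulatory category when oxidation
indices cross legal thresholds, but a real-time storage trial at ambient
temperature takes a year or more. Accelerated shelf-life testing (ASLT)
stores the product at elevated temperatures, measures how fast quality
indices degrade, models the temperature dependence of those rates, and
extrapolates back to market conditions. oliveASLT implements that pipeline
end to end for zero-order (linear-in-time) quality indices:

1. **Zero-order kinetics.** For each index and storage temperature,
   `fit_zero_order()` estimates the apparent rate constant $k$ as the OLS
   slope of value on time, $I(t) = I_0 + k\,t$.
2. **Arrhenius temperature dependence.** `fit_arrhenius_twostep()` fits the
   reparametrized Arrhenius model
   $$\ln k = \ln k_{ref} - \frac{E_a}{R}\left(\frac{1}{T} -
   \frac{1}{T_{ref}}\right),$$
   with $T_{ref}$ chosen mid-range to decorrelate $\ln k_{ref}$ and the
   apparent activation energy $E_a$. The frequency factor is
   $k_0 = \exp(\ln k_{ref} + E_a/(R\,T_{ref}))$.
3. **Shelf-life.** `predict_shelf_life()` converts a fitted model and an
   acceptability limit into $SL = (I_{lim} - I_0)/k_T$, and
   `fit_shelf_life_plot()` regresses $\ln SL$ on temperature for
   extrapolation beyond the tested range.

## Parameters that matter

* `gas_constant` (default 8.31 J/(K mol)): the convention used in the
  reference rate tables this package ships; configurable to 8.314. It
  affects the reported $E_a$ and $k_0$ only — shelf-life predictions
  evaluate the fitted line directly and are invariant to it.
* `T_ref` (default 318.15 K): 45 °C, the midpoint of the 25–60 °C
  accelerated design. Refitting with another `T_ref` changes $k_{ref}$ but
  leaves $E_a$, $k_0$ and every prediction unchanged (a tested invariance),
  so the exact midpoint convention is immaterial.
* `min_points` (default 4): smallest segment the zero-order fit accepts;
  three points define a line but leave no residual diagnostics, four is the
  minimum that does.
* `alpha` (default 0.05): significance level for calling an index
  responsive (slope > 0 with $p < \alpha$ at the highest tested
  temperature).

Celsius-to-Kelvin conversion is +273.15 everywhere. Reported whole-day
shelf-lives use `floor()`: a product is not credited with a day it does not
complete, and floor is the only rounding consistent with the reference
shelf-life table the acceptance checks reproduce (e.g. 377.8 → 377,
32.08 → 32).

## Two routes to the Arrhenius parameters

The default **two-step** route first condenses each temperature into a
fitted rate, then regresses $\ln k$ on $(1/T - 1/T_{ref})$. It is exactly
reproducible by closed form, robust, and is what the packaged EVOO rate
tables support. The **one-step** route (`fit_arrhenius_onestep()`) fits all
retained observations jointly with shared $(E_a, k_{ref})$ and
per-temperature intercepts, which propagates within-series uncertainty
properly; it uses `nls(algorithm = "port")` initialized from the two-step
solution, so on noise-free data both routes coincide with the generating
parameters. The two-step log-linear route is the default because its
estimates are closed-form, unit-transparent, and reproduce the reference
activation energies within 1%; the one-step route is under-determined by
published rate tables (it needs raw trajectories).

## Segment truncation

Indices that saturate (pyropheophytin a reaches a plateau at high
temperature) must be fitted only on their rising part.
`select_increasing_segment()` searches all time-ordered prefixes of at
least `min_points` observations exhaustively and keeps the positive-slope
prefix with the highest $R^2$, ties broken toward the longest prefix. A
prefix shorter than the full series is eligible only when the excluded tail
*departs downward* from the extrapolated prefix line by more than
prediction noise (mean standardized tail deviation below −2, with the
full-series RMSE as the noise scale). Without that eligibility guard, pure
$R^2$ maximization truncates genuinely linear noisy series about a third of
the time — a short prefix that is near-collinear by chance beats the full
series — biasing the slope; with it, spurious truncation drops below 10%
while plateaued trajectories are still cut within one observation of the
last rising point (a tested property against an exhaustive brute-force
oracle). The residual possibility of chance truncation on noisy linear data
is a known limitation; fits report `n_used` and `truncated_at` so it is
always visible.

Lag phases are only *flagged*, never corrected: the flag fires when the
earliest observation sits more than two RMS residuals below the fitted line
and dropping it improves $R^2$. In the reference storage study no lag was
observed, so the flag is advisory and the rate is always reported from the
selected segment unchanged.

## The synthetic study generator

`default_study_config()` emulates a sealed-bottle EVOO storage trial: four
temperatures (25/40/50/60 °C), 15 sampling days over 0–300 days, two
analytical replicates per day. Responsive indices (K270, conjugated
trienes, hexanal, %PPP) follow zero-order growth with reference activation
energies (58.39, 75.46, 54.78, 102.94 kJ/mol) and reference rates derived
at run time from the packaged rate table; %PPP is capped at a 26% plateau.
Non-responsive indices (PV, K232, phenols, tocopherols) stay flat at a
reference fresh-oil composition. Noise is additive homoscedastic Gaussian
per observation (multiplicative noise and zero-clipping are available by
flag), with standard deviations chosen at realistic analytical
repeatability: 0.005 absorbance for K270, 0.01 mg/kg for CT, 0.08 mg/kg for
hexanal, 0.3 percentage points for %PPP, and 1–3% relative for the flat
indices.

Design choices stated once:

* **Sampling schedule.** Published storage designs give bottle counts, not
  dates. The default schedule (0, 2, 5, …, 300 days) is densified early, as
  is standard ASLT practice, because the fastest kinetics at 60 °C —
  notably %PPP, which reaches its plateau within about ten days — are
  unobservable on an even 21-day grid; an even grid can be supplied via
  `sampling_days` if wanted.
* **Initial values.** K270 (0.15), PV (5.7), K232 (1.81), phenols (332.9)
  and tocopherols (225.6) are a reference fresh-EVOO composition. The
  initial values of %PPP (1.0%), CT (0.05 mg/kg) and hexanal (0.20 mg/kg)
  are not published for the reference study and are stated assumptions of
  the generator (fresh EVOO carries only traces of pyropheophytin a and
  secondary oxidation products).
* **Plateau.** Implemented as a hard ceiling applied before noise; the
  plateau level (26%) is a stated assumption, as the reference study shows
  but does not parameterize it.

What passing synthetic tests shows — and what it does not: the generator
draws exactly the model the estimators assume (linear growth, additive
Gaussian noise, hard plateau). Recovery of generating parameters therefore
validates the estimation machinery, not the adequacy of zero-order
kinetics, homoscedastic noise, or plateau shape for any real oil. Real
trajectories can show autocorrelated replicate error, mild curvature, and
oxygen-limitation effects the generator deliberately omits.

## Numerical choices

* OLS fits go through `stats::lm`; slope/intercept equality with the
  closed-form normal-equation solution is tested to machine precision.
  $R^2$ is clamped to $[0, 1]$ and defined as 0 for a constant response.
* Slope p-values use the $t$ distribution with $n_{used} - 2$ degrees of
  freedom; a perfect fit with non-zero slope reports $p = 0$, a constant
  series $p = 1$.
* The one-step optimizer runs `nls` "port" with tolerance $10^{-10}$ and up
  to 1000 iterations, initialized from the two-step fit; non-convergence is
  an error carrying the index name, never a silent fallback.
* Parameter covariance is the standard OLS/Gauss–Newton estimate,
  transformed to $(\ln k_{ref}, E_a)$; shelf-life confidence intervals use
  the delta method on $\ln SL$ (default) or a seeded parametric bootstrap.
* Shelf-life plots regress $\ln SL$ on temperature in °C by default
  (matching the conventional shelf-life-plot axis); an
  Arrhenius-consistent $1/T$ abscissa is available via `x_axis`.
* Two-temperature Arrhenius fits are exact interpolations; their parameter
  covariance is reported as zero (no residual degrees of freedom).

## Problem sizes used in the validation suite

The packaged validation studies are sized for desk-scale reproducibility:
end-to-end activation-energy recovery runs the full eight-index study over
200 seeds (median estimate within 5% of each generating $E_a$); the
one-step route is checked over 60 replications; null false-positive rates
over 500 simulated flat series; noise-convergence over $10^4$ draws.

## Known limitations

* Zero-order kinetics only: first-order or mechanistic
  hydroperoxide-balance models are out of scope.
* The responsiveness call is a single hypothesis test at the highest
  temperature; at $\alpha = 0.05$, one flat index in twenty will be
  misflagged (the pipeline tolerates this, skipping indices whose rates
  cannot support an Arrhenius fit, and the label never blocks fitting).
* Activation energies are descriptive of temperature sensitivity, not
  mechanistic: oxidation is a composite radical-chain process.
* Extrapolation below the calibrated 25–60 °C span (e.g. shelf-life at
  20 °C) inherits the usual risks of Arrhenius extrapolation; the pipeline
  warns when prediction temperatures leave the calibrated range.
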