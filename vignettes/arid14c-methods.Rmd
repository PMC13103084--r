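---
title: "Radiocarbon models of dryland soil carbon: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiocarbon models of dryland soil carbon: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arid14c)
```

## The scientific problem

Drylands store a large share of global soil organic carbon (SOC), and how
long that carbon persists — and how quickly it transits back to the
atmosphere as respired CO2 — is poorly constrained. Radiocarbon provides the
constraint: radioactive decay (half-life 5730 y) dates carbon fixed
centuries to millennia ago, while the 1950s--60s "bomb spike" of atmospheric
14C traces carbon cycling on annual-to-decadal timescales. `arid14c`
implements the full analysis chain for paired measurements of bulk-SOC
Delta14C and incubation-respired CO2 Delta14C across a site network:
isotope corrections, carbonate screening, endmember mixing, steady-state
pool models, and threshold regression along environmental gradients.

Throughout, Delta14C is the per-mil deviation of a sample's 14C/12C ratio
from the 1950 absolute standard, decay-corrected between 1950 and the
measurement: 0 permil is the preindustrial atmosphere, positive values
carry bomb-derived carbon, and -1000 permil is radiocarbon-dead.

## Isotope conversions and corrections

AMS measurements arrive as Fraction Modern F14C. The sample Delta14C is

$$\Delta^{14}\mathrm{C}_{sample} = \left(F^{14}\mathrm{C}\,
  e^{\lambda_C (1950 - t)} - 1\right) \times 1000,$$

with the decay constant $\lambda_C = 1/8267\ \mathrm{yr}^{-1}$ and $t$ the
sampling year (`f14c_to_delta14c()`). Sampling dates span mid-2015 to
mid-2020, so $t$ may be fractional; the formula is continuous in $t$.
Because sites were sampled in different years, all values are background
corrected by subtracting the atmospheric Delta14C of the sampling year
(`background_correct()`), putting every site on a common reference.

The delta13C of soil inorganic carbon (SIC) is recovered from the
total-carbon mass balance
$\delta^{13}C_{TC} w_{TC} = \delta^{13}C_{SOC} w_{SOC} +
\delta^{13}C_{SIC} w_{SIC}$ (`delta13c_sic()`). Total C (dry combustion)
and SIC (ignition residue) come from different instruments, so the closure
$w_{TC} \approx w_{SOC} + w_{SIC}$ is only checked to a tolerance: a
relative imbalance above 10% warns and above 25% errors. Respiration rates
convert headspace CO2 accumulation to mass-specific production with the
ideal gas law (`respiration_rate()`), defaulting to the static-incubation
geometry (0.54 L headspace, 30 g soil, 20 degC, 1 atm).

## The atmospheric forcing curve

All pool models are forced by an annual atmospheric Delta14C record. The
packaged parametric curve (`synthetic_bomb_curve()`) has four regimes:

* flat pre-bomb baseline (default 0 permil) before 1955 — the small Suess
  depression of the early 20th century is ignored, a bias that is
  negligible against the standard errors of millennial ages;
* linear monotone rise from 1955 to the 1964 peak (default +700 permil);
* exponential post-peak relaxation with a 16-year e-folding time;
* the relaxation asymptote is shifted so the curve passes exactly through
  the configured end level (default 0 permil) at the reference year 2020.

The anchoring choice matters. A relaxation decaying to a 0-permil
*asymptote* would still sit at +24 permil in 2018, whereas the observed
atmosphere was within a few permil of zero by then (fossil-fuel CO2
dilution pulls it below the pre-bomb level). Anchoring the curve through
0 permil at 2020 reproduces the observed record to roughly 10 permil over
1975--2020 (e.g. 244 vs ~250 permil in 1980, +2.9 vs ~0 permil in 2018)
and keeps the young mixing endmember realistic. A published compilation
can replace the parametric curve at any point via `load_curve()` (CSV with
header `year,delta14c_permil`); no hemisphere/zone distinction is built in,
because the zone assignment is a per-site judgment the user can express
through `load_curve()`. Evaluation interpolates linearly between annual
nodes, returns the first value before the first node, and refuses to
extrapolate beyond the last node.

## One-pool steady-state model

A homogeneous pool with decay rate $k$ at steady state obeys

$$\frac{dF}{dt} = k\,(F_{atm}(t) - F) - \lambda_C F,$$

where $F$ is the pool's absolute fraction-modern ratio and
$F_{atm} = \Delta^{14}C_{atm}/1000 + 1$. The model starts in 1900 at the
pre-bomb steady state $F_0 = k/(k + \lambda_C)\,F_{atm}(1900)$ — exact
under the constant pre-1900 forcing, so no spin-up is needed — and runs to
the sampling date. Each model year is advanced with the exact exponential
solution holding the forcing at its year-midpoint value. This integrator
is unconditionally stable across the whole fitted rate range
($10^{-5}$--$10\ \mathrm{yr}^{-1}$), reproduces the flat-atmosphere steady
state to machine precision, and is shared verbatim by the two-pool code so
degenerate reductions are bit-identical. Mass balance uses $k$ alone
(steady stocks are input/$k$); $\lambda_C$ appears only in the isotopic
bookkeeping.

`fit_one_pool()` inverts the model by scanning $k$ over a log grid (2000
points by default), locating every sign change of (model - observed), and
refining each root by bisection to 0.1 permil — comfortably below AMS
measurement precision. Bomb-influenced observations (above the sampling-year
atmosphere but below the model's maximum over $k$) admit two rates; the
smaller rate (longer transit time) is selected and both roots are kept in
the fit object. Under the packaged curve the model maximum at 2018 is about
+94 permil, so larger observations are reported as outside the model range
rather than silently clamped. For a single well-mixed steady-state pool the
mean age, mean transit time and turnover time coincide at $1/k$, which is
why one fit to bulk SOC and one to respired CO2 approximate the slow and
fast dynamics separately.

Worked anchors (also recomputed by `scripts/acceptance.R`): fitting the
cohort-mean bulk value of -190.0 permil at 2018 gives an age of about
1900 y, and the cohort-mean respired value of -39.2 permil gives a transit
time of about 470 y. Both sit inside the 10% band around the survey's
published 2100 +/- 140 and 520 +/- 30 y; the remaining gap is the
curve approximation plus Jensen's inequality — the age of the mean
Delta14C is smaller than the mean of per-site ages because age is convex
in Delta14C.

## Two-pool models

Because respired CO2 is consistently younger than bulk SOC, the package
also fits two-pool structures (`simulate_two_pool()`, `fit_two_pool()`):

* **parallel** — independent pools receive input fractions $\gamma$ and
  $1-\gamma$; bulk Delta14C is stock-weighted, respired flux-weighted;
* **series** — all input enters the fast pool, a fraction $a_{21}$ of its
  outflux transfers to the slow pool; respired CO2 is
  $(1-a_{21})\,k_f C_f + k_s C_s$.

Two observations (bulk, respired) cannot identify three parameters, so the
fast rate is profiled over a fixed grid (default 25 log-spaced values in
0.02--2 yr^-1) and $(k_{slow}, \gamma\ \mathrm{or}\ a_{21})$ are optimized
at each grid point (Nelder--Mead on bounded transforms, multiple starts).
Every profile member reproducing both observations within 1 permil forms
the reported solution family; the point estimate is the member with the
shortest mean transit time, and the full profile stays in the fit object
for audit. This makes the under-determination explicit instead of
returning one arbitrary member. Fitted to the cohort means (-190.0, -39.2
permil), every family member keeps more than 90% of the carbon stock in
the slow pool.

Transit and age moments (`ages_and_transit()`): parallel transit
$\gamma/k_f + (1-\gamma)/k_s$, pool ages $1/k_i$; series transit
$1/k_f + a_{21}/k_s$, slow-pool age $1/k_f + 1/k_s$; system age is always
the stock-weighted mean pool age. The series system age is verified in the
test suite against a stochastic particle oracle that samples stationary
atom ages directly.

## Carbonate (SIC) screening of respired CO2

Rewetting carbonate soils releases CO2 from carbonate dissolution, which
is 14C-depleted and would bias respiration ages old. CO2 in isotopic
equilibrium with calcite at the 20 degC incubation temperature is offset
by -9.6 permil (`sic_equilibrium_d13c()`); the carbonate share of respired
CO2 then follows from a two-endmember delta13C mass balance
(`f_sic_from_d13c()`), requiring at least 2 permil separation between the
SOC and carbonate-equilibrium endmembers to be identifiable. Shares
outside [0, 1] are clamped to the boundary and flagged rather than
rejected, since measurement noise routinely produces slightly out-of-simplex
estimates. The implied SOC-derived Delta14C is recovered by inverting the
14C mixing (`adjust_delta14c_for_sic()`); when a site has no measured
carbonate Delta14C the endmember defaults to -1000 permil
(parent-material carbonate), configurable because pedogenic carbonate can
be substantially younger.

Screening (`screen_site()`) applies, in order: SIC content below 0.1
mass-% means all respired CO2 is attributed to SOC; an estimated carbonate
share above 15% excludes the site from respiration analyses; membership in
a configured excluded region (a dataset-specific representativeness
judgment, not an algorithm — hence a config list) excludes it; otherwise
the site is retained and downstream analysis uses its **original**
respired Delta14C, because sub-15% adjustments are minor relative to their
uncertainty. The high-share rule takes precedence over the region rule so
that region-level removals refer to the sites remaining after screening.

## Old-carbon share of respiration

The fraction of respired CO2 drawn from old carbon comes from two-endmember
Delta14C mixing (`f_old()`):
$f_{old} = (\Delta^{14}C_{young} - \Delta^{14}C_{CO_2}) /
(\Delta^{14}C_{young} - \Delta^{14}C_{old})$, with the young endmember
taken from the forcing curve at the sampling year (a config flag fixes it
at 0 permil for sensitivity runs; recently fixed plant carbon is likely
somewhat above the sampling-year atmosphere, an acknowledged bias that is
not modelled). Three old endmembers are evaluated per site
(`f_old_suite()`): the bulk-SOC signature (high-end estimate),
radiocarbon-dead petrogenic carbon at -1000 permil (low-end), and — where
particulate/mineral-associated fractions are available — the
mineral-associated (MAOC) signature inferred from
$\Delta^{14}C_{MAOC} = \Delta^{14}C_{bulk}/w_{MAOC}$ under the
modern-POC assumption (`maoc_delta14c()`; results below -1000 permil are
flagged infeasible and the MAOC case is dropped for that site). Because it
is genuinely ambiguous whether published cohort fractions average
site-level ratios or mix cohort means, `run_pipeline()` reports both
summaries (`f_old_site_mean` and `f_old_of_means`).

## Threshold (breakpoint) regression

Abrupt shifts of Delta14C along aridity/NPP/SOC gradients are detected
with the continuous broken-line model
$y = \beta_0 + \beta_1 x + \beta_2 (x - \psi)_+$ (`fit_breakpoint()`).
Rather than iterative linearization, $\psi$ is profiled over all midpoints
between sorted unique predictor values (excluding a 5%-of-range edge
margin, and requiring 5 points per side), with ordinary least squares at
each candidate: deterministic, and globally optimal on the grid. Model
support is judged by Gaussian-likelihood AIC, $n\ln(RSS/n) + 2p$ with
$p = 4$ mean-function parameters (intercept, slope, slope change,
breakpoint) against $p = 2$ for the simple line; ties go to the simpler
model. The $\psi$ confidence interval is a seeded nonparametric pairs
bootstrap (499 resamples by default).

A precision note: with a breakpoint near the edge of the predictor range,
few points constrain the second segment. In the survey-like design
(n = 97, aridity 0.46--0.99, breakpoint at 0.87, slope change -300, 25
permil response noise) the median absolute error of $\hat\psi$ is about
0.04 — for this package's grid profiler and for an independent
continuous-$\psi$ optimizer alike — dropping below 0.02 once the noise
falls to 15 permil. Threshold *locations* from such designs should be
read with that precision in mind even when the AIC firmly supports a
breakpoint.

## The synthetic site generator

`generate_sites()` produces site tables with the statistical structure the
analysis assumes, so every stage is testable end to end without field
data: aridity uniform on 0.46--0.99 with correlated climate, vegetation
and soil covariates in field-realistic ranges; a true one-pool age per
site for bulk and respired carbon; forward simulation through the same
pool model and bomb curve used in fitting; carbonate contamination
composed through the forward delta13C and Delta14C mixing; Gaussian
measurement noise (3 permil on Delta14C, 0.3 permil on delta13C, typical
AMS/IRMS precision); and a hidden-truth sidecar for parameter recovery.

Design choices: bulk log-ages follow
$\ln(age) = 6.1 + 1.75\,aridity + 6\,(aridity - 0.87)_+ + \epsilon$,
$\epsilon \sim N(0, 0.35)$, clamped to 30--5800 y — ages are generated on
a log scale because observed site ages span two orders of magnitude, the
embedded breakpoint lets threshold recovery be tested against a known
truth, and the coefficients were calibrated once so the cohort reproduces
the survey's headline statistics (mean bulk Delta14C about -190 permil
spanning roughly -420 to -50, mean included respired about -40 permil);
respired ages are a lognormal multiple (ratio 0.17, log-sd 0.4) of the
bulk age. SIC content is zero-inflated (46% of sites below the 0.1%
floor) so every screening branch is exercised, and carbonate shares are
Beta(1, 7) so a realistic minority of sites crosses the 15% exclusion.
POC/MAOC fractions are emitted for a 41/97 subset to exercise
optional-field handling.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: spatial or regional autocorrelation (regions are
random labels), depth structure, seasonality, non-steady-state stocks,
correlated measurement errors, C4-plant delta13C divergence between SOC
and SOC-derived CO2, and pedogenic-vs-parent carbonate mixtures. Recovery
results on synthetic cohorts demonstrate the estimators are consistent
under the model's own assumptions, not that the assumptions hold in the
field.

## Numerical choices and degenerate inputs

* One-pool root refinement to 0.1 permil; two-pool family tolerance 1
  permil (both below measurement precision).
* Dual one-pool roots: smaller $k$ selected, all roots retained.
* Mixing fractions and carbonate shares outside [0, 1]: clamp and flag.
* Equal mixing endmembers, sub-floor delta13C separation, $f_{SIC} = 1$,
  $w_{SIC} = 0$, observations outside the model range: explicit errors
  with domain language, never silent NA.
* AIC tie ($\Delta AIC = 0$): the linear model wins.
* Breakpoint candidates need 5 points per side; otherwise an error.

## Problem sizes in the test suite

The suite runs the full property set at deliberately modest sizes: 50
synthetic sites for one-pool recovery (2 permil noise, median relative
age error < 5%), 200 replicates for breakpoint precision, 100 replicates
by 199 bootstrap resamples for breakpoint CI coverage, and 97-site
cohorts elsewhere. These sizes give stable Monte-Carlo medians while
keeping the default check fast; all are ordinary function arguments, so
larger experiments are one call away.

## Limitations

* The one-pool "age" is a steady-state homogeneous-pool summary; real SOC
  is a continuum of ages, so bulk and respired fits bracket rather than
  resolve the distribution.
* Two-pool fits to two observations are a one-parameter family by
  construction; conclusions should be drawn from the family, not the
  point estimate.
* The parametric bomb curve is a global annualized approximation;
  hemisphere-resolved compilations should be supplied via `load_curve()`
  for per-site work.
* Threshold locations near the predictor-range edge carry ~0.04 median
  error at survey-like noise (see above).
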