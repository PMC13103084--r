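# arid14c

Radiocarbon constraints on the persistence and turnover of soil organic
carbon (SOC) in drylands.

Dryland soils store vast amounts of carbon, but how long it persists — and
how old the carbon leaving the soil as respired CO2 is — is hard to pin
down. Radiocarbon answers both questions at once: radioactive decay
(half-life 5730 y) dates carbon fixed centuries to millennia ago, while the
1950s–60s "bomb spike" in atmospheric 14C traces decadal cycling. `arid14c`
is for researchers analysing paired Δ14C measurements of bulk SOC and
incubation-respired CO2 across site networks: it turns raw isotope
measurements into mean ages, transit times, old-carbon fractions, and
ecological thresholds, with a synthetic-data generator for end-to-end
validation.

## What it computes

* **Isotope corrections** — Fraction Modern to Δ14C with
  Δ14C = (F14C·e^(λ(1950−t)) − 1)·1000, λ = 1/8267 yr⁻¹, and background
  correction against the atmosphere of the sampling year.
* **Atmospheric forcing** — a parametric bomb curve (baseline 0‰, rise from
  1955 to a +700‰ peak in 1964, 16-y e-folding decline anchored at 0‰ in
  2020), or any user-supplied annual record.
* **Carbonate screening** — δ13C two-endmember mass balance for the soil
  inorganic carbon (SIC) share of respired CO2 (calcite–CO2 fractionation
  9.6‰ at 20 °C), Δ14C de-mixing, and the 0.1 % SIC floor / 15 % f_SIC
  exclusion rules.
* **Old-carbon mixing** — f_old = (Δ14C_young − Δ14C_CO2)/(Δ14C_young −
  Δ14C_old) under bulk-SOC, petrogenic (−1000‰) and MAOC old endmembers.
* **Pool models** — one-pool steady state dF/dt = k(F_atm(t) − F) − λF run
  from 1900 under the bomb curve and inverted for k (mean age = transit
  time = 1/k; dual bomb-region solutions resolved to the longer transit),
  plus two-pool parallel/series fits with an explicit solution family.
* **Thresholds** — continuous broken-line regression
  y = β0 + β1x + β2(x − ψ)+ with profiled ψ, AIC comparison against a
  simple line, and a seeded bootstrap CI for ψ.
* **Synthetic cohorts** — `generate_sites()` emulates a 97-site dryland
  survey (aridity 0.46–0.99, carbonate prevalence, POC/MAOC subset) with
  hidden ground truth for parameter-recovery tests.

## Worked example

```r
library(arid14c)

curve <- synthetic_bomb_curve()

# mean age of bulk SOC from its cohort-mean Delta14C
fit <- fit_one_pool(-190.0, curve, 2018)
print(fit)
#> One-pool steady-state radiocarbon fit
#>   observed -190.0 permil (year 2018.0) -> k = 0.000526 yr^-1, age = transit = 1903 y

# share of respired CO2 drawn from carbon with the bulk-SOC signature
f <- f_old(-39.2, -190.0, atm_delta14c(curve, 2018), "bulk_soc")
cat(sprintf("f_old (bulk-SOC endmember): %.1f%%\n", 100 * f$f_old))
#> f_old (bulk-SOC endmember): 21.8%

# full pipeline on a synthetic 97-site cohort
sites <- generate_sites(scenario_config(seed = 4))
res <- run_pipeline(sites)
print(res)
#> Dryland radiocarbon pipeline result
#>   97 sites; 77 included in respiration analyses
#>   bulk Delta14C      -204.1 +/- 9.9 permil
#>   respired Delta14C   -42.7 +/- 6.6 permil
#>   difference (respired - bulk)   159.2 +/- 9.4 permil
#>   one-pool mean age (bulk)      2248 +/- 142 y
#>   one-pool transit (respired)    569 +/- 45 y
#>   f_old (site means): bulk-SOC 25.2%, petrogenic 5.3%, MAOC 15.2%
#>   two-pool (parallel): transit 373 y, slow pool 100% of stock
#>   bulk Delta14C aridity threshold: psi = 0.888 (piecewise)
```

Reading the output: bulk SOC across the cohort is strongly
radiocarbon-depleted (mean −204‰), i.e. millennia old (one-pool mean age
≈ 2200 y), while respired CO2 is far less depleted (−43‰, transit ≈ 570 y)
— old carbon decomposes, but respiration is weighted toward younger
substrates. A quarter of respired carbon carries the bulk-SOC signature
(5% if the old endmember is radiocarbon-dead rock carbon, 15% under the
mineral-associated endmember), and bulk Δ14C drops abruptly beyond an
aridity threshold of ≈ 0.89. Twenty of 97 sites were screened out of
respiration analyses for carbonate interference.

The per-site table (`res$per_site`) carries each site's corrected values,
carbonate partition and status, mixing fractions, and fitted ages. A thin
CLI wraps the same functions:

```sh
Rscript inst/cli/arid14c simulate --seed 4 --out sites.csv
Rscript inst/cli/arid14c run --sites sites.csv --out outdir/
Rscript inst/cli/arid14c fit-pool --delta14c -190 --year 2018
```

## Package layout

| Area | Functions |
| --- | --- |
| Forcing | `synthetic_bomb_curve`, `load_curve`, `atm_delta14c` |
| Corrections | `f14c_to_delta14c`, `background_correct`, `delta13c_sic`, `respiration_rate` |
| Carbonate | `sic_equilibrium_d13c`, `f_sic_from_d13c`, `adjust_delta14c_for_sic`, `screen_site`, `sic_partition` |
| Mixing | `f_old`, `maoc_delta14c`, `f_old_suite` |
| Pool models | `simulate_one_pool`, `fit_one_pool`, `simulate_two_pool`, `fit_two_pool`, `ages_and_transit` |
| Thresholds | `fit_breakpoint`, `compare_aic` |
| Synthetic data | `scenario_config`, `generate_sites`, `incubation_gate`, `write_sites` |
| Pipeline | `run_pipeline`, `read_sites`, `validate_sites`, `difference_bulk_respired`, `arid14c_config` |

The methods vignette (`vignettes/arid14c-methods.Rmd`) documents the
models, their assumptions, numerical choices, and the design decisions
behind the defaults.
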