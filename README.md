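# baikalsi

Silicon cycling, wind-driven deep ventilation and diatom community change in
Lake Baikal — an R package for reconstructing photic-zone nutrient dynamics
from sediment-core proxies and surface winds.

## The scientific problem

Primary productivity in Lake Baikal, the world's oldest and deepest lake, is
regulated by the rate at which nutrient-rich deep water is returned to the
photic zone. Diatoms — the dominant primary producers — record this in the
silicon isotope composition of their opal frustules (δ³⁰Si_diatom):
fractionation during biomineralization (enrichment factor ε < 0) means that
the more completely the supplied silicic acid pool is consumed, the closer
the diatom composition sits to the source water. The package implements the
open-system mass balance

    δ³⁰Si_diatom = δ³⁰Si_lake + ε · f

with δ³⁰Si_lake = 1.71 ‰ and ε = −1.61 ‰, where *f* is the fraction of
supplied Si(OH)₄ remaining unused; relative **utilization** is
100 · (1 − *f*) %. Combining utilization with biogenic silica mass
accumulation rates (BSi MAR = BSi% · dry bulk density · accumulation rate) as
a productivity measure gives the relative **supply** of silicic acid to the
photic zone, normalized to 100 % at a 2005 CE reference sample:

    Supply = 100 · (MAR / MAR_ref) / (U / U_ref)

Deep ventilation itself is wind-driven: persistent northeasterly winds
aligned with the lake axis push surface water coastward through Ekman
transport (M = τ / (f ρ), τ = ρ_a C_D W²), triggering thermobaric coastal
downwelling during the weakly stratified May–June and December–January
windows. The package detects persistent NE wind events (interruptions
shorter than one day do not break an event), accumulates their transport,
and expresses yearly seasonal means as anomalies against a 1990–2000
baseline.

Statistical layers shared by all series: Monte Carlo uncertainty propagation
(normal measurement errors, 10,000 replicates by default), penalized-spline
trends with a continuous-time AR(1) residual process and 95 % *simultaneous*
confidence bands on the first derivative (intervals where the band excludes
zero flag significant change), single-breakpoint piecewise regression with a
bootstrap-calibrated F test, Shapiro–Wilk-gated Welch-t / Wilcoxon period
comparisons, and community ordination (square-root transform, covariance
PCA, partial redundancy analysis with time as covariable, autumn/spring
taxon ratios).

A synthetic-data module generates isotope/BSi cores, wind series and
community matrices by inverting these same equations, so every stage can be
validated against known truth without any external data.

## Worked example

```r
library(baikalsi)

core   <- make_core(core_config(), seed = 11)       # synthetic 2,000-y core
paired <- align_series(core$isotopes, core$bsi)
res    <- propagate_uncertainty(paired, n_reps = 10000, seed = 11)
head(res[, c("age_ce", "utilization_pct", "supply_pct", "supply_mc_sigma")])
#>      age_ce utilization_pct supply_pct supply_mc_sigma
#> 1   0.00000        70.48095   66.03679        4.795212
#> 2  52.52224        73.00768   64.32399        4.581591
#> 3 104.86156        68.09589   70.58201        5.206687
#> 4 157.01427        68.87011   65.51625        4.829991
#> 5 208.97651        77.70934   62.21411        4.284506
#> 6 260.74425        70.77963   66.47199        4.844314

fit <- derivative_band(fit_trend_car1(res$age_ce, res$supply_pct), seed = 11)
print(fit)
#> Penalized-spline trend with CAR(1) residuals
#>   n = 45, span 0.0-2005.0, edf = 13.17, phi(1y) = 0.200
#>   significant change: [1793, 2005]
```

True utilization lies in the 70–90 % band (per-sample estimates scatter
around it with ~3.4 points of isotope noise); supply before ~1850 is about 65 % of
the 2005 reference value (i.e. flat at its pre-industrial level) and rises
steeply afterwards — the derivative's simultaneous band excludes zero from
the early 19th century onward, flagging the escalation in nutrient supply.
`compare_periods()` contrasts e.g. Little Ice Age (1180–1840 CE) against
modern (post-1900) utilization, and `fit_breakpoint()` locates the onset of
the supply rise. For wind data, `ekman_seasonal()` returns per-season
anomaly series; for community matrices, `partial_rda()` reports the share of
compositional variance attributable to nutrient supply once time is
partialled out.

A command-line front end wrapping these functions ships in
`inst/scripts/baikalsi-cli.R` (subcommands `simulate`, `utilization`,
`supply`, `ekman`, `trends`, `ordination`, `run-all`).

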