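# metascope

Aerobic-scope analysis of ecological fitness thresholds in juvenile
Pacific salmon and their non-native predators.

## The scientific problem

Whether a fish can rear in or migrate through a river reach depends on
how much aerobic power it can mobilize there. The **metabolic index**

&nbsp;&nbsp;&nbsp;&nbsp;Φ = pO₂ / O₂crit(T),&nbsp;&nbsp;&nbsp;
O₂crit(T) = exp(A − E / (k_B·T))

compares environmental O₂ supply (the partial pressure pO₂, kPa) to the
temperature-dependent O₂ requirement of standard metabolism (the
critical oxygen tension O₂crit of SMR). Φ equals the factorial aerobic
scope (MMR/SMR) an organism can realize at the ambient pO₂: at Φ = 1
only maintenance is possible. The traits *A* (hypoxia-tolerance
intercept, ln kPa) and *E* (temperature sensitivity, eV; k_B is
Boltzmann's constant) are estimated from respirometry via the identity
O₂crit = 21·SMR/MMR (assuming O₂crit of MMR = 21 kPa).

The package implements, end to end:

1. **Traits** — SMR/MMR → O₂crit, temperature standardization,
   mass-scaling fit (ln(O₂crit/m) = β + α·ln m), mass standardization,
   and fixed-effects (`lm`) or by-population mixed-effects (`lme4`)
   Arrhenius fits with bootstrap CIs.
2. **Environment** — dissolved O₂ (mg/L) → pO₂ (kPa) via Benson–Krause
   solubility (Garcia–Gordon coefficients), QC quantile trims, site
   occupancy filters, wild-fry classification, telemetry exposure
   windows with travel-rate fallback.
3. **Φ engine** — daily Φ series, robust seasonal smooths (cyclic
   spline + scaled-t errors, mgcv), threshold classification,
   presence-weighted exposure fractions, predator-Φ surplus.
4. **Fitness models** — binomial-logit smooth models (k = 7 cubic
   regression splines, REML penalties, random intercepts, parametric
   flow×Φ interaction), prediction curves, concurvity, BIC comparison
   of Φ- vs temperature-driven models.
5. **Thresholds** — **Φ_crit** and **Φ_stable** by two-breakpoint
   segmented regression (iterative linearization with grid-search
   initialization, delta-method CIs, brute-force oracle) on log-odds
   prediction curves.
6. **Predation** — predation-probability models from tethered-prey
   deployments (by-method and by-site random intercepts, z-scored
   duration), seasonal predator/prey alignment.
7. **Synthetic data** — seeded generators for all five input streams
   (respirometry, environmental monitoring, rearing surveys, telemetry
   outcomes, predation deployments), so the whole pipeline is testable
   without any external data.

## Worked example

```r
library(metascope)

smolt <- trait_set(A = 14.81, E = 0.33, label = "smolt")
o2crit_at_temperature(smolt, 16.6)  # 4.920769 kPa
phi(21, 16.6, smolt)                # 4.267626  (FAS at air saturation)
percent_between(2.82, 3.81)         # 35.10638  (rearing stable vs crit, %)

# end-to-end on synthetic data
res <- run_pipeline(synth_config(seed = 2, n_outcomes = 2000L))
res$thresholds$rearing
#> Thresholds: crit = 2.647 [2.625, 2.668], stable = 3.814 [3.797, 3.831]
#>   stable is 44% above crit; segmented R2 = 0.9975, relative SE = 0.0647
res$bic$rearing$preferred
#> [1] "phi"
```

The threshold printout reads: fry occupancy stops responding to Φ below
Φ_crit ≈ 2.65 and gains nothing above Φ_stable ≈ 3.81; the Φ model beats
the temperature model by BIC. (The lower breakpoint of the generating
truth, 2.82, is recovered with a known ~0.15 smoothing bias — see the
methods vignette.)

A small command-line front end mirrors the main stages:

```sh
Rscript inst/cli/metascope.R synth --seed 42 --outdir data/
Rscript inst/cli/metascope.R env convert --in data/environment.csv --out data/env_po2.csv
Rscript inst/cli/metascope.R run --seed 42 --outdir out/
```

## Layout

- `R/` — implementation (envio, traits, phi, fitmodels, thresholds,
  predation, synthetic, pipeline, cli)
- `tests/testthat/` — unit, property and acceptance tests
- `vignettes/metabolic-index-thresholds.Rmd` — methods vignette
- `scripts/acceptance.R` — acceptance report
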