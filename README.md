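# meiorepair

Statistics for *Caenorhabditis elegans* meiotic double-strand-break (DSB)
repair assays.

When a meiotic DSB forms, the oocyte can repair it off the homologous
chromosome, the sister chromatid, or — failing recombination — by
error-prone end joining. `meiorepair` implements the analysis stack used to
quantify these outcomes across a heat-shock reverse time course, where
progeny laid 22–58 hr post heat shock derive from oocytes that had the
homolog available as a repair template (the "interhomolog window") and
progeny laid 10–22 hr did not:

* **Recombinant frequency statistics** — Wilson score binomial intervals,
  two-sided Fisher exact tests (point-probability convention), crossover
  proportions among scored recombinants, and fold changes, for the
  intersister/intrachromatid (ICR), interhomolog (IH) and sister chromatid
  exchange (SCE) assays.
* **Conversion tract scoring** — minimum/maximum gene-conversion tract
  lengths over a polymorphism ladder 3′ of the Mos1 excision site;
  short-vs-long classification (noncrossover: conversion only at the 12 bp
  site; crossover: minimum tract ≤ 198 bp); heteroduplex flags; junction
  microhomology and TMEJ-signature classification of mutagenic repair
  products.
* **A Bayesian hierarchical Beta-Binomial brood-viability model** with a
  radiosensitivity posterior ratio ("gamma"). Per group (genotype ×
  timepoint window × dose), hermaphrodite hatch probabilities follow
  p ~ Beta(λφ, λ(1−φ)) and hatched ~ Binomial(brood size, p), with
  γ = φ(dose)/φ(0 Rads) computed draw-by-draw. Fitting uses a bundled
  deterministic adaptive Metropolis sampler with split R-hat / ESS
  diagnostics, and posterior-predictive simulation of 1500 hermaphrodites
  per group.
* **RAD-51 focus profiling** — focus-to-nucleus assignment at a 0.4 μm
  surface-distance threshold, per-germline position normalization
  (pachytene = 0 to 1), sliding-window mean ± SEM profiles (width 0.1,
  step 0.01), and per-stage-bin pairwise Mann-Whitney U tests with
  Holm-Bonferroni correction.
* **Seeded synthetic-data generators** for every input shape, so the whole
  pipeline runs and is tested without any external data.

The package is tidyverse-native: user-facing functions take a data frame
first and return tibbles, fitted models have `tidy()`/`glance()`/
`autoplot()` methods, and `plot_*()` helpers produce the field's standard
displays. A thin command-line dispatcher (`meiorepair_cli()`, wrapped by
`inst/cli/meiorepair`) exposes the stages `validate`, `stats`, `tracts`,
`brood-fit`, `brood-gamma`, `rad51` and `simulate`; every stage is
byte-deterministic given `--seed` and its inputs.

## Worked example

Compare SCE frequencies between a *brc-1* mutant (5 exchange-positive of 26
scorable chromatid pairs) and wild type (2 of 49):

```r
library(meiorepair)
compare_proportions(5, 26, 2, 49, labels = c("brc-1", "wild type"))
#> Two-proportion comparison (Fisher exact, two-sided)
#>   brc-1: 5/26 = 19.2% (95% CI 8.5-37.9%)
#>   wild type: 2/49 = 4.1% (95% CI 1.1-13.7%)
#>   p = 0.045
fold_change(5, 26, 2, 49)
#> [1] 4.7
```

SCEs occur in 19.2% of mutant chromatid pairs versus 4.1% in wild type — a
4.7-fold increase, unlikely under equal rates (p = 0.045).

Fit the brood-viability model to synthetic data with a known
radiosensitivity ratio of 0.5 (mean viability 0.45 under 2500 Rads vs 0.9
unirradiated, 15 hermaphrodites per condition) and recover it:

```r
groups <- tibble::tibble(
  genotype = "mut", window = "T22_34", dose_rads = c(0, 2500),
  phi = c(0.9, 0.45), lambda = 50, mean_brood = 200, n_herm = 15)
broods <- sim_brood(groups, seed = 1)
fit <- fit_brood_model(broods, control = mcmc_control(seed = 1))
gamma_posterior(fit)
#> # A tibble: 1 x 6
#>   genotype window dose_rads median conf_low conf_high
#>   <chr>    <chr>      <dbl>  <dbl>    <dbl>     <dbl>
#> 1 mut      T22_34      2500  0.483    0.432     0.537
```

The posterior median γ of 0.48 (95% credible interval 0.43–0.54) recovers
the generating ratio of 0.5: irradiation roughly halves this genotype's
brood viability.

See `vignettes/meiotic-dsb-repair-statistics.Rmd` for the full model
description, parameter conventions and design choices.

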