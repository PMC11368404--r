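---
title: "Methods: statistics for meiotic DSB repair assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: statistics for meiotic DSB repair assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meiorepair)
library(dplyr)
```

# What this package models

Meiotic double-strand breaks (DSBs) in *C. elegans* oocytes can be repaired
off the homologous chromosome, the sister chromatid, or — when recombination
fails — by error-prone end joining. Three genetic/cytological assays probe
these outcomes, and this package implements the statistics used to analyze
each:

* **Reverse time-course progeny assays** (ICR: intersister/intrachromatid
  repair; IH: interhomolog repair). A heat shock induces a Mos1-excision DSB
  at a known locus; progeny laid in successive 12-hour windows after the
  shock derive from oocytes that were at successively *earlier* meiotic
  stages when the break formed. Progeny laid 22–58 hr post heat shock come
  from leptotene–mid-pachytene oocytes, when the homolog is available as a
  repair template (the *interhomolog window*); progeny laid 10–22 hr come
  from late-pachytene–diplotene oocytes (the *non-interhomolog window*).
  Windows are half-open `[start, end)` because parents are transferred to a
  fresh plate at hours 22, 34 and 46 and discarded at 58: an egg laid at the
  instant of transfer is scored on the new plate.
* **SCE scoring**: sister chromatid exchanges counted on EdU-labeled
  diakinesis bivalents, as exchange-positive chromatid pairs out of scorable
  pairs.
* **Conversion tract sequencing**: each recombinant's repair products are
  genotyped at a ladder of polymorphisms 12–567 bp 3′ of the excision site.
* **Brood viability under ionizing radiation**: per-hermaphrodite hatched
  and dead-egg counts after 0, 2500 or 5000 Rads, modeled hierarchically
  (below).
* **RAD-51 focus counts** along the distal–proximal germline axis, a
  cytological proxy for resected DSBs engaged in recombination.

A seeded synthetic-data module generates inputs with the statistical
structure each stage assumes, so the full pipeline is exercised end to end
without any external data.

# Frequency statistics

All binomial confidence intervals are **Wilson score intervals** (the
default of the DescTools convention used in this field); a Clopper–Pearson
option exists behind `method = "clopper-pearson"`. The Wilson choice is not
cosmetic: the assay literature's printed interval endpoints (e.g. 1.1–13.7%
for 2 of 49 scorable pairs) are reproduced only by the Wilson form.
`wilson_ci()` pins the lower bound to exactly 0 at k = 0 and the upper to 1
at k = n.

Two-sided **Fisher exact tests** (`fisher_exact_2x2()`) use the
point-probability criterion — the sum of hypergeometric probabilities of
all tables with the observed margins no more probable than the observed
table, with relative tolerance 1e-7 — i.e. the `fisher.test()` convention.
Degenerate margins return p = 1 (the conditional distribution is a point
mass). Replicates are pooled before testing; displayed frequencies are
combined sums across replicates, and stratified per-replicate testing is
out of scope.

Crossover proportions (`crossover_proportion()`) count crossovers out of
crossovers + noncrossovers only: progeny whose recombinant class could not
be resolved ("undetermined") and mutant progeny stay in the totals but
never enter these denominators.

Reporting conventions: percentages to one decimal, fold changes to one
decimal, p-values to three decimals (two significant figures below 0.01).

# Conversion tract scoring

Each tract is a vector of per-polymorphism calls: `converted`,
`unconverted`, `heteroduplex` (two chromatogram peaks at a known
polymorphism: unresolved mismatched duplex), or `unreadable`.

* The **minimum tract** spans the most proximal to the most distal
  converted polymorphism, inclusive: `distal − proximal + 1`, so a single
  converted site gives 1 bp. Heteroduplex counts as converted for extent
  (heteroduplex points are drawn inside tract spans); unreadable is
  non-informative.
* The **maximum tract** extends to the nearest flanking unconverted
  polymorphisms on *both* sides (proximally bounded by the excision site at
  position 0, distally by one past the ladder end). The distal extension is
  standard; the symmetric proximal rule is this package's documented choice
  — the alternative (one-sided extension) would change only `max_bp`, which
  is reported but never used for classification, so no headline statistic
  depends on it.
* A **short noncrossover** has conversion only at the most proximal
  polymorphism (12 bp); a **short crossover** has minimum tract ≤ 198 bp,
  the wild-type median minimum crossover tract length (inclusive
  threshold).
* Recombinants carrying two distinguishable repair products are flagged
  `ambiguous` and excluded from summaries.

The default ladder fixes the published endpoints (12 and 567 bp) and ships
plausible synthetic interior positions; every classification rule depends
only on position 12 and the 198 bp threshold, so the interior spacing never
affects results.

**Mutation signatures.** `junction_microhomology()` returns the largest m
such that the m bases ending at the deletion start equal the m bases ending
at the deletion end — identical sequence abutting both junction sides, the
annealing signature of theta-mediated end joining (TMEJ). Matching is exact
(no mismatches) and m is a maximum, so ties cannot arise.
`classify_mutations()` calls an event TMEJ-like when the deletion is
< 50 bp and carries ≥ 1 bp of junction microhomology or a templated
insertion (an insertion of ≥ 3 bp found in the reference in either
orientation; shorter insertions match by chance and are never flagged).

# The Beta-Binomial brood viability model

For each group — genotype g, timepoint window t, radiation dose i — the
brood of hermaphrodite h is modeled as

$$p_{g,t,i,h} \sim \mathrm{Beta}(\lambda_{g,t,i}\,\phi_{g,t,i},\;
\lambda_{g,t,i}(1-\phi_{g,t,i})), \qquad
\mathrm{hatched}_{g,t,i,h} \sim \mathrm{Binomial}(n_{g,t,i,h},\, p_{g,t,i,h})$$

where brood size n = hatched + dead eggs (unfertilized oocytes never enter
brood size), φ ∈ (0,1) is the group mean viability and λ > 0 the Beta
shape-parameter sum: small λ means strong inter-hermaphrodite
overdispersion, λ → ∞ recovers a plain binomial. Marginalizing p gives the
beta-binomial likelihood `betabinom_loglik()` actually used for fitting.

*Hierarchy interpretation.* The displayed equations of the source analysis
index p by group only, yet the model is explicitly meant to absorb
inter-hermaphrodite variance. A single p shared by all hermaphrodites of a
group would be unidentifiable jointly with a free (φ, λ); we therefore fit
the marginal beta-binomial per hermaphrodite (equivalently: p drawn per
hermaphrodite), and all downstream quantities use the group-level mean
viability φ = E[p]. This decision is recorded in the fit object's metadata
(its priors and control settings are stored alongside the draws).

*Radiosensitivity metric.* For every irradiated group,
$\gamma_{g,t,i} = \phi_{g,t,i} / \phi_{g,t,0\,\mathrm{Rads}}$ computed
draw-by-draw with numerator and denominator paired by draw index
(generated-quantities semantics), summarized by the posterior median and
central 95% credible interval. γ = 1 means irradiation had no effect;
γ = 0 means sterility. Genotypes are compared by credible-interval overlap
(`gamma_interval_overlap()`); because φ is strictly inside (0,1) on the
sampling scale, γ is always finite.

*Priors* (the source analysis states none; these are this package's
documented defaults, configurable in `brood_priors()`): φ ~ Uniform(0,1);
λ ~ Exponential(rate 1/1000), weakly informative with mass on both heavy
overdispersion and near-binomial groups. A Half-Normal(σ = 500) λ prior is
built in for sensitivity refits.

*Sampler.* Groups are conditionally independent, so each is fit separately
by a component-wise adaptive random-walk Metropolis on (logit φ, log λ):
4 chains of 2000 warmup + 2000 retained draws by default, per-coordinate
proposal scales adapted every 50 warmup iterations toward an acceptance
rate in the 0.30–0.45 band. Each group's chains are seeded from a
deterministic hash of the control seed and the group key, so a group's
posterior is bit-identical whether fit alone or alongside other groups, and
the whole fit is bit-reproducible under one seed. Convergence is monitored
with split R-hat and a Geyer-truncated effective sample size per parameter;
R-hat > 1.01 raises a warning and flags the fit, never silently passes.
Zero-brood hermaphrodites contribute no likelihood term (viability is
undefined at brood 0) but are counted in `glance()`.

*Posterior predictive check.* `posterior_predictive_sim()` simulates 1500
hermaphrodites per group by default — brood ~ Poisson(group mean brood
size), (φ, λ) resampled from the posterior draws, p ~ Beta, hatched ~
Binomial — matching the published simulation design, with zero-brood
parents retained as missing viabilities.

# RAD-51 focus profiling

Focus-to-nucleus assignment (`assign_foci()`) models nuclei as spheres and
counts a focus toward a nucleus when its distance to the nucleus *surface*
(0 for interior points) is at most 0.4 μm; a focus within threshold of
several nuclei goes only to the nearest, with ties broken toward the lowest
nucleus identifier, so no focus is double-counted. The real segmentation
produces arbitrary surface meshes; the sphere simplification preserves the
threshold semantics and is the only geometry this package attempts.
Interior foci count at distance 0 (the sign convention of the upstream
"distance to surface" statistic is unstated; counting interior points is
the only biologically sensible reading).

Positions are normalized per germline so pachytene spans exactly [0, 1]:
`(raw − tz_end) / (pachytene_end − tz_end)`; transition-zone nuclei map to
negative values, and a transition zone a quarter the length of pachytene
starts at −0.25, the lower edge of the profiled span.

`sliding_window_profile()` reports mean foci per nucleus, SEM (sample
SD/√n) and n in closed windows of width 0.1 advancing by 0.01 position
units; empty windows are omitted, and the overlap between successive
windows is inherent and intended. SEM is pooled across germlines (the
per-germline alternative is a known display choice, not implemented).

Stage bins — TZ (−0.25, 0], EP (0, 0.2], E/MP (0.2, 0.4], MP (0.4, 0.6],
M/LP (0.6, 0.8], LP (0.8, 1] — are left-open/right-closed so position 0
falls in the transition zone and 1.0 in late pachytene; only boundary
nuclei are sensitive to this choice. Within each bin,
`compare_foci_by_bin()` runs two-sided Mann–Whitney U tests on per-nucleus
counts for every genotype pair and applies Holm–Bonferroni within the bin
(family = the bin's testable pairs). Focus counts are heavily tied, so the
test uses exact enumeration of all group assignments (permutation p on
tie-averaged ranks) when the combined sample is ≤ 20 and the tie-corrected
normal approximation without continuity correction otherwise.

# Synthetic data: what it emulates and what it does not

Each generator draws from its own named RNG stream derived from
(seed, generator name), so adding a generator to a workflow never perturbs
another's output, and every generator is bit-reproducible.

* `sim_progeny()`: per parent and window, brood ~ Poisson, class counts ~
  Multinomial — the shape of the per-plate source-data tables. Default
  class rates are illustrative (recombinants rare, crossovers a minority);
  the true per-window rates are only partially recoverable from published
  totals and are **not** claimed.
* `sim_brood()`: the model's own generative process; 15 hermaphrodites per
  condition by default, matching the three-replicates-of-five design, with
  brood sizes Poisson as in the published posterior simulation.
* `sim_tracts()`: a true tract anchored at the excision site with
  configurable length distribution; ladder sites inside are converted,
  converted calls flip to heteroduplex at a configurable rate. Draws
  covering no ladder site are dropped as nonrecombinant (they would not
  have been scored).
* `sim_germline()`: nuclei uniform along (−0.25, 1] with Poisson focus
  counts from a position-dependent rate; no attempt at real gonad 3D
  geometry or nucleus packing.
* `sim_junctions()`: reference sequences with a deletion carrying *exactly*
  the requested junction microhomology (flanks forced equal at m, forced
  unequal at m + 1). Requires deletion size > microhomology, since a
  microhomology as long as the deletion forces flank periodicity that can
  raise the realized value above the request.

Passing tests on these generators demonstrates the *statistical machinery*
— estimators, tests, classifiers, the sampler — under the model's own
assumptions. It does not validate biological features the generators omit:
transgenerational effects, stage-dependent brood sizes, spatial nucleus
structure, or real per-window recombination rates.

# Numerical choices and problem sizes

* Likelihoods in log space via `lbeta`/`lchoose`; the sampler works on the
  unconstrained (logit φ, log λ) scale with Jacobians, so φ never touches
  0/1 and λ never 0.
* Exact Mann–Whitney enumeration is capped at combined n = 20
  (choose(20,10) = 184,756 assignments); beyond that the tie-corrected
  normal approximation is used.
* Wilson bounds are computed in closed form and clipped to [0,1];
  boundary cases k = 0 and k = n are pinned exactly.
* Test-suite problem sizes (chosen to give tight checks at interactive
  runtimes): exhaustive Fisher-oracle agreement for all tables with total
  ≤ 22 plus 200 seeded tables up to total 40; exhaustive tract
  classification over all 4^5 call vectors on a five-site ladder; 1000
  planted junctions; 20-dataset φ-recovery at the full default MCMC
  length; 30-replicate interval-overlap calibration and 500-replicate
  RAD-51 power simulation at 200 nuclei per genotype.

# Known limitations

* The brood model fits groups independently (no partial pooling across
  genotypes or windows); this matches the source analysis but forfeits
  shrinkage when groups are small.
* γ compares mean-viability parameters, not per-hermaphrodite predictive
  distributions; heavy-tailed groups with equal φ are indistinguishable by
  γ alone.
* Published γ values are figure-only, so the model is validated by
  parameter recovery on synthetic data, not by numeric reproduction.
* The sphere nucleus model ignores real surface geometry; counts near
  touching nuclei can differ from mesh-based assignment.
* `read_progeny()` validates structure and counts but cannot detect
  semantically wrong labels (e.g. swapped windows).
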