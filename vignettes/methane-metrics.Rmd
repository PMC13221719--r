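---
title: "Methane metrics for pasture-based sheep: models, simulation design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methane metrics for pasture-based sheep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methmetrics)
```

## The problem

Enteric methane in sheep can now be spot-measured at scale with portable
accumulation chambers (PAC): an animal sits in a sealed chamber for about
50 minutes and its CH~4~ and CO~2~ accumulation is converted to a daily
output in g/d. With thousands of such records linked to body weight,
intake, growth, carcass and CT phenotypes, the question becomes *which
definition of "methane efficiency" to use*: absolute output, a ratio to a
production trait, or a model-based residual. These definitions are not
interchangeable — they rank animals differently and trade off total
emissions against productivity in different ways. `methmetrics` implements
the full analysis chain needed to study those trade-offs: data editing,
trait derivation, variance-component estimation, and selection-ranking
comparison — together with a synthetic flock generator so every stage can
be verified end-to-end without access to confidential industry data.

## Trait definitions

For each edited emission record the package derives:

* **Absolute output**: CH~4~ in g/d as measured.
* **Ratio traits**: methane intensity per kg body weight (MI~BW~), per kg
  metabolic body weight (MI~MBW~, with MBW = BW^0.75^), per kg/d average
  daily gain, per kg carcass weight, per kg CT muscle or fat mass, per
  unit predicted kill-out proportion, per unit muscle-to-fat ratio and per
  litre rumen volume (growing animals only for the ADG/carcass/CT set);
  methane yield MY = CH~4~/DMI (g/kg DM); CH~4~/(CH~4~+CO~2~); and CO~2~
  yield = CO~2~/DMI. Each ratio is the exact quotient; it is absent when
  the denominator is absent, non-positive (logged) or ineligible for the
  cohort. Intake enters in kg DM/d and ADG in kg/d — the printed trait
  scales are only consistent with those units.
* **Residual methane traits (RMT~x~)**: the deviation of a record's
  methane from a linear mixed-model prediction that adjusts for systematic
  effects and one or more production traits *x* ∈ {BW, MBW, DMI, MBW+DMI,
  ADG, CW, MBW+ADG} (growing; the first four for ewes).

The residual-trait model for growing animals is

$$y_{i} = \mu + G_j + A_k + \text{sex} + \text{birth litter} +
\text{rearing litter} + \text{age class} + \beta_5\,\text{rec} +
\beta_6\,\text{het} + \textstyle\sum_b \beta_b B_b + PT(s) + e_{i}$$

with random contemporary group $G_j$ (flock × measurement date × PAC run)
and random animal $A_k$; ewes replace sex by lactation status and age in
months by age in years. Heterosis is $1-\sum_i s_i d_i$ and recombination
loss $1-\tfrac{1}{2}(\sum_i s_i^2 + \sum_i d_i^2)$ over the parental breed
fractions; breed proportions enter as continuous covariates with Suffolk
as the reference breed. Age classes are categorical: the data carry no
guarantee of linearity in age, and the covariate label is reserved for
heterosis/recombination/breed fractions, which are genuinely continuous.

**Which residual?** Two readings of "residual methane" are defensible:
the conditional residual $e_i$ alone, or the animal effect plus residual
$y - (X\hat\beta + \hat G_j)$. The package defaults to the latter
(`mode = "animal"`): residual traits are interpreted as capturing
animal-specific drivers such as host genetics and the rumen microbiome,
which live in $A_k$, not in $e_i$. The conditional residual remains
available (`mode = "conditional"`). Derived values are reported as
deviations from their cohort mean (`center = TRUE`): a residual trait has
mean zero by definition, and the uncentred mean is already within
shrinkage error of zero (the test suite bounds it below 1% of the trait
SD at the default scale — the only reason it is not exactly zero is that
BLUP shrinkage weights records unevenly).

**Repeatability** is $R = \sigma^2_A/(\sigma^2_A + \sigma^2_e)$. The
fitted model keeps contemporary group as a third variance component but —
following the printed definition — excludes $\sigma^2_{CG}$ from the
denominator: chamber-run and date effects are management environment, not
animal permanence. `include_cg = FALSE` drops the term entirely for users
who prefer the two-component variant. The standard error comes from a
parametric bootstrap (default 200 replicates) because the ratio's
analytic SE is awkward under the variance floor.

## The EM-REML engine

Variance components are estimated by EM-REML on Henderson's mixed-model
equations. The implementation absorbs the random factor with more levels
(typically the animal): with $W = [X\;Z_{CG}]$ and the animal block
diagonal, each iteration reduces to a dense solve of dimension
$p + q_{CG}$ plus sparse products, so a 6,800-record fit with ~3,400
animals and ~650 groups takes seconds. The EM updates are the classical
ones — $\hat\sigma^2_u = (\hat u'\hat u + \sigma^2_e\,\mathrm{tr}\,C^{uu})/q$
and $\hat\sigma^2_e = (y'y - \hat\theta'W'y)/(n - \mathrm{rank}\,X)$ —
with components floored at 10^-10^ and convergence declared when the
largest relative change drops below 10^-8^.

Plain EM converges linearly, and only sublinearly toward a zero-variance
boundary, so the engine wraps the iteration in a safeguarded Aitken
Δ²-extrapolation: every fourth step the per-component trajectory is
extrapolated to its fixed point, and the jump is kept only if the
restricted likelihood does not decrease. Two consequences matter for
verification: converged components sit far inside the stopping tolerance
(balanced one-way fits match the ANOVA closed forms
$\hat\sigma^2_e = MSW$, $\hat\sigma^2_a = (MSB - MSW)/k$ to ~10^-10^),
and boundary cases collapse cleanly to the floor instead of crawling. A
final polish step re-tests each near-zero component at the floor and
adopts it when the likelihood is no worse. The default iteration cap is
2000; sparse designs (a few hundred groups over a few hundred records)
legitimately need several hundred EM steps. Fits that still fail the cap
are flagged and refuse downstream use. The test suite checks the engine
against a direct dense-matrix restricted-likelihood oracle on small
instances and against `lme4` on moderate ones; agreement is ~10^-6^.

Estimated marginal means evaluate the fitted fixed effects at each level
of a factor with continuous covariates held at their sample means, other
factors at their reference levels, and random effects at their
population average of zero; pairwise differences use Wald z tests. With
thousands of records a denominator-degrees-of-freedom correction would
change nothing material, so none is applied.

## What the synthetic flock emulates

`simulate_flocks()` generates the structure the analysis assumes:

* **Population**: 3,400 growing animals / 3,900 ewes across 40 flocks by
  default, with roughly 28% of animals carrying 2–7 repeated records
  (mean ≈ 1.8 records per animal).
* **Contemporary groups**: flock × measurement date × PAC run, 12 chamber
  slots per run, with partially filled final runs so the ≥5-animal group
  rule is genuinely exercised.
* **Breed structure**: purebreds (40%), F1 crosses (30%) and
  Dirichlet-mixed composites (30%) over Belclare, Blackface Mountain,
  Charollais, Cheviot, Lleyn, Suffolk, Texel, Vendeen and a pooled Other
  class, with Texel/Suffolk/Belclare the most frequent. This spreads the
  heterosis covariate over [0, 1] and recombination loss over ~[0, 0.8].
* **Methane**: mean + sex (+0.8 g/d for males, inside the 0.55–1.36 g/d
  band the marginal-means comparison reports) + litter-size and age-class
  effects + heterosis/recombination slopes + per-breed proportions
  (Charollais ≈ −2.1 g/d per unit proportion, and for ewes Belclare −2.2,
  Cheviot −4.4, mirroring the reported directions) + an MBW link
  (0.35–0.4 g/d per kg^0.75^) + an intake link (1.8–2.0 g/d per kg DM) +
  contemporary-group, animal and residual effects with configurable
  variances. Defaults give total variance near the published phenotypic
  spread (growing ≈ 14 ± 5 g/d, ewes ≈ 21 ± 8 g/d) and animal-variance
  fractions near the published repeatabilities (0.26 growing / 0.34 ewe).
* **Intake**: the observed DMI *is* the latent intake that drives the
  record's methane — indoor weigh-back measures a growing animal's stable
  intake, and the pasture n-alkane protocol estimates intake around the
  methane date. Modelling measured DMI as a noisy proxy instead would
  introduce an errors-in-variables attenuation the real protocols do not
  have, and residual traits would retain a spurious correlation with
  intake. Ewe intake coverage (14% of animals, ~85% of their records) is
  set so the count of intake-linked methane records matches the scale of
  the published intake-adjusted trait (~800 records).
* **Production tables**: longitudinal weights (growth ≈ 250 ± 45 g/d,
  clipped to 80–430 so the 150–350 g/d ADG filter bites), carcass
  records (≈ 42% of live weight, slaughter 0–40 d after the last methane
  record so the 30-d window rule bites), CT traits scaled to body weight,
  and ewe litter records.
* **Windows by construction**: body weights are truncated to the cohort
  windows (growing 25–80 kg, ewes 55–100 kg); growing ages are confined
  to 105–600 d by sampling each animal's records from a contiguous block
  of sessions.

What it deliberately does **not** emulate: pedigree relationships (animal
effects are i.i.d.), seasonal pasture dynamics, within-day PAC kinetics,
growth of body weight across a growing animal's repeated records, and any
genotype-specific variance heterogeneity. Passing tests therefore show
that the *pipeline machinery* is correct under the assumed variance
structure — not that the published real-data estimates would reproduce,
which the undeposited data make impossible at any rate.

The repeatability calibration helper (`repeatability_study_config()`)
builds 1,000 animals × 2 records with the trait links switched off —
otherwise unobserved intake variance would leak into the animal term and
the true animal-variance fraction would not equal the requested one — and
with 10 flocks so PAC runs are full: with only ~4 animals per group the
group variance is weakly identified and the repeatability estimate is
markedly noisier across replicates, for no gain in realism.

## Data editing rules

The QC stage applies, in order: the 4 g/d methane floor; a single-pass
±3 SD screen with mean and SD computed on the post-floor cohort (the
editing is described as one pass, and iterating would remove records the
described edit does not); the 2,500 g/d CO~2~ ceiling, which only
invalidates the record for CO~2~-based traits; and the ≥5-animal
contemporary-group rule, applied after the emission filters with group
sizes recomputed on surviving records. Weight windows and the
production-table edits (carcass 15–26 kg, slaughter age 100–450 d and
within 30 d of the nearest methane record, ADG 150–350 g/d from weights
within ±120 d, CT within 3 d with trait-wise ±3 SD screens, DMI within
±30 d with a ±3 SD screen) treat all "within N d" windows as inclusive of
both endpoints. Filters only subset — no value is ever modified — and
every removal is logged with the rule it tripped.

## Ranking comparison

The selection comparison takes animals with complete data for all four
headline metrics (CH~4~, MI~MBW~, MY, RMT~MBW+DMI~), represents each
animal by its most efficient (lowest) record per metric, and selects the
top round(0.25 n), breaking boundary ties by ascending animal id. Group
means of intake, methane, weight and cohort-specific traits are computed
over the selected animals' ranking records. Because the selected groups
overlap in membership, the pairwise comparisons (Welch t tests with Holm
adjustment, annotated with compact letters) are descriptive, not a
formal independent-samples inference; this mirrors how such tables are
usually presented and is documented rather than "corrected".

## Problem sizes used in the checks

The packaged tests and the acceptance script run the growing and ewe
cohorts at their default scales (≈6,500 simulated records each, ≈5,800 /
6,200 surviving QC), ten calibration replicates of 1,000 × 2 records per
cohort for repeatability recovery, a 16,000-animal draw for checking the
generator's variance decomposition, and small (≤30-record) instances for
the brute-force REML oracle. These sizes keep every stage's Monte-Carlo
error an order of magnitude below the tolerances being asserted.

## Known limitations

* Two crossed random intercepts at most; no nested terms, no genetic
  covariances, no heritability estimation.
* Wald z inference throughout; no Satterthwaite/Kenward-Roger df.
* The exact scaling of the kill-out intensity (proportion vs percent
  denominator) is ambiguous in the field; the package divides by the
  proportion (≈0.45) and documents this choice here.
* Correlations are computed at record level, including repeated records
  per animal, so their effective sample size is smaller than `n`.
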