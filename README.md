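# methmetrics

Derivation and comparison of enteric-methane emission metrics for
pasture-based sheep phenotyped with portable accumulation chambers (PAC).

Reducing methane from ruminants is a breeding goal, but there is no
consensus trait definition: absolute daily output (g CH₄/d), ratio traits
(methane intensity per kg body weight, metabolic body weight, carcass or
CT tissue; methane yield per kg dry matter intake; CO₂-based ratios) and
model-based residual traits rank animals differently and trade off total
emissions against productivity in different ways. `methmetrics` is aimed
at quantitative geneticists and livestock scientists who want to study
those trade-offs on data with the structure of a national multi-breed PAC
campaign — and, because such datasets are rarely public, it ships a
synthetic flock generator with configurable variance components so the
whole analysis is verifiable end to end.

The package implements:

* **Synthetic flocks** (`sim_config()`, `simulate_flocks()`): per-record
  methane built as mean + fixed effects (sex, litter sizes, age class,
  heterosis, recombination loss, breed proportions, lactation status) +
  production-trait links + contemporary-group, animal and residual
  effects with configurable variances; linked intake, weight, carcass,
  CT and maternal tables; flock × date × PAC-run group structure with
  12-slot runs.
* **Data editing** (`assign_contemporary_groups()`,
  `apply_emission_filters()`, `apply_weight_and_window_filters()`): the
  4 g/d methane floor, single-pass ±3 SD screens, the 2,500 g/d CO₂
  ceiling (CO₂ traits only), the ≥5-animal contemporary-group rule,
  cohort body-weight windows (growing 25–80 kg, ewes 55–100 kg) and the
  carcass/ADG/CT/DMI window rules, with a full exclusion log.
* **Covariates** (`heterosis_coefficient()`, `recombination_loss()`,
  `metabolic_body_weight()`, `average_daily_gain()`): heterosis
  1 − Σᵢ sᵢdᵢ, recombination loss 1 − (Σᵢ sᵢ² + Σᵢ dᵢ²)/2 over parental
  breed fractions, MBW = BW^0.75, and OLS growth slopes from weights
  within ±120 d of the methane date.
* **Ratio traits** (`compute_ratio_traits()`, `trait_summary()`): the
  twelve quotient traits with cohort eligibility and absence rules.
* **Mixed models** (`lmm_spec()`, `fit_lmm()`): a bespoke EM-REML engine
  on Henderson's mixed-model equations (larger random factor absorbed,
  safeguarded Aitken acceleration, variance floor 1e-10, tolerance 1e-8)
  returning fixed effects, variance components, BLUPs and the REML
  log-likelihood; validated against closed-form ANOVA estimators, a
  brute-force restricted-likelihood oracle and `lme4`.
* **Residual traits, repeatability, marginal means**
  (`derive_residual_trait()`, `estimate_repeatability()`,
  `marginal_means()`): RMT_BW/MBW/DMI/MBW+DMI/ADG/CW/MBW+ADG per cohort;
  R = σ²ₐ/(σ²ₐ+σ²ₑ) with bootstrap SE; estimated marginal means with
  Wald-z contrasts.
* **Associations and ranking** (`correlate()`, `correlation_matrix()`,
  `rank_top_quartile()`): record-level Pearson correlations with analytic
  SEs, and the four-metric top-25% selection comparison with Welch/Holm
  group tests.
* **Pipeline** (`pipeline_config()`, `run_pipeline()`): all stages in
  sequence with CSV artifacts and a JSON-lines log.

## Worked example

```r
library(methmetrics)

cfg <- sim_config("growing", seed = 42, n_animals = 800, n_flocks = 10)
b   <- simulate_flocks(cfg)
#> Synthetic growing flock bundle: 800 animals, 1570 emission records
#>   tables: dmi 41, weights 3200, carcass 194, ct 169, maternal 0

cg <- assign_contemporary_groups(b$emissions)
ef <- apply_emission_filters(cg$records)
wf <- apply_weight_and_window_filters(ef$records, "growing", dmi = b$dmi,
                                      carcass = b$carcass, ct = b$ct)
nrow(wf$records)          # 1398 records survive the editing rules
md  <- prepare_model_data(wf$records, b$animals, dmi_links = wf$dmi_links)

rmt <- derive_residual_trait("RMT_BW", md, "growing")
rmt$fit
#> EM-REML linear mixed model: ch4
#>   n = 1398 records, rank(X) = 29, 42 iterations, converged: TRUE
#>   variance components:
#>     animal_id            3.12919
#>     contemporary_group   3.7457
#>     resid                11.8186
round(mean(rmt$values$value), 2)   # 0    -- residual trait is centred
round(sd(rmt$values$value), 2)     # 3.67 -- animal + residual spread, g/d
```

The variance components sit at the scale the generator was configured
with (contemporary group 4, residual 11.8 (g/d)²; the animal component is
estimated with considerable noise at this small demonstration size), the
residual trait is uncorrelated with the body weight it adjusts for
(`cor` rounds to 0.00), and downstream:

```r
sp  <- residual_trait_spec("RMT_BW", "growing")
est <- estimate_repeatability(md, "ch4", factors = sp$factors,
                              covariates = setdiff(sp$covariates, "body_weight"),
                              ref_levels = sp$ref_levels, nboot = 50, seed = 1)
#> methane repeatability: R = 0.27 (SE 0.04)

marginal_means(rmt$fit, "sex")$emmeans
#>    level emmean    se
#> 1 female   13.7 0.424
#> 2   male   14.6 0.441
```

Males emit about 1 g/d more than females at this seed — the simulated
sex effect is +0.8 g/d — and the repeatability estimate sits at the
simulated animal-variance fraction (0.26). `run_pipeline()` chains all of
the above plus ratio traits, correlations and the top-quartile ranking
into a CSV artifact directory.

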