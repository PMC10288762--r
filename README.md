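# mrisubtype

Differential treatment response across MRI atrophy subtypes in two-visit
randomized trials of mild cognitive impairment (MCI).

Clinical trials in prodromal Alzheimer's disease recruit biologically
heterogeneous cohorts, and that heterogeneity can mask who actually
benefits from a drug. `mrisubtype` is for trial statisticians and
neuroimaging researchers who want to test whether treatment response varies
with a subject's *MRI subtype*, expressed two ways:

* **Continuous subtyping dimensions** — *severity*, the BV/CSF index
  `(GM + WM) / CSF` (lower = more global atrophy), and *typicality*, the
  hippocampus-to-cortex ratio `mean(L,R hippocampus) / mean of three
  cortical region L/R means` (middle frontal, inferior parietal, superior
  temporal; lower = limbic-predominant-like, higher =
  hippocampal-sparing-like).
* **Categorical subtypes** — typical AD, limbic-predominant,
  hippocampal-sparing and minimal atrophy, from visual-rating scores (MTA,
  PA, GCA-F) thresholded with age-adjusted cut points.

Efficacy outcomes are annualized percent changes (APC) of ICV-adjusted
hippocampal, ventricular and total grey-matter volumes and of the
AD-signature cortical thickness,

```
APC = (follow-up − baseline) / baseline × 365 / interval_days × 100
```

and percent changes (PC) of cognitive scores. The primary inference is the
treatment × dimension interaction in OLS models

```
APC ~ treatment * severity + treatment * typicality + age [+ field_strength]
```

with optional BIC-based backward selection under the marginality
constraint, plus subtype × treatment ANCOVA (Type-II SS, BH-corrected post
hoc contrasts) and a baseline group-comparison table. A first-class
synthetic two-arm, two-visit cohort generator makes every stage testable:
injected interaction effects are recoverable, the null tests hold their
size, and the whole pipeline is deterministic given a seed.

## Worked example

Simulate a trial-sized cohort, derive the dimensions and outcomes, subtype
it, and fit the primary interaction model:

```r
library(mrisubtype)

cohort   <- generate_cohort(simulation_config(seed = 7))
derived  <- derive_measures(cohort)
profiles <- build_subtype_profiles(cohort, derived)
subtype_frequencies(profiles)$categorical_subtype
#> # A tibble: 4 × 3
#>   level                   n percent
#>   <chr>               <int>   <dbl>
#> 1 typical_AD              4    2.31
#> 2 limbic_predominant     42   24.3
#> 3 hippocampal_sparing    13    7.51
#> 4 minimal_atrophy       114   65.9

tab <- analysis_table(cohort, derived, profiles)
fit_interaction_model(tab, "apc_signature")
#> <interaction_fit> outcome: apc_signature  (n = 173)
#>   F = 19.924, R^2 = 0.458, p = 3.238e-19
#>                   term estimate std_error statistic   p_value
#> 1          (Intercept) -0.50498   1.80937   -0.2791 7.805e-01
#> 2                  age -0.01959   0.01692   -1.1575 2.487e-01
#> 3     field_strength3T -0.25767   0.24327   -1.0592 2.911e-01
#> 4            treatment -5.62924   1.68207   -3.3466 1.013e-03
#> 5             severity  0.01638   0.01215    1.3478 1.796e-01
#> 6           typicality  1.72774   4.58751    0.3766 7.069e-01
#> 7   treatment:severity  0.09510   0.01627    5.8467 2.614e-08
#> 8 treatment:typicality 14.64389   6.44989    2.2704 2.448e-02
```

Reading the fit: the generator injected treatment × severity = 0.11 and
treatment × typicality = 16 %/year per unit on the AD-signature APC; at
n = 173 a single cohort recovers them within sampling error (0.095 and
14.6 here). The positive interactions mean treated subjects with *less*
atrophy at baseline (higher BV/CSF index, more hippocampal-sparing-like
ratio) lose cortical thickness more slowly than placebo, while the benefit
shrinks towards the limbic-predominant / typical-AD corner of the plane.

`run_pipeline("out/", seed = 7)` runs the whole chain (inclusion screen →
derive → subtype → models) and writes `derived.csv`, `subtypes.csv`,
`interaction_models.csv`, `anova_models.csv`, `anova_posthoc.csv`,
`baseline_table.csv`, two figures and a digest manifest; reruns with the
same seed are byte-identical. A thin CLI wrapper with the same stages lives
at `exec/mrisubtype`. Real cohorts enter through
`read_cohort("morphometry.csv", "clinical.csv")`; the column contract is
documented in `?read_cohort`, and all cut points and region vocabularies
live in an editable YAML configuration
(`inst/extdata/subtype-config.yaml`).

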