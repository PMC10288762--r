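---
title: "MRI subtyping dimensions and treatment-response models: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MRI subtyping dimensions and treatment-response models: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrisubtype)
```

## The scientific problem

Alzheimer's disease is heterogeneous: individuals with the same clinical
stage show different regional patterns of brain atrophy, and those patterns
plausibly modulate who benefits from a given therapy. `mrisubtype`
implements an analysis pipeline for two-visit randomized trials in mild
cognitive impairment (MCI) that asks whether the response to treatment —
measured as the annualized change of MRI outcomes — varies with a subject's
position on two *continuous subtyping dimensions*, and, for comparison, how
the same question looks through the conventional *categorical* subtype
lens.

## The two subtyping dimensions

**Severity** is proxied by the BV/CSF index: total brain volume (grey +
white matter) divided by total CSF volume,

$$\mathrm{BV/CSF} = \frac{\mathrm{GM} + \mathrm{WM}}{\mathrm{CSF}}.$$

Lower values mean more global atrophy (towards a typical-AD-like pattern);
higher values mean minimal atrophy. The CSF volume is taken as a provided
input column; which CSF compartments it comprises is a property of the
upstream segmentation pipeline and is deliberately not re-derived here.

**Typicality** is proxied by the hippocampus-to-cortex ratio: the mean of
left and right hippocampal volumes divided by the unweighted mean of three
cortical regions' left/right mean volumes (middle frontal, inferior
parietal, superior temporal). Low values lean limbic-predominant, high
values lean hippocampal-sparing. Two parsing choices are worth making
explicit:

* The denominator is a *two-level average* (per-region left/right means,
  then a flat mean over the three regions), not a volume sum.
* "Middle frontal" is not a single label in the Desikan parcellation; the
  package sums the caudal and rostral middle frontal parcels per
  hemisphere.

The ratio is stored raw; any ×100 display scaling belongs to reports only.

## Categorical subtypes from visual ratings

The conventional classification thresholds three visual-rating scales:
medial temporal atrophy (MTA, 0–4, left/right), posterior atrophy (PA,
0–3) and the frontal subscale of global cortical atrophy (GCA-F, 0–3).
MTA is abnormal when the left/right *mean* reaches the age-band cut
(≥ 1.5 at ages 45–74, ≥ 2.0 at 75–84, ≥ 2.5 at 85–94); PA and GCA-F are
abnormal at ≥ 1 regardless of age. The four subtypes are a total function
of the three indicators: abnormal MTA with abnormal PA and/or GCA-F is
*typical AD*; abnormal MTA alone is *limbic-predominant*; abnormal PA
and/or GCA-F with normal MTA is *hippocampal-sparing*; all normal is
*minimal atrophy*.

Design choices where the rule tables are silent:

* Left/right MTA are combined by the arithmetic mean before thresholding —
  the dominant convention in the subtyping literature, and it uses both
  hemispheres.
* Continuous (machine-estimated) ratings are thresholded directly, without
  rounding to half-steps; the cuts are ≥-comparisons and rounding would
  move borderline cases.
* Ages outside 45–94 raise an error rather than clamping: the rule table's
  support is as published, and silent extrapolation would hide a data
  problem.
* The age-adjusted severity-band cut-offs on the BV/CSF index are not
  restated in the literature this package models; they ship as clearly
  marked, editable placeholders in the YAML configuration and are used for
  descriptive banding only. A value exactly on a boundary falls in the less
  atrophic band.

## Efficacy outcomes

The MRI outcomes are annualized percent changes (APC) of four composites:
ICV-adjusted hippocampal volume, ICV-adjusted lateral-ventricle volume,
ICV-adjusted total grey matter, and the AD-signature cortical thickness
(mean over entorhinal, inferior temporal, middle temporal and fusiform
left/right mean thicknesses):

$$\mathrm{APC} = \frac{v_{\mathrm{fu}} - v_{\mathrm{bl}}}{v_{\mathrm{bl}}}
\times \frac{365}{\mathrm{interval\ (days)}} \times 100.$$

The annualization constant is 365 days exactly, matching the outcome
definition this pipeline reimplements. Negative APC means loss. Values
outside ±100%/year can arise if a measure more than doubles; they trigger a
warning, not an error. Cognitive outcomes use the percent change (PC), the
same formula without the annualization factor.

Head size is removed with the residual approach:
`adjusted = value − b · (ICV − mean ICV)`, with the slope `b` estimated by
least squares on the *baseline* rows of the analysis cohort and applied
unchanged to both visits. Refitting per visit would leak fit noise into the
change scores; with a common slope and a subject's ICV constant across
visits, the adjustment shifts both visits by the same offset, so the APC
numerator is untouched and only the denominator is re-centred. The
`icv_fit_sample` argument lets users fit the slope on a control-only
subsample.

## The inferential models

For each outcome the package fits, by ordinary least squares,

$$y = \beta_0 + \beta_1\,\mathrm{trt} + \beta_2\,\mathrm{sev} +
\beta_3\,\mathrm{typ} + \beta_4\,\mathrm{age} +
[\beta_5\,\mathrm{field}] + \beta_6\,(\mathrm{trt}\times\mathrm{sev}) +
\beta_7\,(\mathrm{trt}\times\mathrm{typ}) + \varepsilon,$$

with treatment as a 0/1 dummy (0 = placebo) and MRI field strength included
iff the outcome is an MRI APC. The two interaction coefficients are the
effects of interest. Complete cases only (per-protocol logic; no
imputation), and `n` is reported with every fit.

**Backward selection.** When selection is requested, candidate sub-models
are scored by BIC under the marginality constraint (an interaction is never
retained without both its main effects; age and field strength are never
dropped, since they are design covariates rather than hypotheses). With at
most 12 removable terms every admissible sub-model is enumerated
exhaustively, which is deterministic and exactly optimal. The greedy
variant walks the full elimination path — at each step dropping the
candidate whose removal gives the lowest BIC — and returns the best model
among *all* candidates scored during the pass. Stopping at the first
non-improving step is a known local-optimum trap; scoring the whole path
removes it. Backward-only search still cannot revisit a dropped term, so
exact agreement with exhaustive enumeration is guaranteed only when effects
are decisively present or absent; with borderline effects (|t| near the
BIC boundary of about two) the two searches can legitimately differ, which
is why the exhaustive mode is the default. Ties favour the smaller model,
then enumeration order, so selection is deterministic.

**Subtype ANCOVA.** The categorical analysis is a fully between-subjects
two-factor ANCOVA (subtype × arm) with age (and field strength for MRI
outcomes) as covariates. Effects are tested with Type-II sums of squares:
subtype cells in such cohorts are wildly unbalanced, and Type-II keeps main
effects interpretable in that setting. Post hoc arm contrasts within each
subtype are computed from the model's cell means and Benjamini–Hochberg
adjusted *within the outcome's contrast family* — the narrowest defensible
reading of "post hoc analyses were BH-adjusted", documented here precisely
because it is a choice. Subtype levels with an empty or single-observation
arm cell are inestimable: their contrasts are reported as undefined with a
warning and the level is excluded from the interaction test rather than
silently absorbed.

**Baseline table.** Group comparisons use one-way ANOVA for continuous
variables (Kruskal–Wallis on request, per variable — no automatic normality
gate, since any such rule would itself be a silent analytic choice) and the
chi-square test without continuity correction for categorical variables.

## The synthetic cohort generator

Real trial data of this kind are proprietary, so the package carries a
first-class generator whose defaults describe the study conditions the
pipeline targets: 173 subjects, 48% randomized to active treatment, age
73.8 (6.6) years, ~26% of scans at 3T, follow-up MRI near 12 months with
10% of scans falling uniformly in 6–11 months, severity 29.2 (12.7) and
typicality 0.25 (0.03) as independent Gaussians (correlation configurable,
0 by default — the dimensions are conceptually separate axes).

Two constructions make the generator a sharp validation instrument:

* **The latent dimensions are realized exactly.** CSF volume is set to
  (GM+WM)/severity and hippocampal volumes to typicality × (observed
  cortical denominator), so the *derived* baseline dimensions equal the
  latent ones to machine precision. Interaction-coefficient recovery is
  therefore free of errors-in-variables attenuation, and calibration
  failures cannot hide behind predictor noise.
* **Atrophy rates are injected in closed form.** Follow-up values equal
  baseline × (1 + rate/100 × interval/365) with
  rate = base + arm × (main + β_sev·(sev − mean) + β_typ·(typ − mean)) +
  Gaussian noise. Centring the interaction injection keeps cohort-level arm
  differences physiologic while the configured β's are exactly the
  regression interaction coefficients. With all noise off and the interval
  pinned to 365 days, the computed APC of unadjusted measures equals the
  configured base rate identically; for ICV-adjusted volumes the residual
  offset rescales the denominator, and the corresponding closed-form
  identity is what the tests assert.

Default injected effects echo the magnitudes such a trial reports
(typicality × treatment ≈ 16 %/year per unit and severity × treatment ≈
0.11 %/year per unit on the AD-signature APC; ≈ −101.75 on the ventricular
APC); they are study conditions for recovery experiments, not claims about
any particular dataset. Rate noise defaults (1–4 %/year by measure) subsume
biological and measurement variability of the change score.

Visual ratings are monotone noisy linear transforms of latent atrophy
(MTA of head-size-free hippocampal volume; PA and GCA-F of severity),
clipped to their scale bounds — a declared stand-in for an unknown joint
distribution, monotone before noise by construction. The clipping is a
known truncation. Only regions feeding the derived measures carry
structured signal; the remaining Desikan columns are calibrated noise so
the schema stays complete. Cognitive scores decline by a configured percent
with Gaussian noise and no treatment effect by default. The
`scenario_amnestic_mci()` preset shifts the rating links towards pronounced
medial-temporal and scarce posterior/frontal atrophy, which makes minimal
atrophy and limbic-predominant the two dominant categorical subtypes after
classification — the composition an amnestic-syndrome inclusion screen
produces.

What the generator does *not* emulate: realistic spatial covariance of the
full parcellation, scanner- or site-effects beyond field strength, dropout,
floor/ceiling dynamics of cognitive tests, or any nonlinear atrophy
trajectory. Tests passing on this generator therefore demonstrate the
*statistical machinery* (formulas, geometry of the adjustment, test size,
coefficient recovery, selection optimality, determinism), not that real
MCI data satisfy the generative assumptions.

## Numerical choices and degenerate inputs

* ICV adjustment requires ≥ 3 fit subjects and non-constant ICV; violations
  are errors, as are zero baselines in APC/PC and non-positive intervals.
* Rank-deficient model designs fail with the aliased terms named;
  single-arm data are refused.
* The inclusion screen (age > 50; FCSRT free recall ≤ 17 or total recall
  < 40; CDR ≤ 0.5; MMSE > 24) reports every failed criterion, and a missing
  eligibility field is an error, never a silent exclusion.
* All randomness flows from a single seed; fits are deterministic, and two
  pipeline runs with the same seed produce byte-identical CSVs.

## Problem sizes used in the validation suite

The package's own test suite sizes its simulations for a laptop-class
single-core run: 2000 null replicates of n = 200 for test-size calibration,
500 replicates of n = 2000 for interaction-effect recovery and interval
coverage, 500 datasets for the selection-optimality comparison, 100
trial-sized cohorts for the scenario-composition check, and an exhaustive
~58,000-cell grid for the classifier oracle. These sizes were chosen so
each Monte-Carlo standard error is comfortably below the margin being
asserted. All replicates of an experiment share one RNG stream seeded once
by a master seed; per-replicate re-seeding with sequential seeds is avoided
because nearby seeds give correlated early draws and inflate the
Monte-Carlo variance of pooled estimates.

## Known limitations

* The severity-band thresholds shipped in the configuration are
  placeholders; banding output is descriptive until users supply published
  cut-offs.
* The per-outcome BH family for post hoc contrasts is one defensible
  definition among several; users who want a across-outcomes family should
  adjust the pooled p-values themselves.
* "Mixed ANOVA" terminology notwithstanding, the design here has only
  between-subject factors; no repeated-measures covariance structure is
  modelled, because the outcome is already a change score.
* The generator's monotone rating links are a modelling device; real
  ratings-given-morphometry relations are noisier and possibly
  non-monotone at scale extremes.
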