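---
title: "Methods behind the ASMD suspicion index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind the ASMD suspicion index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical procedure the package implements,
the defaults it fixes, and what its synthetic-data experiments can and
cannot show. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The problem

Acid sphingomyelinase deficiency (ASMD) is a rare lysosomal storage
disorder whose presenting signs — hepatosplenomegaly, thrombocytopenia,
interstitial lung disease, dyslipidemia with low HDL-C, and a spectrum of
neurological findings — overlap with far more common conditions and with
other storage disorders (Niemann–Pick type C, Gaucher disease). A
suspicion index converts a handful of binary symptom indicators into a
probability that a patient warrants confirmatory enzymatic or genetic
testing. The development design compares three chart-review groups:
confirmed cases, phenotypically similar lysosomal-disease controls, and
confirmed non-cases.

## Screening statistics

Each symptom is screened on a 2×2 cases-versus-controls table with
pairwise-complete denominators (an `unknown` chart entry is excluded from
that symptom only, never coerced to `absent`).

* **Exact p-value.** Two-sided Fisher exact test by the point-probability
  convention: the p-value sums the central hypergeometric probabilities of
  every table with the observed margins whose probability does not exceed
  the observed one (relative slack 1e-7 against floating error). This is
  the convention of standard statistical software, and `fisher.test` is
  used as an independent oracle in the tests, never as the implementation.
* **Odds ratio.** The conditional maximum-likelihood estimate: the value
  maximizing Fisher's noncentral hypergeometric likelihood given all
  margins, obtained by root-finding on the conditional score equation
  (expected cell count equals observed; relative tolerance 1e-8 on the
  root). The reporting orientation is **comparator odds over case odds**,
  matching the development study's published table and the reverse of the
  conventional case-exposure direction: symptoms enriched in cases get
  odds ratios below 1. Tables with a zero cell sit on the boundary and
  return exactly 0 or infinity; a Haldane–Anscombe-corrected sample
  estimate is reported alongside as a finite auxiliary.
* **Multiplicity.** Holm's step-down adjustment over the testable
  symptoms (delegated to `stats::p.adjust`); untestable symptoms (no
  known observations in a group) are excluded from the family.
* **Candidates.** The development methods state p < 0.001 and the results
  section p < 0.01; both are supported, the packaged default is 0.001 and
  is applied to the raw p-value (the published per-symptom p-values are
  unadjusted).

One published row (interstitial lung disease, 32/48 vs 3/52, printed
p = 0.03) is internally inconsistent — the exact p computed from its own
counts is below 1e-10 — and is treated as a typesetting artifact
throughout.

## The risk model

The score is a three-class multinomial logistic regression over binary
symptom indicators, with the non-case group as reference. The fit
maximizes the multinomial log-likelihood minus `ridge/2 · ||slopes||²`
(intercepts unpenalized) by Newton iteration with step-halving from a zero
start; the objective is strictly concave for positive ridge, so the fit is
deterministic — no random initialization, no hidden layers. The default
ridge of 1e-2 exists because the study prevalences are quasi-separated
(several symptoms occur in 0% of non-cases, dyslipidemia in ~100%); an
unpenalized fit would diverge along the separating directions. Convergence
is declared when the gradient max-norm falls below 1e-8 (fits) or 1e-6
(inside the subset search).

Because all predictors are binary, the likelihood is aggregated over
distinct symptom patterns (at most 2^p rows) before the Newton step; this
is an exact reformulation, and it is what makes ~100,000 refits in the
stability selection affordable. Two numerical caveats are documented
deliberately: the ridge penalty is not invariant to the choice of
reference class (predicted probabilities agree across reference codings
exactly only as the ridge vanishes), and `unknown` predictor values are
handled by complete-case exclusion with the count kept on the fitted
object.

## Variable selection

The events-per-variable rule caps the model at
`floor(n_events / 10)` predictors; with 48 cases this is four. Hepatomegaly
and splenomegaly are merged first into `hepatosplenomegaly` (present only
if both are present, `unknown` if undecidable), reflecting their clinical
co-occurrence, so the cap covers the five clinically named signs in four
slots.

Selection then repeats, per random stratified 70/30 split of the cohort:
fit every non-empty candidate subset of size ≤ 4 on the training part
(exact enumeration — no heuristic search), score it on the held-out part,
and record the winner. The per-split criterion defaults to held-out
classification accuracy, with multinomial test deviance as the
alternative; the development report does not name its criterion, and this
choice is documented as an assumption. Ties break toward the smaller
subset and then lexicographically, which makes the procedure invariant to
candidate ordering. Variables winning in more than 70% of splits form the
final set. A random-forest importance ranking (mean decrease in impurity,
averaged over repeated fits) serves as a cross-check of the same question
with a more flexible learner.

## The deployed tool

The tool gates on hepatosplenomegaly: a patient without it is never
scored (the prerequisite enters the fitted model as a predictor fixed at
1 during scoring, so the same model remains usable on full cohorts). The
three remaining inputs are 0/1 questions; the output is the multinomial
probability vector, and the 8-row probability table enumerates every
input combination. The high-risk cutoff defaults to 0.50 — the
development study's reported median case score — and `derive_cutoff()`
recomputes it as the median case probability over gated-in cases of a
given cohort. Percent output uses a decimal point at full internal
precision.

## Internal validation

Validation is one-versus-one for the two published contrasts (cases vs
controls, cases vs non-cases), not one-versus-rest. Each bootstrap
repetition resamples patients with replacement stratified by group (so
the 48-case class cannot vanish), refits the model on a stratified 70%
part of the resample and evaluates on the held-out 30%; confidence
intervals are percentile order statistics. ROC curves threshold the case
probability at its unique values; the trapezoidal AUC then equals the
normalized rank-sum statistic with half-weight ties, verified in tests
against an all-pairs concordance oracle and an independent ROC
implementation.

## The synthetic-cohort generator

No patient-level data are distributed with the development report, so the
generator is a first-class module emulating the study conditions: group
sizes 48/52/808, per-group symptom prevalences equal to the published
counts over group sizes, published sex splits, age means/SDs and
family-history rates. Within-patient dependence uses one standard-normal
latent severity factor per patient; symptom j is Bernoulli with logit
`alpha_gj + lambda·z`, and `alpha_gj` is recalibrated by 1-D numerical
integration so the configured marginal prevalence is preserved for any
loading. The packaged default loading is 1.0, which qualitatively
reproduces the reported co-occurrence of visceral signs (isolated
hepatomegaly without splenomegaly being rare); `dependence = 0` gives
exactly independent symptoms and is the setting used for oracle-style
tests. One root seed drives per-group substreams, so resizing one group
leaves the others byte-identical.

Choices where the published record is silent, fixed once: ASMD subtypes
are assigned uniformly over A/A-B/B to cases (subtype is not used
downstream); ages are normal truncated at zero with onset ≤ current age
enforced by resampling then clamping. The published non-case age row
(onset mean 34.9, current mean 14.0) contradicts that ordering, so the
realized non-case age marginals shift — a property of the printed table,
noted rather than repaired. Percentages print to 0 decimals to mirror the
published tables; underlying values keep full precision.

**What passing tests do and do not show.** The generator reproduces
group-wise marginal prevalences and a plausible positive dependence, not
the study's true joint symptom distribution, symptom onset times, or
subtype-specific profiles. Results that hinge on the joint distribution —
which variable wins the contested fourth selection slot, the numeric
median case score, the deployed tool's exact probabilities (which rest on
unpublished fitted coefficients) — are therefore checked as qualitative or
property-style assertions, and the measured values on synthetic cohorts
(e.g. a median case score near 1 rather than 0.5, because the synthetic
margins separate cases far more cleanly than real charts) should not be
read as estimates of the study's numbers.

## Problem sizes used

The packaged experiments run at sizes chosen to make the stochastic
assertions stable on a single workstation: stability selection on a
tenfold cohort (480/520/8080) with 100 splits and exact enumeration of
the 1,092 admissible subsets of 13 candidates per split; bootstrap
validation with 100 repetitions at study scale; oracle sweeps over
exhaustive small 2×2 tables plus several hundred random tables up to
n = 60; parameter recovery at n = 20,000. The full-scale defaults (1000
repetitions) remain the documented configuration values.

## Known limitations

* The screening engine offers no continuous-covariate tests or confounder
  adjustment (ages are described, not tested; age likely confounds the
  dyslipidemia contrast).
* The selection criterion and the study's exact train/test protocol are
  under-documented in the published record; both supported criteria are
  exposed and the default is an assumption.
* Percentile (not BCa) bootstrap intervals.
* No external validation, calibration curves or decision-curve analysis;
  the package validates internally only.
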