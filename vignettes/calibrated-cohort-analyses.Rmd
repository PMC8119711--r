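---
title: "Calibrated cohort simulation and robustness analyses for sex-modified memory effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrated cohort simulation and robustness analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palcohort)
```

## The scientific problem

Large web-recruited cohorts make it possible to ask whether biological sex
*modifies* environmental and vascular associations with cognition, rather
than treating sex as one more adjustment covariate. The concrete setting
this package implements is a cohort of roughly 80,000 adults aged 18–85 who
completed a three-trial, twelve-word-pair paired-associate learning (PAL)
task (total score 0–36) and answered seventeen demographic and
health/lifestyle questions, including current smoking. The published
analyses of that cohort report, in word-pair units:

* a pooled sex × smoking interaction of **0.99** (SE 0.22) in a linear
  model with 30 non-intercept design columns, F(30, 81,670);
* stratified ("simple effects") smoking coefficients of **−1.01** (SE
  0.14) in women and **−0.27** (SE 0.18, p = 0.135) in men;
* sex × cardiovascular-disease (CVD) composite interactions of −0.84 /
  −1.38 / −1.64 for CVD sums 1 / 2 / 3+ against the sum-0 control group;
* a propensity-matched smoking effect in women of −0.54 with a 95%
  credible interval (−0.93, −0.14);
* three resampling studies: balanced down-sampling power curves (50% power
  near n = 10,000), a misclassification Monte Carlo (at 10% label error
  the women's effect stays significant in >90% of replicates, the
  interaction in ~75%), and permutation tests (no permuted |t| reached the
  observed women's statistic in 10^6 permutations).

The underlying individual-level data are not deposited. The package
therefore pairs every analysis with a **synthetic cohort generator**
calibrated to the printed composition and effect/SE ratios, so the entire
analytical machinery is executable, testable and auditable end to end.

A useful consistency check, which the generator exploits: a single
residual sd of ≈ 8.26 word pairs reproduces all three printed smoking SEs
simultaneously at the printed stratum sizes and prevalences (0.14 women,
≈ 0.17 men, ≈ 0.22 interaction), and under label-inversion algebra it also
reproduces the printed "75% significant at 10% error" figure analytically
(attenuation 0.427 × SE shrink 0.73 ⇒ post-error t ≈ 2.63 ⇒ power ≈ 0.75).

## The cohort model and generator

`generate_cohort()` draws records with:

* sex (64.3% women) and age (uniform over 18–85 by default; the source
  gives no age histogram, so this is a configurable choice, not a claim);
* a smoking prevalence curve `smoking_prevalence_curve()` that declines
  with age, keeps men's rate 1.3× women's at every age, and integrates to
  7.9% overall; a flat curve is available for tests that require smoking
  to be independent of age and sex;
* the four CVD booleans (heart disease, hypertension, diabetes, stroke)
  drawn *jointly*: first the per-sex sum group (0/1/2/3+) from its printed
  distribution, then the component flags spread uniformly over the
  `choose(4, k)` combinations (the source constrains only the sum). A 3+
  participant has all four conditions with probability 0.2;
* the remaining covariates from configurable prevalence tables
  (`default_prevalences()`) — plausible stand-ins, since the source's
  supplemental composition tables are not public;
* a latent outcome `intercept + effects + N(0, noise_sd)`, clipped to
  [0, 36] and rounded. The observed task has a floor and a ceiling, which
  the clipping emulates; it can be disabled (`clip_and_round = FALSE`) for
  exact-recovery tests. `noise_sd` may differ by sex: matching both the
  women's printed SE (0.14) and the men's (0.18) requires mild
  heteroscedasticity (≈ 8.26 vs ≈ 8.92 word pairs).

Nuisance covariate effects default to moderate nonzero values (e.g. an
education gradient of up to 2.6 word pairs, −1.0 for seizure history).
They matter in two places: they give lasso stability selection real signal
to find, and they make the residual sd of a correctly specified model
differ from the marginal outcome sd, as in real data. The CVD sum effects
are deliberately *non-additive* in the four component booleans (the effect
attaches to the count, not the condition), which is why the smoking
model's additive boolean adjustment is a mild, realistic misspecification;
it is orthogonal to smoking by construction and does not bias the focal
terms.

Scenario presets (`scenario_config()`): `"A"` (stratified truths
−1.01/−0.27), `"B"` (interaction truth 0.99), `"NULL"` (all effects zero,
for type-I-error calibration) and `"cvd"` (sex-specific CVD group
effects). For `"cvd"` the published numbers are internally inconsistent —
the pooled interactions (−0.84/−1.38/−1.64) do not equal the differences
of the published per-sex stratified effects (−0.23/−0.32/−0.53) because
stratified refits free every covariate slope — so the preset keeps the
women's stratified values and chooses the men's so that the two quantities
the package's recovery checks exercise are simultaneously true: the pooled
group-1 interaction is −0.84 and the men's stratified 3+ effect is −1.80.

### Seeding

One global seed expands into per-stage child seeds through
`child_seed(seed, stage)`, a fixed affine hash modulo 2³¹−1; every engine
takes its own seed, so any stage can be reproduced in isolation and the
whole pipeline is a pure function of (config, seed).

### Calibration

Three calibration helpers connect the generator to printed values:

* `calibrate_noise()` finds the `noise_sd` whose *expected* coefficient SE
  matches a target at a given n. The SE is proportional to sigma for a
  fixed design, so iterated proportional rescaling over simulated fits
  converges in 2–3 rounds; clipping makes the map mildly nonlinear, which
  the iteration absorbs. For a balanced 2×2 design with no covariates the
  closed form SE = 4·sigma/√n applies (`balanced_interaction_se()`), and a
  target SE above what the bounded 0–36 score can produce is reported as
  unreachable rather than silently approximated.
* `calibrate_effect()` divides the focal latent effects by the analytic
  floor/ceiling attenuation factor (`clip_attenuation()`, the mean
  interior Gaussian mass; ≈ 0.96 under defaults), so *expected fitted*
  coefficients match configured targets.
* `calibrate_fitted()` adjusts a focal effect so the coefficient *realized
  on a specific generation seed* equals a target. The published
  simulation studies ran on the one real cohort whose fitted coefficient
  is the printed value; reproducing their percentages therefore requires
  conditioning on a cohort whose fit matches the print, not just whose
  expectation does — the fitted value is affine in the configured effect
  at fixed seed, so two corrections converge essentially exactly.

Because the downstream percentages (power, error-injection survival) are
steep functions of the realized effect-to-SE ratio, the package's
acceptance computations pool replicates over three independent calibrated
cohort draws rather than trusting a single draw.

## Models

`pal_lm()` fits OLS on a deterministic treatment-coded design
(`build_design()`): reference level = first declared level, sex coded
man = 1, so a positive sex × smoking coefficient means smoking is *less*
negative in men — the convention under which −1.01 (women), −0.27 (men)
and a positive pooled interaction cohere. The default schema's category
sizes were chosen so the full model expands to exactly 30 non-intercept
columns, matching the printed omnibus df; degrees of freedom follow
df₂ = n − 31. Simple effects are full stratified refits, not pooled-model
contrasts — the only reading under which the stratified pair and the
pooled interaction can all hold, since stratification frees every
covariate slope per sex.

The CVD model is `pal ~ cvd_group*sex + age + education` (12 non-intercept
columns) exactly as described; the printed omnibus F(31, 81,669) implies
31 columns, which this covariate set cannot produce — the package
implements the described model and surfaces the df mismatch here rather
than inventing hidden covariates.

"Standardized beta coefficients" in the source sits uneasily with
coefficients carrying word-pair units; the package reports raw word-pair
coefficients, which is the scale the printed values are on.

`stability_selection()` subsamples half the cohort (without replacement),
fits a lasso path (focal terms unpenalized), and counts a covariate as
selected when any of its columns is nonzero at any penalty at or above a
per-subsample threshold `lambda_scale · sigma_hat · sqrt(2 log p / n)`
(a universal-threshold heuristic on the unpenalized residual scale). The
default `lambda_scale = 0.35` is the documented constant under which all
seventeen default covariates clear the 0.70 retention cutoff at the study
size, mirroring the published finding; a conservative scale (≈ 1)
suppresses pure-noise covariates almost entirely, which is how the
null-calibration test uses it.

## Propensity-score matching

`estimate_propensity()` is a logistic model of smoking on all adjustment
covariates; `match_smokers()` performs greedy 1:1 nearest-neighbour
matching on the logit of the score, processing smokers in descending
score order, without replacement and with no caliper by default (the
defaults of the matching software the source names), distance ties broken
by record order. `matched_effect()` regresses the matched records' PAL on
the smoker indicator plus covariates (a switch reduces it to the
difference in means — the source does not state whether covariates were
kept) and simulates `draws` coefficient vectors from the fit's
multivariate-normal sampling distribution; the 95% credible interval is
the 2.5–97.5 percentile band of the smoker-coefficient draws, the
simulation-inference reading of the published "credible interval". The
published women's interval is printed in descending order ("−0.14 to
−0.93"); the package always emits (lower, upper).

The generator's `confounding` switch makes smoking depend on covariates
through a logistic model (intercept solved to keep the overall
prevalence), which is what makes matching non-trivial in tests: with it
on, the coverage check verifies that the matched interval covers a true
effect of −0.54 in ≥ 90% of seeds.

## Resampling engines

All three engines refit only the smoker-dependent design columns per
replicate, via the Frisch–Waugh–Lovell decomposition on a cached QR of the
fixed columns; the test suite asserts bit-level agreement with full OLS
refits, so speed costs no exactness.

**Balanced down-sampling** (`downsample_balanced()`, `power_curve()`).
The published procedure samples smokers/non-smokers and sexes "at equal
size per age", sizes 268–13,400 = 4 × 67 × (1…50), i.e. one to fifty
records per (age, sex, smoker) cell over 67 single-year bins. Under the
published composition this is arithmetically impossible at the upper
sizes: 13,400 needs 3,350 male smokers per the grid, but 35.7% men × 7.9%
smokers × 81,701 ≈ 2,700 exist in total, and even 37 per cell at 9,916
exceeds what any age distribution can supply (the minimum cell count
cannot exceed the mean, ≈ 48). The engine therefore implements both
readings: `balance = "cell"` does the exact per-cell draw and errors
loudly, naming the deficient cell (no silent rebalancing); `balance =
"group"` (the default, and the only mode executable at the published
sizes) equalizes the four sex × smoker groups at n/4 each and samples
uniformly within group. Group balance is what drives the interaction SE
(≈ 4σ/√n), so the power conclusions are insensitive to the within-age
refinement. `min_n_for_power()` reads the smallest evaluated size
reaching a target fraction significant.

**Misclassification Monte Carlo** (`inject_error()`,
`error_injection_study()`). The source describes the perturbation both as
"re-assigning" and as "randomizing" smoker status; the package's default
is a hard inversion of the selected records' labels, because inversion
reproduces the published 75%-at-10% interaction figure under attenuation
algebra, while redrawing from the marginal roughly halves the effective
error rate (that variant is available via `mode = "redraw"`). The closed
form `attenuation_factor(rate, prevalence)` — the difference in true-smoker
probability between labeled groups, 0.427 at rate 0.10 and prevalence
0.079 — is both a test oracle and the analytic bridge to the published
percentages. Rate 0 reproduces the unperturbed p-values exactly.

**Permutation test** (`permutation_test()`). Smoker labels are permuted
across records (preserving the smoker count — the "permuted datasets"
reading, justified by exchangeability), the complete model refitted, and
the empirical p reported with the (k+1)/(B+1) correction so it is never
zero. On tiny cohorts the empirical p converges to the exhaustive
enumeration over all label arrangements, which the suite checks.

## Problem sizes and budgets

Default replicate budgets are scaled down from the published ones (1,000
down-samples, 10,000 error replicates, 10⁶ permutations) to sizes chosen
for tight Monte Carlo error at interactive cost: the shipped checks use
200 down-sample replicates per size, 1,000 error replicates per rate, and
10,000 permutations, at the full cohort size n = 81,701; all budgets are
arguments. At these sizes the Monte Carlo standard error of a fraction
near 0.75 is ≈ 1.4 pp per cohort, and pooling over three cohort draws
brings the total (cohort + replicate) spread of the error-injection
percentage to ≈ 1.5–2 pp.

## Known limitations

* The generator reproduces printed margins and effect/SE ratios, not the
  real joint covariate distribution (which is not public): passing
  recovery tests demonstrates the machinery and its calibration, not
  epidemiological truth about smoking and memory.
* Ages are uniform by default and covariates mutually independent given
  sex; real cohorts have age-structured covariates. Both are config
  points, and the smoking-age curve is the one deliberate exception.
* The down-sampling per-cell mode faithfully errors on the published
  composition (see above); results at published sizes use group balance.
* Omnibus F values of synthetic cohorts differ from the printed ones (the
  printed F mixes all covariate signal, which depends on the real joint
  distribution); no acceptance quantity depends on them.
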