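---
title: "From diet questionnaires to lipidomic signatures of diet quality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From diet questionnaires to lipidomic signatures of diet quality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## What this package models

Food-frequency questionnaires summarise habitual diet, but they are
self-reported and noisy. A complementary, objective readout is the serum
lipidome: habitual intake of fish, whole grains, processed meat and so on
leaves a measurable imprint on circulating lipid species. This package
implements the full analysis chain that connects the two in a two-wave
epidemiological cohort:

1. **Diet quality scoring** — a 10-component healthy eating index
   (MIDUS-HEI) on a 0–11 point scale, built from banded questionnaire
   responses.
2. **Lipid panel quality control** — removal of species with too many
   measurements below the limit of detection, and rank-based
   inverse-normal (Blom) standardization of the retained species.
3. **Signature derivation** — L1-penalized (LASSO) regression of the HEI
   total on the standardized lipids in the training wave; the *lipid
   signature* of a subject is the intercept-free weighted sum of the
   selected species.
4. **Honest training-set scores** — leave-one-out cross-validation: each
   training subject is scored by a model refitted without them, so the
   reported training correlation carries no training bias.
5. **Clinical endpoints** — metabolic syndrome by the updated ATP III
   rule, and 10-year atherosclerotic cardiovascular disease risk by the
   2013 ACC/AHA pooled cohort equations, normalized to a z scale.
6. **Adjustment-model ladders** — nested linear models (tiers I/II/III)
   of biomarkers and normalized risk on the signature, and logistic
   models of metabolic syndrome on the HEI.

Because the cohort data such analyses use are access-restricted, the
package ships a synthetic-cohort generator that reproduces the
*statistical structure* the pipeline assumes, with planted ground truth,
so every stage is testable end to end.

## The healthy eating index

Ten food groups are scored from banded intake: five with a direct
relation to the score (vegetables/fruits, whole grains, oily fish, lean
meat, non-meat protein), three inverse (sugared beverages, high-fat
meat, fast food) and two non-linear (fermented dairy, alcohol). Each
component contributes 1 point when the recommended criterion is met,
0.5 when partially met, 0 otherwise; vegetables-and-fruits alone can
contribute 2 (it aggregates two food groups in one question), giving a
0–11 range.

Two conventions had to be fixed where the band table leaves real-valued
intakes ambiguous:

* Count-typed intakes (servings asked as whole servings: vegetables/
  fruits, whole grains, lean meat, non-meat protein, sugared beverages,
  high-fat meat, drinking days) are **floored** before band lookup, so
  2.5 servings/day falls in the "1–2" band. Components whose bands are
  genuinely fractional ("<1 serving/week" of oily fish or fast food, the
  "(1 to <2)" dairy shoulder) are banded on the raw value — flooring
  would erase those bands.
* The lean-meat bands overlap at zero ("None" vs "0–2"); we resolve
  0 → 0 points, 1–2 (after flooring) → 0.5, ≥3 → 1.
* Alcohol: a nondrinker scores 0, as does anyone above the sex-specific
  quantity limit (2 drinks/day for men, 1 for women, both inclusive);
  within-limit drinkers score 1 at ≥3 drinking days/week, else 0.5.

Subjects with any unscorable component are excluded with a logged
reason (the cohort's own convention); an `allow_partial` mode that sums
the scorable components exists but is off by default.

## Lipid QC and the Blom transformation

Species are retained only when *strictly less than* 20% of their
measurements fall below the limit of detection. Below-LOD cells of
retained species must still enter the rank-based standardization; the
default policy (`rank_low`) pushes them below every observed value so
they share the lowest tied (average) rank, which is the least
committal reading of a left-censored value. Half-minimum and zero
substitution are available for comparison.

Every retained species is mapped to normal scores by Blom's
transformation, `z = qnorm((rank - 3/8)/(n + 1/4))` with average ranks
for ties. The transform is invariant to any strictly monotone
change of scale, which makes the downstream LASSO indifferent to the
(arbitrary) concentration units of each lipid class. Standardization is
computed on the pooled waves by default — the transformation precedes
the train/test split in the analysis order — with a per-wave option.

## Signature fitting and honest evaluation

The LASSO is fitted with glmnet on the training ("core") wave, with the
penalty chosen by 10-fold cross-validation minimizing mean squared
error (`cv_min`; `cv_1se` and fixed penalties are available). Fold
assignment is controlled by a mandatory seed. Predictors enter
pre-standardized; no internal re-standardization is applied. The
signature score is the intercept-free weighted sum of the selected
species; the intercept is kept in the model object for full prediction.

Training-set scores are leave-one-out cross-validated: the penalty is
selected once on the full training wave and held fixed while the model
is refitted *n* times, each time leaving one subject out and scoring
them with the refit. Holding the penalty fixed keeps the *n* refits
comparable and tractable; re-selecting the penalty inside every fold is
a defensible alternative the package does not implement. The refits run
through an internal warm-started coordinate-descent solver that
minimizes exactly the glmnet objective; tests require agreement with
direct glmnet refits to numerical precision. Testing-wave subjects are
scored directly with the training-wave weights.

Signature–HEI agreement is summarised by Pearson correlation with a
two-sided t-based p-value, reported separately for the LOO-scored
training wave, the testing wave, and both pooled. One degenerate case
needs a rule: when cross-validation selects the empty model, the
signature is identically zero and its scores are numerical refit noise
with vanishing variance; correlating them with the outcome amplifies
that noise into a meaningless (and systematically negative) number. The
pipeline therefore reports degenerate correlations as r = 0 with a
`degenerate` flag whenever the training model selects no species.

## Metabolic syndrome and cardiovascular risk

Metabolic syndrome is ≥3 of 5 criteria, with the inequalities applied
exactly as printed in the updated ATP III definition (waist strictly
above 102/88 cm by sex; triglycerides ≥150 mg/dL or treatment; HDL-c
strictly below 40/50 mg/dL by sex or treatment; SBP ≥130 or DBP ≥85
mmHg or treated-with-diagnosis; glucose ≥100 mg/dL or treatment).
Missing medication flags default to untreated, with a warning —
conservative toward non-disease.

Ten-year ASCVD risk uses the four published race- and sex-specific
pooled cohort equations, shipped as an inspectable coefficient table.
Subjects outside the calculator's validity windows (age 40–79 years,
total cholesterol 130–320 mg/dL, HDL-c 20–100 mg/dL, SBP 90–200 mmHg)
are excluded first; "between" is read as inclusive at both endpoints
(the clinical-calculator convention) and boundary subjects are logged
so the choice is auditable. Race groups beyond the two published ones
map to the white/other equations, as the source recommends. One quirk
of the published coefficients is worth knowing: the white-male
age-by-smoking interaction makes the smoking multiplier cross one just
below the 79-year age bound, so smoking monotonicity holds only below
about 79 years.

The estimated risks are normalized by an inverse-normal map. The
source phrasing is ambiguous between two readings, so both are
implemented: rank-based normal scores of the risk vector (default,
distribution-free) and the direct quantile map `qnorm(risk)`. Outputs
are labelled with the method used.

## Adjustment models

The linear ladder nests structurally: tier I adjusts for sample wave,
age, sex and race; tier II adds BMI; tier III adds the HEI total.
Exposure and continuous outcomes are z-scored on the analysis sample so
coefficients are standardized and comparable across biomarkers.
Logistic models of metabolic syndrome (and each criterion) on the HEI
adjust for wave, sex, race, age, education (two dummies against a
postgraduate reference), smoking (two dummies against current) and
physical activity, reporting the odds ratio per HEI point with a Wald
interval. The normalized-risk ladder additionally emits
`exp(estimate)` as a clearly-labelled derived odds-ratio-style view;
the standardized linear coefficient is the primary result. Analyses
are complete-case throughout; no multiplicity correction is applied by
default (an optional FDR adjustment would be a caller-side
`p.adjust`).

## The synthetic cohort generator

The generator's purpose is narrow: produce data with exactly the
dependence structure the pipeline assumes, with known ground truth, at
realistic sizes (1200 training / 850 testing subjects, 400 lipid
species, 57 of them diet-responsive, by default).

**One latent factor.** A latent diet quality `D ~ N(0,1)` (with small,
realistic demographic shifts: female, white, older, more educated and
non-smoking subjects eat slightly better; the training wave sits ~0.3
HEI points below the testing wave) drives everything the analysis is
supposed to detect. The analysis only ever consumes the HEI total, so
one factor is sufficient for testability.

**Questionnaires by a threshold ladder.** The 21 scoring steps of the
ten components (two per component, three for vegetables/fruits) are
placed at the quantiles of a discretized normal target for the HEI
total (mean 5.8, SD 1.5 by default, matching the published cohort
means of roughly 5.6 and 6.0 by wave). Each component's band is then
`#(w·D + noise > thresholds)` with a high loading (w = 0.97), and a
concrete intake is drawn inside the chosen band. Two properties follow
by construction: the marginal HEI distribution matches its target
(the mean is exact in expectation), and the HEI tracks `D` at r ≈
0.97. A more obvious design — moderate per-component band
probabilities on a shared factor — cannot deliver both an SD near 1.5
and a factor correlation above 0.9: ten moderately-loaded step
functions of one factor necessarily give the sum an SD near 3. The
interleaved ladder, which spreads the steps across the factor's range,
is what makes both targets attainable.

**Lipids.** Signal species load on `D` with geometrically decaying
loadings (ratio 0.5: a few dominant species over a long tail, the
shape such signatures show in practice), scaled so the population
correlation between the best linear lipid combination and the HEI
equals the requested coupling ρ\*. The scaling uses
`cor(combination, HEI) = cor(combination, D) · cor(D, HEI)`, with
`cor(D, HEI)` measured on the realized cohort; couplings at or above
that ceiling raise an error stating the feasible bound. Concentrations
are a lognormal transform of the latent values (the rank-based
standardization makes the pipeline indifferent to this). Below-LOD
flags censor the lowest cells per species: a configurable share of
noise species is censored heavily (25–60%, so the LOD filter has real
work), all others lightly (0–3%). An equal-loadings mode
(`loading_decay = 1`) supports feature-recovery experiments.

**Clinical variables.** The five MetS criteria are probit events on a
shared metabolic factor (loaded on age and, negatively, on `D`), and a
common threshold shift is solved numerically — by exact conditional
Poisson-binomial evaluation of P(≥3 criteria) averaged over the
realized factor — so the classified prevalence hits its target
(37% by default). Each criterion's continuous variable is anchored at
its diagnostic cutoff (e.g. triglycerides `150·exp(0.55·excess)`), so
the binary criterion and the continuous value can never disagree.
Insulin, IL-6 and CRP carry explicit standardized effects of `D`
(defaults −0.20, −0.15, −0.15); HDL-c, glucose, blood pressure, waist
and BMI inherit their diet dependence through the metabolic factor,
reproducing the expected sign structure (HDL-c positive, the rest
negative). Diastolic pressure is generated mostly below its 85 mmHg
cutoff so the blood-pressure criterion is driven by the calibrated
systolic latent; medication flags are drawn mainly among
criterion-positive subjects. Both choices keep the prevalence
calibration accurate to well within ±5 percentage points.

**What the generator does not emulate.** Realistic lipid units and
class-specific covariance, per-food (rather than factor-mediated) diet
effects, longitudinal structure, and measurement drift between waves.
Passing recovery tests on this generator therefore demonstrates that
the *pipeline machinery* is correct and unbiased under its stated
assumptions — not that the published effect sizes would replicate in
any particular real cohort.

## Numerical choices and problem sizes

* LASSO refits: internal coordinate descent with convergence threshold
  1e-11 on the scaled squared step, warm-started at the full-data
  solution; agreement with glmnet is enforced by tests at 1e-5.
* Ranks: average ties everywhere (Blom scores, risk normalization).
* The recovery experiments in the test suite run the full study-scale
  conditions — 20 seeds per coupling level at 1200/850 subjects and
  400 species — which the warm-started refit engine completes in a few
  minutes; the orchestration and generator unit tests use scaled-down
  cohorts (a few hundred subjects, tens of species) chosen to exercise
  every code path rather than statistical power.
* Degenerate inputs: constant columns transform to zeros with a
  warning; zero-variance outcomes, single-class logistic outcomes,
  separation, and collinear covariates raise informative errors rather
  than returning numbers.

## Known limitations

* The LOO penalty is fixed at the full-training-wave selection; the
  alternative (re-selecting the penalty in every fold) would be slower
  and slightly more conservative, and the package does not offer it.
* The odds-ratio view of the risk association is a labelled transform
  of a standardized linear coefficient, not a fitted logistic model.
* The eligibility windows' inclusive endpoints and the below-LOD
  handling policies are interpretations of ambiguous conventions; both
  are logged/configurable so sensitivity checks are one argument away.
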