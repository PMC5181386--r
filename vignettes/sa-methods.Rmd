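---
title: "Methods: scoring successful aging and relating it to self-rated health"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring successful aging and relating it to self-rated health}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rowekahn)
```

## The model

The Rowe–Kahn view of successful aging (SA) combines three criteria —
avoiding disease and disability, maintaining physical and cognitive
function, and staying socially engaged — which this package operationalizes
as six binary dimensions per respondent. Five of the six are
*cohort-relative*: thresholds are set within each age cohort so that roughly
the "best third" is classified positive. That choice deliberately absorbs
normal age-related decline — a 76-year-old is compared with 76-year-olds —
and it is why the package works with two separate cohort labels ("1952",
around age 57, and "1932", around age 76) rather than pooling.

Two summary measures come out of the profile: the conventional binary SA
(`all_six`, all six dimensions positive) and the SA *continuum* (`count`,
0–6). The analysis module treats the continuum as the primary graded
exposure because very few respondents in populations like this satisfy all
six criteria at once, which makes the binary measure uninformative for most
of the sample.

## Scoring rules and boundary conventions

* **Chronic disease.** A respondent is disease-free when no morbidity code
  falls in the qualifying ranges (`disease_code_set()`); ranges are
  inclusive at both ends, exclusions are removed, and codes are compared as
  zero-padded 4-digit integers. An empty code list is disease-free; a
  *missing* code list yields a missing dimension.
* **Disability and cognition.** Printed cutoffs are inclusive in the printed
  direction: disability "≤ 0.5" admits 0.5, cognition "41+" admits 41. This
  is the literal reading of the published dimension definitions.
* **Physical function.** Grip strength and FEV1 are height-standardized
  within sex-by-cohort strata (least-squares residual on height; a
  ratio-to-height variant is available via
  `standardize_physical(method = "ratio")`). The dimension is positive with
  3+ of 4 favorable indicators; comparisons against the medians are
  *strict*, so a value exactly at the median is unfavorable — the rules say
  "above"/"below" median, not "at or above".
* **Engagement.** Interpersonal engagement requires all three items in both
  cohorts; productive engagement requires 3+ items in the working-age cohort
  and 2+ in the post-retirement cohort, reflecting the higher employment
  rate in the younger group.
* **Missingness.** Any missing component makes its dimension missing, and
  any missing dimension makes `count` and `all_six` missing; such
  respondents are excluded from all estimates (complete-case analysis).
  Per-outcome denominators additionally drop respondents missing that
  outcome, so denominators differ across outcomes.

## Cohort-relative thresholds

`derive_thresholds()` supports an "approximate tertile" rule that matches
how tertiles behave on discrete, zero-inflated scores: the cutoff is the
point on the *observed value grid* whose classified-positive fraction is
closest to the nominal fraction (1/3; 1/4, 1/5, 1/2 for the sensitivity
modes), with ties broken toward the more inclusive cutoff. On a disability
score with a large point mass at zero this correctly returns a cutoff of 0
with a positive fraction well above a third — the same phenomenon visible in
published "tertiles" of 40–45%. The published cutoffs themselves are
available as a fixed preset (`mode = "published"`), which is the default for
the main analysis; only the physical-function medians are always
data-derived, since no published median values exist on the standardized
scale.

Because the nominal fractions are ordered, positive sets nest across modes
(quintile ⊆ quartile ⊆ tertile ⊆ median); the test suite asserts this
nesting, permutation invariance of all classifications, and agreement with
a brute-force restatement of the rules on small instances.

## Outcome coding

Four-level health ratings ("excellent/good/fair/poor") are favorable at
excellent or good. Seven-point satisfaction scales are favorable at the
three most positive responses; the neutral midpoint is *unfavorable*. The
package fixes 7 = most positive; instruments coded in the reverse direction
are re-oriented at read time (`satisfaction_reversed = TRUE`), since the
numeric direction of such scales varies between instruments.

## Statistical methods

* **Single proportions** use the Wilson score interval: its coverage is
  close to nominal at moderate n and it cannot escape [0, 1], which matters
  for outcomes near 90% prevalence.
* **Differences of proportions** use the Newcombe hybrid-score interval
  built from the two Wilson intervals, again chosen for behavior near the
  boundary (a Wald interval degenerates at 0/100%).
* **Mutually adjusted effects** come from one additive logistic model per
  outcome containing all six dimensions, reported as
  marginal-standardization risk differences: the mean predicted favorable
  probability with a dimension set positive for everyone minus set negative
  for everyone. This keeps adjusted results on the same percentage-point
  scale as the crude differences instead of switching to odds ratios.
  Confidence intervals are percentile intervals from a nonparametric
  bootstrap over respondents (default 200 resamples, seeded); refits showing
  separation or non-convergence are flagged, not dropped. With a single
  binary predictor the standardized difference collapses to the crude risk
  difference exactly, which the tests assert to 1e-6.
* **Subgroups.** Stratified analyses repeat the crude estimates within
  cohort, sex, occupational class and negative-affect halves; heterogeneity
  is assessed by the Wald test of the dimension-by-stratifier interaction in
  a logistic model. The negative-affect split is the median of the analysis
  sample's trait scores, ties assigned to the "below" half (configurable).
* **No multiplicity correction** is applied: the output is estimation with
  confidence intervals, not a family of accept/reject decisions.
* **Display rounding** is one decimal, half away from zero; all computation
  is at full precision.

## The synthetic generator

No public data carry these variables, so `generate_cohorts()` provides the
test bed. Design choices, in the package's own terms:

* A single standard-normal latent health factor per person, shifted by sex
  (−0.08 female, +0.10 male) and occupational class (−0.60 manual, +0.20
  nonmanual), drives every dimension variable linearly (continuous measures)
  or logit-linearly (binary items, disease). This is the simplest structure
  that produces the qualitative pattern of interest: all six dimensions
  positively associated with all four outcomes, stronger gradients by class
  than by sex.
* **Calibration at construction time.** Cohort intercepts for disease,
  disability, cognition, and the ordinal outcome cutpoints are solved by
  numerical quadrature over the latent mixture so that marginal rates equal
  the configured targets (disease-free 81.2%/58.0%; no-disability at the
  published cutoffs 44.8%/40.3%; top-tertile cognition 1/3; favorable
  outcomes 68.6%, 76.2%, 80.6%, 88.5%). Targets live in the config; solving
  happens in `sim_config()`, so a user changing a target gets a re-calibrated
  generator automatically.
* **Negative affect** is drawn independently of latent health and enters
  only the outcome logits (slope −0.5). This dissociation is structural:
  affect moves self-ratings, not SA dimensions, and the tests verify both
  halves of that statement on replicate simulations.
* **Disease codes** are sampled uniformly from the qualifying ranges for
  respondents with disease; a quarter of disease-free respondents carry an
  innocuous non-qualifying code, so code-level logic (exclusions, benign
  codes) is exercised rather than bypassed.
* **Ordinal outcomes** are generated ordered-logit style: a latent response
  (latent-health slope ~1, logistic error) cut at calibrated points, with
  fixed spacings (1.5/1.8 around the favorable cut for 4-level scales, 0.9
  for 7-point scales) so all levels are populated. The recent-health outcome
  carries an extra −0.55 logit shift in the older cohort, mirroring the one
  outcome with a visible cohort gap.
* **Disability, cognition, physiology.** The disability score is a rounded,
  zero-floored normal on a 0.5 grid (zero-inflated by construction); the
  cognition score a rounded normal (SD contributions 8 latent + 6 noise);
  grip/FEV1/SBP/pulse are normals with height and cohort effects and latent
  loadings (+3 kg, +0.3 L, −8 mmHg, −4 bpm per SD). No published
  distributional information exists for these instruments beyond the
  cutoffs, so these are plausibility choices, fixed once.
* **Missingness** is MCAR at a configurable rate (default 0); a MAR switch
  ties the rate to latent health, since excluded respondents in studies of
  this kind tend to be more disadvantaged. Cohort and sex labels are never
  masked.

What the generator does *not* emulate: the real sampling design and
attrition process, geographic structure, and the exact joint distribution of
the dimensions — e.g. its all-six prevalence (~4%) is higher than the
published ~0.6–1.9%, because a single latent factor induces more
between-dimension correlation than the real data show. Passing tests
therefore demonstrate that the pipeline recovers the structure it is fed and
reproduces published *arithmetic*, not that the generator replicates the
cohort.

## Problem sizes and numerical tolerances

The test suite runs the full pipeline at study scale (886 + 483) and smaller
cohorts (150–500) for property checks; parameter-recovery tests use 50
replicate simulations at study scale and compare replicate means against
closed-form expectations computed by numerical integration, within
Monte-Carlo standard-error bounds. Interval implementations are checked
against independent oracles to 1e-6 (Wilson, via score-test inversion) and
1e-9 (Newcombe, via an independent closed-form arrangement). Quadrature
tolerances are 1e-8 to 1e-10; calibration roots are solved to 1e-9.

## Known limitations

* The six dimensions are summary dichotomies; the package does not model the
  underlying continuous domain scores jointly.
* Adjusted effects assume an additive logistic model without
  dimension-by-dimension interactions.
* The heterogeneity check is a per-pair Wald interaction test, not a joint
  test across dimensions.
* `derive_thresholds()` requires non-empty cohorts and at least two complete
  records per sex-by-cohort stratum for standardization; tiny strata are an
  error, not a silent fallback.
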