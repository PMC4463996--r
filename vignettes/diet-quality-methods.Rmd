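---
title: "Diet-quality scoring and cohort analytics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diet-quality scoring and cohort analytics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietq)
```

`dietq` implements a four-stage analysis of FFQ-style dietary records —
intake summarisation, plausibility screening, HEIFA diet-quality scoring,
and cohort statistics — together with a synthetic-cohort simulator that
realises the statistical structure these analyses assume. This vignette is
the package's own account of the science: the models, their assumptions,
the tunable parameters, and the decisions taken where published HEIFA
variants leave the details open.

## The intake model

An FFQ analysis treats each participant's record as a vector of daily gram
amounts over a fixed item list. A composition table (one row per item)
carries the bridge to everything else: food-group and variety-subgroup
assignment, a standard serve size, and per-100 g energy and nutrients.
All derived quantities are **linear in the amounts**:

* group grams/day, serves/day (`grams / serve_size`, summed) and percent of
  energy;
* the wholegrain proportion of grain intake and low-fat proportion of dairy
  intake, both on a gram basis;
* nutrient levels: saturated fat, total sugars and discretionary energy as
  percent of total energy; sodium in mg/day; alcohol in g/day of ethanol.

Energy is taken from the composition table's `energy_kj` column, which the
loader validates against macronutrient-derived energy using the standard
food-standards conversion factors — protein 17, fat 37, carbohydrate 16.7
and alcohol 29 kJ/g, with 4.184 kJ/kcal — at a 10% tolerance. The factor
set is configuration-exposed (`energy_factors`) because index publications
rarely state which set their nutrient engine used.

Liquids are stored internally in grams; the `density_g_ml` column converts
to volume where beverage proportions are needed. Two behaviours sit outside
the FFQ item model, mirroring how such surveys are actually run: weekly SSB
volume comes from a single-item question (it contributes to the beverage
denominator but never to FFQ energy), and takeaway frequency is an ordinal
category (`0-1`, `2-3`, `4-5`, `6+` times/week).

### Degenerate records

A record with zero FFQ energy makes every percent-of-energy quantity
undefined. Rather than propagating `NaN`, the summary flags the record
(`zero_energy`) and sets %E fields to `NA`; the scorer then awards 0 to all
five moderation components and withholds their met-guideline flags. A
zero-energy diet cannot meaningfully "meet" a moderation guideline.

## Plausibility screening

Reported energy intake is screened against predicted basal metabolic rate
(BMR) using the weight-only Schofield (1985) equations, in MJ/day:

| sex    | 18–29 y         | 30–59 y         |
|--------|-----------------|-----------------|
| male   | 0.063 w + 2.896 | 0.048 w + 3.653 |
| female | 0.062 w + 2.036 | 0.034 w + 3.538 |

Age bands are half-open — age 30 falls in the 30–59 band — a convention
that must be fixed somewhere and is documented here. Ages outside [18, 60)
raise an error rather than extrapolating.

The ratio EI/BMR (EI in MJ/day) excludes a reporter when it is **strictly**
below 0.5 or strictly above 2.0; ratios of exactly 0.5 or 2.0 are retained.
These are the fixed cut-offs of the classical screen, not the
physical-activity-adjusted Goldberg bounds; the narrower fixed window is
what baseline FFQ studies in this field typically apply. Incomplete records
(any missing demographic or behaviour field) are excluded first, before the
ratio is considered; the screening log records exactly one status per input
record, so inclusion and the exclusion categories always partition the
cohort.

## The scoring rubric

The index has 11 components: the five core food groups, discretionary
foods, saturated fat, sodium, total sugars (10 points each), and water and
alcohol (5 points each), totalling 100. The component structure is fixed;
everything numeric below is a `ScoringConfig` default that can be
overridden from JSON.

**Quantity scoring** is linear below the target and flat above:
`max_pts * min(serves/target, 1)`. Targets follow the 2013 Australian
Guide to Healthy Eating adult recommendations (serves/day): vegetables
6 (male) / 5 (female), fruit 2, grain foods 6, meat & alternatives 3 / 2.5,
dairy & alternatives 2.5. Over-consumption of meat is deliberately not
penalised: no penalty is described for the index variant implemented here,
and the cap keeps the component within its maximum.

**Sub-score splits.** Vegetables and fruit each split 5 quantity + 5
variety points; a subgroup counts toward variety when at least one serve
per week is consumed (five vegetable subgroups: green, orange, legumes,
starchy, other; five fruit subgroups: pome, citrus, berry, stone,
tropical). Grains split 5 quantity + 5 wholegrain points with full credit
when more than half of grain grams are wholegrain, prorated below — the
"mostly wholegrain" guideline criterion. Dairy is treated symmetrically
with its low-fat proportion.

**Moderation scoring** interpolates linearly between a full-score and a
zero-score cut-off. Defaults, with the reasoning:

| component          | full cut    | zero cut    | basis                      |
|--------------------|-------------|-------------|----------------------------|
| saturated fat      | 10 %E       | 15 %E       | recommended <10 %E         |
| total sugars       | 15 %E       | 30 %E       | recommended <15 %E         |
| sodium             | 2300 mg/day | 4600 mg/day | upper intake level; double |
| discretionary food | 20 %E       | 60 %E       | recommended limit of 20 %E |
| alcohol            | 20 g/day    | 40 g/day    | ~2 standard drinks; double |

The full-score cuts follow the published recommendations; the zero-score
cuts are set at double the recommendation (one-and-a-half for saturated
fat, where the plausible intake range is narrower). Published HEIFA
variants do not print their full cut-off appendix, so these zero cuts are
explicit package defaults, flagged as assumptions and fully
config-exposed. Whether alcohol is better scored on g/day or %E is
similarly open; g/day is the default because guideline advice is phrased
in standard drinks, and the basis is recorded in the configuration.

**Water** scores `5 * min(water_prop / 0.5, 1)` where `water_prop` is
water's share of total beverage volume (survey water plus all FFQ
beverages, including alcoholic drinks, plus the daily-equivalent SSB
volume). A record with no beverages at all has `water_prop = 0`.

**Met-guideline flags** are the tally denominators: a quantity component is
met at or above target, a moderation component at or below its full cut,
water at or above the full-credit proportion. This "full credit = met" rule
is switchable in principle because index publications report met
percentages without printing the exact rule; the package's rule is the
natural one under its own rubric.

### Numerical behaviour

Scores are plain double arithmetic; component bounds and
`total = sum(components)` hold to 1e-9 and are enforced by a fuzzing suite
(10,000 random valid summaries) plus an independently coded brute-force
evaluator of the same rubric that must agree to 1e-9 on random summaries.
Permuting composition rows leaves scores unchanged to 1e-12 (matrix
summation order may differ at the last bit). The archetype builder places
quantities 2% above target so that `min(serves/target, 1)` can never fall
below 1 through floating-point division.

## Archetype diets

`generate_archetype()` constructs the two endpoints of the scale as real
records, which pins the scale ends exactly and gives every downstream test
a known-score fixture:

* the **perfect** diet allocates just over one weekly serve (×2.2 margin)
  of every vegetable and fruit subgroup, fills each group's remaining
  quantity with the item carrying the lowest sugar + saturated-fat +
  sodium energy burden, uses only wholegrain grain items and low-fat dairy
  items, and drinks only water. It must score exactly 100;
* the **null** diet contains only a sodium-dense discretionary item and
  spirits, scaled so sodium and alcohol sit 5–10% beyond their zero cuts,
  with the percent-of-energy moderation values then necessarily beyond
  theirs. It must score exactly 0.

Both are verified by scoring at construction time; if a composition table
cannot realise an endpoint (no wholegrain item, a missing variety subgroup,
no sodium-bearing discretionary item), construction fails with an explicit
error rather than silently truncating.

## The synthetic cohort

The simulator emulates the baseline of an overweight young-adult cohort
(n = 230, 141 female / 89 male, ages 18–35, BMI lognormal with mean 27.2
and SD 2.5 kg/m²) with the features the analyses assume:

* **Right-skewed intakes.** Group totals are lognormal with sex-specific
  arithmetic means seeded from observed group means in such cohorts
  (vegetables ≈ 117 g/day, fruit ≈ 210, grains ≈ 243, meat ≈ 190, dairy
  ≈ 337) and geometric SDs of 1.5–2. Dietary intake data are strongly
  right-skewed with SDs comparable to means, which the lognormal captures
  while staying non-negative. Parameterisation is by the arithmetic mean so
  configured values are recovered by sample means (verified within three
  simulation standard errors at n = 2000).
* **A latent diet-quality propensity** `z ~ N(0,1)` tilts group means
  multiplicatively and mean-preservingly (`exp(βz − β²/2)`): positive for
  core foods, negative for discretionary foods and alcohol. It also routes
  grain intake toward wholegrain items and dairy toward low-fat items via a
  logit-tilted share. This single factor produces the quartile gradients
  the trend analysis looks for.
* **Energy tracks requirement.** Each person's intakes scale with relative
  BMR and a shared lognormal "appetite" factor (geometric SD 1.15), both
  mean-preserving. Without this coupling, independently drawn group totals
  make reported energy nearly independent of body size and the
  plausibility screen excludes a large fraction of honest records — the
  coupling is what makes a *configured* misreporter fraction recoverable.
* **Misreporters** (default 15/230) have all amounts rescaled so EI/BMR
  lands uniformly in (0, 0.4] or [2.1, 3.0], exercising both exclusion
  tails; **incomplete records** (default 2/230) lack the takeaway response.
* **Behaviours.** Weekly SSB volume is zero for a never-consumer fraction
  (23.5%) and otherwise lognormal with a negative loading on `z` (default
  −0.6 per SD); the takeaway category is sampled from an ordered logit on
  `z` (default slope −0.8) with baseline category probabilities
  0.41/0.46/0.12/0.01.

Generation is fully deterministic given `seed` (R's default Mersenne-
Twister generator).

**What the simulator does not model:** item-level correlation beyond group
totals (no food-pairing structure), day-to-day variation (an FFQ already
integrates over a month), differential misreporting by food social
desirability, and any real survey's measurement error. Passing tests on
synthetic cohorts therefore demonstrate that the *pipeline* is correct
under the assumed structure, not that any particular real cohort satisfies
that structure.

## Cohort statistics

All inference reduces to textbook forms, each verified in the test suite
against hand-computed examples:

* **Quartiles** are rank-based with stable tie-breaking by input order and
  sizes differing by at most one (`floor(n·k/4)` boundaries). Q1 is the
  least guideline-consistent quarter.
* **Linear trend** across quartiles is the slope t-test from OLS on the
  quartile index 1–4 (the default, robust to unequal group sizes). A
  closed-form orthogonal-contrast route `(-3,-1,1,3)` with the error mean
  square taken around the fitted trend line is retained as an independent
  oracle; with balanced groups the two are algebraically identical, and the
  suite checks agreement to 1e-6 on 50 random balanced datasets. Classical
  ANOVA software sometimes pools only pure within-group error instead
  (df N−4); that variant differs whenever higher-order trend is present in
  the sample, and under imbalance the weighting of group means is itself an
  open choice — OLS-on-index is the package's primary answer.
* **Gender comparisons** use the Welch t test by default (a pooled-variance
  option exists, since publications that say only "t test" leave the
  variant open) and the Pearson chi-square without continuity correction on
  met-guideline 2×2 tables (a correction flag exists; conclusions at the
  sample sizes involved are robust to either).
* **Behaviour regressions** are simple one-predictor OLS fits of the total
  score on SSB mL/week and on the takeaway category coded 0–3; category
  frequencies are all the survey records, so equal spacing is an explicit
  coding decision, not an estimate.
* **Reference comparison** is descriptive only: cohort mean (SD) against
  fixed reference-population constants (national-survey means for adults
  aged 19–30), with no inferential test, because the constants carry no
  dispersion information. No multiple-testing adjustment is applied
  anywhere, matching standard practice for these descriptive baseline
  tables.

## Problem sizes in the test suite

The suite runs in well under a minute: fuzzing uses 10,000 random
summaries; Monte-Carlo recovery checks use cohorts of 230–2000; trend
equivalence uses 50 balanced datasets of 16–160 points. These sizes give
the property checks comfortable power while keeping the default test run
fast.

## Known limitations

* The rubric's zero-score cuts and the variety subgroup lists are package
  defaults standing in for appendix-level details that differ between
  published index variants; conclusions sensitive to them should be
  re-checked under the user's own configuration.
* The bundled composition table is a small synthetic demonstration set with
  typical per-100 g values, not an extract of any national food database;
  real analyses should supply their own table.
* Serves are computed from grams alone; mixed dishes that span food groups
  must be pre-disaggregated upstream, as is usual for FFQ nutrient engines.
* The screen uses fixed 0.5/2.0 cut-offs; physical-activity-adjusted
  Goldberg bounds are out of scope.
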