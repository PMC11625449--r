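---
title: "Food-exchange modelling of dietary fat intakes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Food-exchange modelling of dietary fat intakes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fatexchange)
```

## The problem and the model

Children's saturated-fat (SFA) intakes in many European populations sit
well above the recommended ceiling of 10 % of total energy (%TE), while
polyunsaturated-fat (PUFA) intakes often fall short of the 6 %TE floor. A
food-exchange model is a scenario analysis that asks: if the high-SFA
foods a cohort actually eats were swapped, gram for gram, for lower-SFA or
higher-unsaturated alternatives of the same kind — whole milk for low-fat
milk, butter for a high-PUFA spread, fatty meat cuts for lean grilled cuts
of the same product, chocolate biscuits for plain ones — how would the
dietary fat profile and compliance with fat recommendations change? The
fat removed this way is *exchangeable*: not intrinsic to the food's
identity, so the swap disturbs dietary habits minimally.

`fatexchange` implements this analysis as a pipeline over three inputs: a
food composition table (per-100 g nutrients for each food), multi-day food
diaries (one row per consumption event), and a participant roster. The
stages are:

1. **Intakes.** For each participant, mean daily intake of each nutrient
   is the sum of `amount_g / 100 ×` the food's per-100 g vector, divided
   by the number of distinct recorded days. %TE uses fixed energy factors
   (below). The same sum partitioned by food category gives per-category
   subtotals, which by construction add back up to the daily totals.
2. **Determinants.** Participants are ranked on SFA %TE and split into
   tertiles; per-category contributions are compared across the thirds
   with one-way ANOVA, Bonferroni-adjusted over the family of categories,
   and a Scheffé post hoc rendered as compact letter groupings.
3. **Exchange.** An ordered rule set maps selected foods to replacements;
   each matched diary entry keeps its participant, day and grams and only
   the food code changes. Rules are first-match-wins and applied in a
   single pass, and a rule never selects its own replacement, so applying
   a rule set twice is exactly the same as applying it once.
4. **Comparison.** Baseline and modelled intakes are compared per
   nutrient with paired t tests (Bonferroni-adjusted across the endpoint
   family), and per food category as the relative change in percentage
   contribution. Categories in which *every* consumed food is matched by a
   rule lose their whole contribution: the relative change is exactly
   −100 %, a structural property of complete replacement rather than an
   empirical estimate.
5. **Compliance.** The percentage of (survey-weighted) participants
   meeting each fat recommendation, per arm, with inclusive bounds.

## Parameters that matter

* **Energy factors** (`energy_factors()`): all fat classes 9 kcal/g,
  protein 4, carbohydrate and sugars 3.75 — the UK convention matching the
  British/Irish composition-table lineage these surveys use. They are an
  argument, not a constant, because other tables use 4.0 kcal/g
  carbohydrate by difference.
* **Contribution method**: the default `population_proportion` (ratio of
  weighted sums) is the convention of the Irish national survey series;
  `mean_of_ratios` (average of per-participant shares) is provided for
  sensitivity analysis. The two agree exactly when all participants share
  one diet, and can differ otherwise because the former weights
  high-consuming participants more.
* **Tertile contribution measure**: `share` (percent of the participant's
  own nutrient intake from a category) or `pct_te` (the category's direct
  %TE); survey tables are printed under both readings, so both are
  implemented and `share` is the default.
* **α = 0.05** throughout; the Bonferroni families default to the rows of
  the table being reported (categories for the tertile table, nutrient
  endpoints for the comparison table) and are configurable because a
  larger tested family can legitimately exceed the reported subset.
* **Recommendations**: SFA ≤ 10 %TE and PUFA ≥ 6 %TE (UK/Irish), EPA+DHA
  ≥ 250 mg/d (EFSA). Compliance is also reported for total fat, MUFA and
  trans fat, whose child-specific numeric cut-offs are not uniformly
  published; the shipped values (≤ 35, ≥ 10, ≤ 2 %TE) are flagged
  `implementer_default` in `default_recommendation_set()` and should be
  replaced where it matters. Bounds are inclusive because the
  recommendations print `≤`/`≥`.
* **Vitamin E is stored and reported in mg/d.** Published intake tables
  occasionally print vitamin E in µg/d at values that are only plausible
  as mg/d; this package takes one unit and never silently rescales user
  data.

## The synthetic cohort generator

National food-consumption surveys are rarely deposited, so the package
ships a seeded generator whose defaults encode the study conditions the
analysis assumes: 600 children (300 boys, 300 girls) aged 5–12, each with
4 consecutive diary days starting on a weekday chosen so at least one
weekend day is always included, 26 food categories with at least two foods
each, and a paired lower-SFA counterpart for every exchangeable food.

Each child-day is built from a meal-slot plan (milk at breakfast, bread
and spread, a main protein, starch, snacks, and so on) with occurrence
probabilities and log-normal portions whose medians scale with age
(multiplier 0.80–1.05 across ages 5–12, daily energy landing near
1450–1500 kcal/d, the realistic range for this age span). A child-level
fat-preference latent variable shifts, on the logit scale, the probability
of choosing the full-fat variant in the milk, cheese, spread, meat and
biscuit slots. This single construct produces both the between-child
spread of SFA %TE and the gradient the tertile analysis expects: children
in the highest SFA tertile drink more whole milk and eat more butter *by
construction*, because the same latent variable drives both.

Calibration: a global logit shift applied to every full-fat propensity is
tuned by bisection (deterministic, at most 30 iterations) until the
realised cohort mean SFA %TE is within 0.05 of the 14 %TE target. All
random draws are made once, before calibration; the shift only moves
choice thresholds, so the procedure is exactly reproducible under a seed
and bounded in time. With the default dispersion the tertile means land
near 11.3 / 14.0 / 16.6 %TE. An unattainable target (outside the range the
food list can span) raises a calibration error rather than returning a
miscalibrated cohort.

What the generator does **not** emulate: day-of-week and seasonal
consumption structure beyond the weekend flag, within-food brand
variability, correlated meal composition (chips with sausages), energy
misreporting, or the demographic weighting structure of a real survey (a
weight column exists but defaults to 1). Passing tests on synthetic data
therefore demonstrate the correctness and invariants of the pipeline —
conservation, directionality, calibration — not empirical claims about any
real cohort's intake distributions.

## Numerical and design choices

* **Tertile ties.** Ranking is a stable sort by (value, participant id);
  tied values may be split across a boundary, with a warning. This keeps
  the assignment deterministic and order-invariant; the alternative
  (moving whole tie groups) makes group sizes data-dependent.
* **ANOVA and Scheffé** are computed from closed-form sums of squares so
  the Scheffé criterion — contrast mean square against
  `(k−1)·F_crit·MSW·(1/nᵢ+1/nⱼ)` — can reuse the ANOVA's `MSW` directly
  and be checked against exhaustive pairwise evaluation. Zero
  within-group variance is reported as a no-difference result when means
  are equal, and as an infinite F when they are not, never as `NaN`.
* **Paired t** delegates to `stats::t.test` except in the degenerate
  zero-variance cases, which are flagged explicitly (`no-change`,
  `zero-variance`).
* **Relative contribution changes** are computed on unrounded
  proportions; rounding to display precision before dividing visibly
  distorts relative changes, so display rounding happens only in the
  emitted `display` columns.
* **Exchange matching** works at the level of category plus an optional
  description pattern, because real exchange lists cut across category
  boundaries ("all biscuits including cookies" but not all snacks); meats
  use a per-source map so each fatty cut is replaced by the lean/grilled
  variant of the *same* product. Only the cheese *category* is exchanged,
  not cheese inside composite dishes — composites are data entries of
  their own category and the package does not decompose recipes.
* **Partial diaries** divide by the number of distinct recorded days
  rather than a hard-coded 4, so a 3-day diary yields a 3-day mean
  instead of a deflated 4-day one.

## Worked example

```{r example, eval = FALSE}
library(fatexchange)

composition <- generate_composition(seed = 1)
cohort <- generate_cohort(cohort_spec(n_children = 600, seed = 1), composition)
baseline <- compute_intakes(cohort$diaries, composition, cohort$roster)

rules <- default_rule_set(composition)
modelled <- apply_exchanges(cohort$diaries, rules, composition)
model <- compute_intakes(modelled$diaries, composition, cohort$roster)

build_comparison_table(baseline, model)
contribution_change_table(baseline, model)
rbind(
  assess_compliance(baseline, arm = "baseline"),
  assess_compliance(model, arm = "model")
)
```

The same run, end to end with all report CSVs, is
`run_pipeline(run_config(out_dir, synthetic_spec = cohort_spec(), seed = 1))`.

## Known limitations

* The exchange model changes food *types* only; portion reduction,
  elimination and energy rebalancing are out of scope by design, so total
  energy drifts slightly downward when replacements are less
  energy-dense.
* No usual-intake deconvolution (within-person day-to-day variance is not
  removed before compliance is assessed); 4-day means are compared to the
  recommendations directly.
* No energy-misreporting screening (Goldberg-type cut-offs).
* Statistical inference on synthetic cohorts describes the generator, not
  any real population; the package's value on real data is the pipeline,
  whose correctness properties (conservation, idempotence, directionality,
  oracle-checked statistics) are what the test suite establishes.
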