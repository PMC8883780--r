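---
title: "Food-replacement scenarios and habitual protein intake: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Food-replacement scenarios and habitual protein intake: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietsim)
```

## The problem

Community-dwelling older adults frequently fall short of the protein intake
of 1.0 g per kg body weight per day recommended for healthy ageing, and a
natural question for nutrition policy is how far that gap could be closed by
subtle substitutions within the existing diet — swapping a habitual food for
a comparable but protein-richer product from the same food group — rather
than by changing the dietary pattern itself. `dietsim` models exactly this:
it takes two-day 24-hour-recall survey data (who ate what, how much, on
which recall day), rewrites consumption records according to configurable
replacement scenarios, and quantifies the effect on the population
distribution of habitual protein intake.

Two statistical components carry the package: the **replacement engine**
(a deterministic rewriting of consumption records under a percentile rule)
and the **habitual-intake estimator** (a measurement-error model that strips
day-to-day within-person variance out of the short-term intake
distribution). A **synthetic-survey generator** provides data with the
relevant statistical structure so that every stage is testable without
access to survey microdata, which is typically not redistributable.

## The replacement rule

For each food group named by a scenario, the engine computes the 75th
percentile (P75) of the protein content per 100 g over the distinct food
items of that group in the composition table. Every consumption record of an
*eligible* participant whose food belongs to the group and has protein
content strictly below P75 is rewritten to the group's single designated
alternative food; an item exactly at P75 is never replaced, and the
alternative's own protein content must be strictly above P75. Substitution
is on the basis of weight consumed: grams are unchanged, and all nutrients
of the record now come from the alternative's composition row.

Eligibility restricts replacement to participants whose baseline 2-day mean
protein intake is strictly below a cut-off (default 1.0 g/kg BW/d,
computed as the mean over the two recall days of
$\sum_r \mathrm{grams}_r \cdot \mathrm{protein}_r / 100 / \mathrm{BW}$).
Participants at or above the cut-off, and participants excluded for unknown
body weight, are left bit-identical. Eligibility is frozen at baseline:
it is evaluated once on the original survey and never re-evaluated while
records are rewritten, so replacements are one-pass and never cascade.
Because the thresholds are computed from the (unchanged) composition table
and every alternative sits above its group's P75, applying a scenario to its
own output makes no further replacements.

Several choices here were genuinely open and are worth recording:

* **P75 basis.** The percentile is taken over each distinct food item of the
  group once, unweighted by how much or how often it is consumed; this is the
  simplest reading of a percentile "of the protein contents in that food
  group". A consumption-restricted dialect (`p75_basis = "consumption"`,
  percentile over only the items actually appearing in the survey's records)
  is provided because composition databases contain many rarely eaten items
  and an analyst may prefer the consumed set. The default is the full
  composition-table set.
* **Percentile definition.** Linear interpolation between order statistics at
  position $1 + 0.75(n-1)$ — the common statistical default
  (`quantile(..., type = 7)`) — verified in the tests against an independent
  sort-and-interpolate oracle. With a single item the percentile is that
  item's value, so a one-item group can never generate a replacement
  (nothing is strictly below it); likewise a group whose items all share one
  protein value.
* **Strictness.** Strict inequalities on both sides: replaced items are
  strictly below P75, alternatives strictly above. Boundary items are
  untouched. Records with zero grams represent "nothing actually consumed"
  and are never substituted, which keeps every logged replacement's protein
  delta strictly positive.

Every substitution is logged (participant, day, group, from/to food, grams,
protein delta in g), and the log is the basis for the two summary
operations: replacement counts per group, and the **contribution ranking** —
per group, the analysis-weighted population mean of the per-participant
summed protein delta divided by 2 (the two recall days), in g/d over all
non-excluded participants. Contributions are measured on the g/d scale, not
g/kg, matching how group-level effects are conventionally reported next to
population means; ties are broken by group label so the ranking is
deterministic.

The **combined-scenario rule** builds a third scenario from two others: take
the top-*k* groups of the second scenario's contribution ranking with that
scenario's alternatives, then walk the first scenario's ranking from the
top, skipping groups already selected, until *k* more are added with the
first scenario's alternatives — exactly 2*k* groups. This reproduces the
published practice of combining the most effective food groups of a
protein-rich and a protein-enriched scenario while resolving duplicates by
falling through to the next-ranked group.

## The habitual-intake model

Two recall days per person are too few to read off anyone's long-run
("habitual", "usual") intake: the distribution of 2-day means is wider than
the distribution of habitual intakes because each mean still carries half of
the within-person day-to-day variance. The estimator is a one-part
shrinkage model in the tradition of usual-intake software such as SPADE and
the NCI method (re-implemented here in simplified form, labelled
SPADE-style rather than SPADE-exact — the original's age-spline modelling
and proprietary internals are deliberately out of scope). Protein is
consumed daily by essentially everyone, so no episodic (two-part)
component is needed.

1. **Transform.** A Box-Cox exponent $\lambda$ is chosen from the grid $0,
   0.1, \ldots, 1$ by maximising the profile log-likelihood of the pooled
   daily values; the shift is 0 when all values are positive, else half the
   smallest positive value, so zero-intake days remain representable. The
   grid pick is tested against an independent profile-likelihood oracle.
   Note that $\lambda$ is only weakly identified when intakes sit far from
   zero relative to their spread (the transform is then nearly affine over
   the data range); this is a property of the likelihood, not of the
   implementation, and is harmless — near-equivalent transforms give
   near-identical habitual distributions.
2. **Variance components.** On the transformed scale, with person means
   $m_i$ over $n_i$ days: $\hat\sigma^2_w$ is the pooled within-person
   variance (for the balanced 2-day design, the mean of $(d_{i1} -
   d_{i2})^2/2$), and $\hat\sigma^2_b = \max(0, \mathrm{var}(m_i) -
   \hat\sigma^2_w \overline{1/n_i})$. Method-of-moments rather than
   iterative ML: the estimators are closed-form, exact for the balanced
   design, and trivially auditable; the tests cross-check them against an
   REML mixed-model fit.
3. **Shrinkage.** $t_i = \mu + c_i (m_i - \mu)$ with $c_i =
   \sqrt{\sigma^2_b / (\sigma^2_b + \sigma^2_w / n_i)}$. The square root
   makes the variance of the $t_i$ equal $\sigma^2_b$ — the contraction
   that distribution estimation needs (the familiar BLUP factor without the
   square root would over-shrink the spread). When $\sigma^2_b = 0$
   everything collapses to $\mu$; when $\sigma^2_w = 0$ the data are
   noise-free and the person means pass through unchanged.
4. **Back-transformation.** The habitual value on the original scale is
   $\mathbb{E}\,[\,g^{-1}(t_i + e)\,]$, $e \sim N(0, \sigma^2_w)$, by
   9-point Gauss–Hermite quadrature (standard order for this integral;
   validated in the tests against the $\lambda = 0$ lognormal-mean closed
   form at $10^{-6}$ relative and a $10^6$-draw Monte-Carlo integral at
   $10^{-3}$ relative). Arguments outside the Box-Cox domain are clipped to
   the boundary, the shift is subtracted afterwards and results floored at
   0. This bias correction is what makes the weighted mean of habitual
   estimates track the mean of the observed person means; a plain inverse
   transform fails that property and is regression-tested as failing it.

The habitual distribution is always estimated on the full non-excluded
population — replacements touch only participants below the cut-off, but the
population distribution, its percentiles and the fraction below the cut-off
are statements about everyone. Survey weighting enters as participant-level
analysis weights supplied with the data (the package does not construct
weights by raking; that is a property of the survey design, not of this
analysis). Two dialects are provided for the per-kg cut-off, because either
could be used upstream: estimate habitual g/d and divide by body weight at
the comparison (default), or estimate directly on g/kg daily values
(`perkg_mode = "per_kg"`).

## What the synthetic generator emulates

`generate_survey()` produces a survey with the structure the analysis
relies on: a nine-group food catalog (bread; yoghurt, cream desserts and
pudding; potatoes, vegetables and legumes; non-alcoholic beverages and
milk; soups; savoury spreads, sweet spreads and cheese; meat and fish;
cereals; fruit) with lognormal per-item protein contents and one
protein-enriched item per group; normal body weights (mean 75 kg, sd 12 kg,
truncated at 35 kg); mean-one lognormal analysis weights; and exactly two
recall days per participant. Consumption is simulated per group and day: a
Bernoulli indicator with a person-specific probability (Beta-distributed
around the group rate, concentration 10), a uniformly chosen item, and a
lognormal portion combining a group-level median, a person-level propensity
(log-sd 0.25) and day-level noise (log-sd 0.35). Day-level indicators plus
day-level portion noise are the two within-person variance sources the
habitual estimator must remove; the person-level terms create the
between-person variance it must keep. Lognormal forms were chosen because
intake quantities are non-negative and right-skewed; group-level protein
medians and portion sizes are round food-table-like values.

The defining calibration: a single global portion scalar is found by
bisection (on the log scale, tolerance 0.005 on the fraction, at most 40
iterations — the fraction is provably monotone in the scalar) such that
52.9 % of included participants have a 2-day mean protein intake below
1.0 g/kg BW/d, the share reported for Dutch community-dwelling older
adults. One interpretable knob, applied once at generation time.

What the generator does **not** emulate: marginal distributions of
nutrients other than protein (energy is a crude linear function of protein,
present so nutrient summaries have a second column), day-of-week and
seasonal structure, correlated food choices within a day, portion-size
coding conventions, or any attempt to match a real composition database
item for item. Passing tests therefore demonstrate that the algorithms are
correct on data with the assumed variance structure — not that the
package's numbers reproduce any particular national survey, whose microdata
the scenarios would need as input.

`generate_known_habitual_cohort()` is the parameter-recovery harness for
the estimator: true habitual values $H_i$ are lognormal and observed days
are $H_i$ times mean-one multiplicative noise, so the truth is known and
the estimated within-person variance, shrinkage contraction and
fraction-below-cutoff can be compared against it (the test suite does this
at $n = 5000$ with habitual log-sd 0.25 and within log-sd 0.35, recovering
$\sigma^2_w$ within 5 % and the fraction below the true median within
0.02).

## Numerical and interface choices

* Exactly two declared recall days per included participant; a day with
  nothing consumed is a declared day with zero records, keeping "no data"
  distinct from "zero intake".
* Protein content is mandatory for every composition item; other nutrients
  are optional per item and an absent nutrient is an error when requested,
  never a silent zero — silent zeros would corrupt population nutrient
  summaries invisibly.
* Weighted summary statistics use weights normalised to sum 1; the weighted
  sd is the square root of the weighted second central moment. Analyses are
  invariant to person ordering and to uniform rescaling of weights.
* Survey CSVs are written with 17 significant digits, so a write/read round
  trip reproduces every double exactly and repeated runs are byte-identical.
* The whole pipeline after generation is deterministic: scenario
  application, contribution ranking (lexicographic tie-break), habitual
  estimation and all reports are pure functions of their inputs.
* Problem sizes in the test suite were chosen to make the statistical
  assertions sharp at desk scale: 200 random small surveys for the
  brute-force equivalence check, 1000 random vectors for the percentile
  oracle, $n = 5000$ for parameter recovery, $n \approx 730$ (the size of
  the motivating survey) for the end-to-end scenario run.

## Limitations

* The replacement model is purely compositional: no satiety or energy
  compensation, no portion re-optimisation, no acceptability or price
  modelling. Replacing a whole food group by a single alternative
  exaggerates effects on nutrients concentrated in that alternative.
* The habitual estimator is one-part and covariate-free; episodically
  consumed nutrients and age-trend modelling would need a two-part model
  and covariate splines. Uncertainty intervals (e.g. bootstrap) are not
  provided.
* The generator's calibration matches one marginal quantity (the fraction
  below the cut-off); it is not a synthetic twin of any real survey.
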