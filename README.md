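# dietsim

Simulation of food-replacement scenarios in two-day 24-hour-recall dietary
survey data, with estimation of the population distribution of habitual
protein intake.

Roughly half of community-dwelling older adults do not reach the protein
intake of 1.0 g per kg body weight per day recommended for healthy ageing.
One candidate intervention keeps the dietary pattern intact and only swaps
commonly consumed foods for comparable, protein-richer products from the
same food group. `dietsim` is for nutrition researchers who want to quantify
what such substitution scenarios would do to a population's protein intake
before testing them in practice.

## What it computes

**Replacement engine.** Within each scenario food group, let P75 be the 75th
percentile (linear interpolation) of protein content per 100 g over the
group's distinct food items. For every participant whose baseline 2-day mean
intake satisfies

&nbsp;&nbsp;&nbsp;&nbsp;½ Σ_d Σ_r grams_r · protein_r / 100 / BW &lt; 1.0 g/kg BW/d,

each consumed food with protein content strictly below P75 is replaced, gram
for gram, by the group's designated alternative (whose content must be
strictly above P75). Participants at or above the cut-off are untouched.
Every substitution is logged; groups are ranked by the analysis-weighted
population mean protein increase they contribute (g/d), and a combined
scenario can be derived from the top-3 groups of two scenarios with a
duplicate-skipping walk.

**Habitual-intake estimator.** Observed 2-day means overstate the spread of
long-run intakes because they retain within-person day-to-day variance. The
one-part estimator (in the tradition of SPADE and the NCI usual-intake
method) Box-Cox-transforms pooled daily intakes (λ chosen by profile
likelihood on a 0–1 grid), separates between- and within-person variance by
closed-form method of moments (balanced 2-day design: σ²_w = mean (d₁−d₂)²/2,
σ²_b = var(means) − σ²_w/2), shrinks person means by
c = √(σ²_b / (σ²_b + σ²_w/n)), and back-transforms with the bias correction
E[g⁻¹(t + e)], e ~ N(0, σ²_w), by 9-point Gauss–Hermite quadrature. From the
resulting distribution: weighted means, percentiles, and the fraction below
the cut-off.

**Synthetic-survey generator.** A seeded generator emulating the structure
of a national food-consumption survey of older adults (nine food groups, two
non-consecutive recall days, between- and within-person intake variance),
calibrated by bisection of a single global portion scalar so that 52.9 % of
participants fall below 1.0 g/kg BW/d at baseline. It makes the full
pipeline reproducible and testable without restricted survey microdata.

## Worked example

```r
library(dietsim)

sv <- generate_survey(generator_config(n_participants = 739, seed = 1,
                                       n_missing_bw = 12L))
sv
#> <diet_survey> 739 participants (12 excluded: unknown body weight), 9213 consumption records, 75 foods in 9 groups

groups <- food_groups(sv$composition)
s1 <- build_enrichment_scenario(sv$composition, groups, style = "rich",
                                scenario_id = "protein-rich")
s2 <- build_enrichment_scenario(sv$composition, groups[1:6],
                                style = "enriched",
                                scenario_id = "protein-enriched")
study <- run_replacement_study(sv, list(s1, s2))
study
#> <replacement_study> cutoff 1 g/kg BW/d
#>   participants: 739 total, 12 excluded (unknown BW), 727 analyzed, 384 eligible (< cutoff)
#>   original: habitual mean 74.9 g/d (1.04 g/kg BW/d), 50.9% meeting cutoff
#>   protein-rich: 3549 replacements, habitual mean 90.3 g/d (1.25 g/kg BW/d), 89.3% meeting cutoff
#>   protein-enriched: 2620 replacements, habitual mean 118.1 g/d (1.61 g/kg BW/d), 99.9% meeting cutoff
#>   combined: 2440 replacements, habitual mean 113.5 g/d (1.56 g/kg BW/d), 99.8% meeting cutoff
```

Reading this: of 739 simulated participants, 12 lack a body weight and are
excluded; 384 of the remaining 727 sit below the cut-off and are eligible
for replacement. Replacing below-P75 foods raises the habitual mean from
74.9 g/d (1.04 g/kg BW/d) to 90.3–118.1 g/d and lifts the share meeting the
recommendation from 50.9 % to 89–100 %, while the records of the 343
participants already at or above the cut-off are bit-identical before and
after. Which food groups drive a scenario:

```r
head(group_contributions(study$scenarios[["protein-rich"]]$result), 3)
#>                              group mean_protein_increase_g_d
#> 1 non-alcoholic beverages and milk                  5.011117
#> 2                            bread                  2.824390
#> 3                    meat and fish                  1.870919
```

Real survey data enter through three CSVs (composition, participants,
records; see `?read_survey`) plus YAML/JSON scenario files (`?read_scenario`);
small examples ship under `inst/extdata/`. A thin command-line wrapper with
`simulate`, `run`, `habitual` and `derive-combined` subcommands is installed
at `system.file("cli", "dietsim", package = "dietsim")`.

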