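# adrules

Association-rule mining of **family and school risk/protective factor
combinations for adolescent depression**, built for researchers in
adolescent mental-health epidemiology who work with item-level
questionnaire data (psychometric scales plus demographic and
school-resource flags) and want combination-level — rather than
single-factor — descriptions of who is at risk.

## What it computes

Each respondent becomes a *transaction*: a set of discrete items derived
from their survey record. Scale totals (family cohesion, family conflict,
financial strain, teacher/peer/autonomy support) are discretized at
nearest-rank quartiles — risk at total ≤ P25 or ≥ P75 depending on the
construct's direction, protective at the mirrored criteria — joined by
binary family/school flags, demographic level items, and exactly one
outcome item: `depression` if the 18-item children's depression self-rating
total is ≥ 15, else `nondepression`.

Rules X ⇒ Y with a fixed consequent are mined by a from-scratch levelwise
Apriori search and evaluated with

- support(X ⇒ Y) = P(X ∪ {Y})
- confidence(X ⇒ Y) = P(Y | X)
- lift(X ⇒ Y) = P(Y | X) / P(Y)

keeping rules with support ≥ min_sup, confidence ≥ min_conf (inclusive) and
lift > 1, sorted by descending confidence. Analyses are stratified by
gender, school stage, and left-behind status, with the stratifier excluded
from its own item universe. Defaults: risk analyses 5% support / 70%
confidence (80% for the left-behind stratifier); protective analyses
20% / 80%.

Because the original survey is not deposited, the package also ships

- a **calibrated synthetic cohort generator** (`generate_participants()`)
  reproducing the study's margins (n = 2445, 52.8% girls, 35.6%
  left-behind, ...) and reliabilities (per-scale Cronbach's alpha within
  ±0.05 of 0.82/0.63/0.80/0.81/0.76/0.84), with a planted logistic
  factor→depression dependence for end-to-end validation;
- an **exhaustive enumeration oracle** (`brute_force_frequent_itemsets()`)
  and a **Monte-Carlo rule oracle** (`planted_rule_oracle()`) that check
  the miner by independent routes;
- **verbatim transcriptions of the six published rule tables**
  (`load_paper_fixtures()`) with a consistency checker
  (`check_paper_tables()`) that recomputes their counts, ranges and
  implied base rates and flags the source's internal discrepancies.

## Worked example

```r
library(adrules)
cohort   <- generate_participants(default_config(), seed = 1)
complete <- filter_complete_cases(cohort)
#> complete-case filter: 2129 of 2445 record(s) retained (316 dropped)
scored   <- score_scales(complete)
risk     <- run_stratified_analysis(scored, analysis_config("risk"),
                                    stratifiers = "gender")
#> risk.gender.female: 1150 records -> 1150 transactions -> 3 rule(s)
#> risk.gender.male: 979 records -> 979 transactions -> 1 rule(s)

risk$tables[["risk.gender.female"]]$rules
#> Association rules: 3 rule(s), consequent 'depression'
#>   thresholds: support >= 0.05, confidence >= 0.7, lift > 1
#>   LHS                                                         support
#> 1 high family conflict, low family cohesion, low peer support 5.04%
#> 2 high family conflict, low family cohesion                   8.43%
#> 3 high family conflict, low teacher support                   6.52%
#>   confidence lift
#> 1 86.57%     2.81
#> 2 75.19%     2.44
#> 3 70.75%     2.30
```

Reading row 1: 5.04% of the girls in this synthetic cohort carry {high
family conflict, low family cohesion, low peer support} *and* screen
positive for depression; among girls carrying that combination, 86.57% are
depressed — 2.81 times the girls' overall depression rate. The planted
family-adversity interaction is recovered as the top rules, with the
single factors alone never passing the confidence threshold.

```r
summary(risk$tables[["risk.gender.female"]]$rules)
#> Rules: 3  (3-item: 2, 4-item: 1)
#>   support 5.04%-8.43%  confidence 70.75%-86.57%  lift 2.30-2.81
#>   implied base rate: mean 30.78%, CV 0.000%
```

The implied base rate (confidence/lift) is constant within a stratum by
the lift identity — a diagnostic this package also applies to the packaged
published tables.

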