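---
title: "Mining family and school risk/protective factor combinations for adolescent depression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining family and school risk/protective factor combinations for adolescent depression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis this package implements

Adolescent depression is associated with many family factors (cohesion,
conflict, economic strain, family structure, parental education, separation
from parents) and school factors (teacher, peer and autonomy support,
mental-health education resources). Single-factor analyses miss how these
factors *combine*. This package implements the combination-oriented
alternative: discretize every factor into a binary risk (or protective)
indicator, attach a depression/nondepression outcome item to each
respondent, and mine association rules

\[ X \Rightarrow Y, \qquad X \subset I,\; Y \in \{\text{depression},
\text{nondepression}\},\; X \cap \{Y\} = \emptyset \]

with the Apriori algorithm, where each respondent contributes one
transaction (their item set) and rules are evaluated by

* **support** \(= P(X \cup \{Y\})\), the fraction of respondents carrying
  both the factor combination and the outcome;
* **confidence** \(= P(Y \mid X)\), the outcome rate among carriers of the
  combination;
* **lift** \(= P(Y \mid X) / P(Y)\), confidence relative to the outcome's
  base rate; lift > 1 means positive association.

Analyses are stratified: rules are mined separately for girls and boys, for
primary-school (grades 5–6) and middle-school (grades 7–9) students, and for
left-behind and non-left-behind adolescents (children separated from at
least one parent for six months or more because the parents work away from
home). The stratifying variable is excluded from its own analysis's item
universe: within a stratum its level item would have 100% support and lift
exactly 1, a tautology the published tables never show.

```{r, eval = FALSE}
library(adrules)
cohort <- generate_participants(default_config(), seed = 1)
scored <- score_scales(filter_complete_cases(cohort))
risk <- run_stratified_analysis(scored, analysis_config("risk"))
summary(risk$tables[["risk.gender.female"]]$rules)
```

## Measures and scoring

Six instruments are scored by plain summation of item responses (no
reverse-keyed items are assumed):

| scale | items | response range | total range | reliability target |
|---|---|---|---|---|
| family cohesion | 16 | 1–5 | 16–80 | 0.82 |
| family conflict | 9 | 0–1 | 0–9 | 0.63 |
| teacher support | 7 | 1–4 | 7–28 | 0.80 |
| peer support | 13 | 1–4 | 13–52 | 0.81 |
| autonomy support | 5 | 1–4 | 5–20 | 0.76 |
| financial strain | 5 | 1–4 | 5–20 | 0.80 |
| depression (DSRSC) | 18 | 0–2 | 0–36 | 0.84 |

The financial-strain block length is a codebook convention — the source
survey does not state its item count, and only its quartiles matter
downstream — so it is fixed at 5 items scored 1–4 (configurable through the
codebook); its reliability target (0.80) is likewise a package convention.
Reliability is checked with Cronbach's alpha, computed with sample
(\(n-1\)) variances:
\(\alpha = \frac{k}{k-1}\bigl(1 - \sum_i s_i^2 / s_T^2\bigr)\).
Missing data are handled by complete-case analysis only: any respondent
with a missing or out-of-range item response on any analysed variable is
dropped, with counts logged. No imputation is attempted.

## Discretization

Quartile-scored variables use nearest-rank percentiles computed on the full
analytic sample: the \(q\)-th percentile is the value at position
\(\lceil qn \rceil\) of the sorted totals. Criteria are inclusive exactly as
the instrument grid states: in risk mode, cohesion and the three support
scales flag at total \(\le P_{25}\), conflict and financial strain at
\(\ge P_{75}\); protective mode mirrors them (\(\ge P_{75}\) cohesion and
support, \(\le P_{25}\) conflict and strain). Three decisions deserve note:

* **Protective support criteria.** The printed criteria grid repeats
  "\(\le\) 25th percentile" in both the risk and protective columns for
  teacher/peer/autonomy support; the accompanying text says protective
  resources are *above the 75th*. The implementation follows the text; the
  grid entry is treated as a typo.
* **Cutoff scope.** Whether the published quartiles were computed pooled or
  within stratum is not stated. Pooled is the default
  (`analysis_config(cutoff_scope = "pooled")`), because the publication
  presents one criteria grid, not per-stratum grids; `"stratum"` is
  available as a switch.
* **Degenerate scales.** A scale whose \(P_{25} = P_{75}\) (possible for
  very coarse or constant totals) contributes no items, and the suppression
  is logged; otherwise a respondent could be simultaneously "low" and
  "high" on one variable.

Binary variables map directly: non-intact family structure, left-behind
status ("separation from parents" in risk mode, "non-left-behind children"
in protective mode — one underlying variable, which is also the excluded
variable of the left-behind-stratified analyses), low parental education,
and absence (or presence) of psychology courses, school counselors, and
counseling rooms. Both gender levels, both school-stage levels and the
three academic-ranking levels are always added as polarity-free items:
mining decides which survive the thresholds. The depression outcome item is
`"depression"` when the DSRSC total is \(\ge 15\) (inclusive — the source
states a "cutoff of 15" without specifying inclusivity, and an inclusive
comparison matches the scale's conventional use), else `"nondepression"`;
exactly one outcome item per transaction.

## Mining

`apriori_frequent_itemsets()` is a from-scratch levelwise search: frequent
1-itemsets; candidate \(k\)-itemsets by joining frequent \((k-1)\)-itemsets
sharing a \((k-2)\)-prefix under a fixed C-collation lexicographic item
order (locale-independent, hence deterministic across machines); candidates
with any infrequent \((k-1)\)-subset pruned before counting; one counting
pass per level on a one-hot indicator matrix. Rules are generated only for
the fixed consequent: every frequent itemset \(S \ni Y\), \(|S| \ge 2\),
yields \((S \setminus \{Y\}) \Rightarrow Y\).

Threshold conventions: support \(\ge\) `min_sup` applied to the support of
\(X \cup \{Y\}\) with the stratum's transaction count as denominator;
confidence \(\ge\) `min_conf` (both inclusive, mirroring "greater than or
equal to the set threshold"); lift strictly \(>\) `min_lift` (default 1).
Whether the source's confidence comparison was inclusive is not stated;
inclusive is assumed. Metrics are kept at full precision on integer counts;
rounding (half-up, 2 decimals, matching the printed tables) happens only in
`write_report()`. Rule tables are sorted by confidence descending, ties by
support descending, then by lexicographic antecedent — a total,
deterministic order. No maximum itemset size is imposed by default.

Default thresholds per analysis: risk mode 5% support with 70% confidence
for the gender and age-group analyses and 80% for the left-behind analysis;
protective mode 20% support and 80% confidence throughout; lift > 1
everywhere.

Correctness is guarded two ways: `brute_force_frequent_itemsets()`
enumerates every subset of the catalog (guarded at 20 items) and must agree
exactly with the levelwise search on randomized instances, and the identity
lift = confidence / base-rate must hold exactly on the integer counts. The
`implied_base_rate_check()` diagnostic inverts that identity: within one
stratum every rule's confidence/lift ratio estimates \(P(Y)\) and must be
nearly constant — a useful consistency check on transcribed tables.

## The synthetic cohort generator

The survey underlying the published tables is not deposited, so the package
ships a generator that emulates the study situation well enough to exercise
and test every downstream stage. Defaults reproduce the reported margins:
n = 2445 complete cases (recruitment 2800 with ~12.7% row-level
missingness), 52.8% girls, 1281/2445 middle-school students with the
reported grade split, 35.6% left-behind. Margins not reported (intact
family structure 85%, low parental education 35%, ranking 25/55/20,
resource coverage 60/50/55%) are fixed at values typical of rural Chinese
county samples. Demographics are drawn independently — no
gender-by-stage-by-left-behind dependence is modelled.

Item responses arise from a Gaussian latent hierarchy: respondent-level
construct scores are multivariate normal with a configurable cross-scale
correlation matrix; each scale's items are thresholded compound-symmetric
latents around the construct score. The inter-item correlation is
calibrated from the reliability target by inverting
\(\alpha = k\rho/(1 + (k-1)\rho)\) — e.g. cohesion
\(\rho = 0.82/(16 - 15 \times 0.82) \approx 0.2216\) — and then correcting
for discretization attenuation: thresholding a standard normal into ordered
categories multiplies inter-item Pearson correlation by roughly
\(\lambda^2\), where \(\lambda\) is the latent–score correlation implied by
the threshold set. Without that correction the coarse scales fall far short
(the dichotomous conflict items would realize \(\alpha \approx 0.50\)
against a 0.63 target). The acceptance suite verifies all seven scale
alphas within ±0.05 of target at n = 2445 averaged over 20 seeds.

Depression is planted, not emergent: binary status is drawn from a logistic
model on the cohort's *own* discretized risk indicators (so the dependence
is expressed on exactly the variables the miner sees), with log-odds 0.9
for low family cohesion and high family conflict, 0.6 for their
interaction, 0.5 for low peer and low teacher support, and intercept −1.72.
The intercept and the family↔school-support block of the cross-scale
correlation matrix were calibrated once, jointly, so the default cohort
satisfies the package's stated operating conditions — overall prevalence
≈ 0.30 (between the ≈25.7% and ≈34.1% base rates implied by the published
gender tables) and a lift for {low cohesion, high conflict} ⇒ depression
near the published 2.4–3.0 range — and then frozen. These conditions are
mutually tight: confidence = lift × prevalence, so at prevalence 0.30 a
lift of 2.5 pins confidence at exactly 0.75.

DSRSC items are then generated from the same compound-symmetric machinery
with a status-shifted construct level (shift 3.0 latent SD between groups,
entering the alpha calibration through its between-status variance), and
minimally adjusted — single random item steps — so the total lands at
\(\ge 15\) exactly when status is depressed. A simpler scheme (truncated
normal total, random composition into 18 items) cannot reach the 0.84
reliability target: an exchangeable random composition makes within-person
item variance too large relative to any feasible total-score variance on
0–36, capping alpha near 0.7. The adjustment step preserves the item
correlation structure because it touches only the minority of respondents
whose raw total falls on the wrong side of the cutoff.

A single integer seed drives the whole generator through deterministically
derived per-stage substreams (demographics, construct levels, items,
outcome, depression items, missingness), so adding a stage never perturbs
earlier draws, and the same seed is byte-reproducible.

`planted_rule_oracle()` estimates any planted rule's support, confidence
and lift by direct Monte-Carlo simulation — recomputing indicators inline
from raw totals, bypassing the transaction and mining code entirely — and
is the independent reference the mined results are compared against.

**What the generator does not emulate:** real item-level content and
differential item functioning, non-Gaussian dependence (only a Gaussian
copula), demographically structured missingness (attrition is completely at
random — the source gives no response-rate mechanism), school-level
clustering from the cluster-sampling design, and any factor→outcome
pathways beyond the planted logistic model. Passing tests therefore
demonstrate that the pipeline recovers known structure from data *like*
this, not that the published substantive findings replicate; the published
tables themselves are not numerically reproducible without the undeposited
survey.

## The packaged published tables

The six published stratified rule tables (risk and protective, by gender,
age group and left-behind status) ship as verbatim transcriptions under
`inst/extdata/`, guarded by an integrity checksum. Verbatim includes the
source's printing artefacts, which are flagged, not fixed: one antecedent
printed twice with different metrics in the left-behind risk table
(`duplicate-lhs`), and one row missing a separator between two labels
(`separator-restored`). `check_paper_tables()` recomputes counts,
itemset-size decompositions, metric ranges and base-rate consistency and
compares them with the source's own summary sentences; it reports exactly
four discrepancies internal to the source (a size decomposition and the
duplicate in the left-behind risk table, and two lift ranges whose prose
excludes printed rows) and confirms everything else. The count
discrepancy between the abstract's 2455 participants and the 2445 complete
cases (which the subgroup counts sum to) is resolved in favour of 2445
throughout.

## Problem sizes and numerical conventions

The test and acceptance suites use: 50 randomized instances (≤ 12 items,
≤ 300 transactions) for miner-vs-enumeration equivalence; 20 seeds at
n = 2445 for reliability calibration; 100 seeded cohorts for planted-rule
recovery (gender-stratified risk analysis) and 100 for the null control
(all planted effects zeroed, expecting no rule to pass 5%/70%/lift > 1);
and n = 20,000 for the compound-symmetry alpha convergence property. These
sizes keep the full suite in the low minutes on one core while leaving
Monte-Carlo standard errors well inside the asserted tolerances.

Ties in rule ordering are broken deterministically (support, then
lexicographic antecedent under C collation); percentile ties follow the
nearest-rank convention, which guarantees each quartile item covers at
least 25% of the sample (more under ties, never less); half-up rounding is
used for reported percentages and lifts because the published tables round
that way and R's default `round()` is half-even.

## Limitations

The package mines descriptive association rules; it attaches no
significance tests to rules (matching the source analysis) and supports no
causal reading. Alternative discretizations (median splits, clinical
norms), FP-Growth/Eclat mining, and redundant-rule pruning beyond the three
thresholds are out of scope. The generator's planted model is a
convenience for validation, not a fitted model of any real cohort.
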