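---
title: "Attributing population disease burden to genetically predicted telomere length"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributing population disease burden to genetically predicted telomere length}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teloburden)
```

## The question and the statistic

Mendelian-randomization (MR) studies consistently find that *longer*
genetically predicted telomere length (gTL) raises the odds of several
cancers, while *shorter* gTL raises the odds of degenerative diseases such
as coronary heart disease and Alzheimer's disease. Odds ratios alone make
the cancer associations look dominant (glioma OR 5.27 per SD longer gTL vs.
coronary heart disease OR 1.28 per SD shorter). But cancers like glioma are
rare and coronary disease is common, so the population-level comparison
requires weighting each odds ratio by how much disease there is to have.

`teloburden` implements that comparison as a small, fully tested pipeline.
For one disease the *excess burden* per standard deviation of gTL is

\[
E \;=\; (\mathrm{OR} - 1) \times R,
\]

where OR is the per-SD odds ratio harmonized to the disease's
risk-increasing direction and \(R\) is the age-standardized incidence or
DALY rate per 100,000 persons. \(E\) is read as cases (or DALYs) per
100,000 persons per SD of gTL in excess of baseline. The 95% CI applies the
same formula to the OR's CI bounds; the burden estimate's own CI is **not**
propagated. Group totals sum the per-disease values and sum the like CI
bounds.

Three conventions deserve emphasis, because they are reproduced
deliberately rather than because they are statistically ideal:

1. **Bounds are summed, not combined.** Summing per-disease CI bounds
   assumes perfect dependence between diseases. It is demonstrably the
   source convention — the published group lower bound (45.49 for the
   long-gTL cancers' excess incidence) equals the sum of the printed
   per-disease lower bounds — so `totalExcess()` defaults to it and the
   acceptance tests verify it. A root-sum-square alternative
   (`bounds = "rss"`), appropriate under independence, is provided for
   sensitivity analyses.
2. **OR stands in for a rate ratio.** \((\mathrm{OR}-1) \times R\) treats
   the odds ratio as if it were a risk ratio. For rare diseases this is
   harmless; for coronary heart disease or dementia it overstates the
   excess somewhat. The package reproduces the approximation as published
   and documents it here rather than silently "improving" it.
3. **Burden uncertainty is ignored.** Only the OR's CI enters the excess
   CI. Synthetic-data tests therefore treat burden CIs as inert metadata.

## Harmonization

Source studies publish ORs in mixed directions: one meta-analysis reports
everything per SD *longer* gTL (so degenerative diseases have OR < 1),
another reports per SD *shorter*. `invertOr()` converts between directions
by the reciprocal, swapping CI bounds: \(1/\mathrm{OR}\),
\((1/U, 1/L)\). No log-scale re-estimation is done — the reciprocal exactly
reproduces the published conversions (e.g. interstitial lung disease
11.11 (6.67–20.00) per SD shorter from 0.09 (0.05–0.15) per SD longer), and
inversion is an involution to machine precision, which the property tests
exercise.

The pipeline's default harmonization (`harmonizeRiskIncreasing()`) puts
each disease in its risk-increasing direction, which is how the published
tables are laid out: cancers per SD longer, non-neoplastic diseases per SD
shorter. `normalizeDirection()` instead forces a single declared direction
and flags (but keeps) protective associations.

When one registry burden category spans several narrow MR case definitions,
`collapseOrs()` combines their ORs as a weighted mean with weights
proportional to relative incidence or prevalence. The source describes the
weighting but not its scale; we default to the arithmetic mean on the OR
scale and expose a geometric (log-scale) option. Weights are normalized
internally (the result is scale-invariant either way) and CI bounds are
collapsed with the same weights as the point estimate. Only statistical
significance admits an OR into the analysis; `dropNonsignificant()` applies
that filter as a visible, logged step.

## Definition mapping

Registry categories are often broader than MR case definitions (e.g. "lung
cancer" vs. lung adenocarcinoma). `caseFraction()` forms the narrow/broad
case-count fraction (SEER-style counts), and `allocateBurden()` multiplies
the broad rate and both its CI bounds by the fraction. Allocation is linear
and conservative: fractions partitioning a broad cause reproduce its burden
exactly, which the property tests assert at machine precision. The one
published fraction — idiopathic pulmonary fibrosis as 26.8% of
interstitial lung disease, from the Danish National Registry of Patients —
ships as a fixture. No uncertainty is attached to fractions themselves,
matching the deterministic treatment in the source analysis.

`subtractSubcondition()` performs the mirrored sensitivity analysis:
removing a sub-condition's share \(f\) of a component's excess from a group
total, identically on values and bounds, with the exact complement property
`result + f * component == total`.

## Worked reproduction

```{r haycock}
rep <- reproduceStudy("haycock")
rep$totals
```

On the transcribed fixtures the recomputed totals sit within 0.1 of the
published values (94.04 and 121.49 excess cases, 1,255.25 and 1,007.75
excess DALYs per 100,000 persons per SD for long and short gTL
respectively); per-disease rows agree within 0.05 after two-decimal
rounding. Residuals are explained entirely by the inputs being printed at
two decimals.

```{r ipf}
rows <- excessRows(rep$report)
tot <- excessTotals(rep$report)
ild <- rows[rows$cause_name == "Interstitial lung disease" &
              rows$measure == "incidence", ]
short_inc <- tot[tot$measure == "incidence" & tot$direction == "per_sd_shorter", ]
subtractSubcondition(short_inc, ild, 0.268)$value
```

For the second bundled study (seven conditions, point ORs only), the
recomputed excess-incidence total agrees with the published 231.42 within
0.5, but the excess-DALY total computed from the printed two-decimal ORs is
838.48 against a published 840.28. The published total is the sum of
per-row excess values that were evidently computed from unrounded ORs the
source does not print; `reproduceStudy("li")` flags the cell rather than
patching it, and the package does not back-derive ORs from the printed
excess column (that would be circular).

## Independent-variant counting

The SNP panel fixture lists 106 SNPs on 18 chromosomes reported as
associated with leukocyte telomere length, with per-chromosome R² LD
matrices. Pairs with \(R^2 < 0.5\) are treated as uncorrelated. That
counting rule does not say what to do with transitive chains
(\(A \sim B\), \(B \sim C\), \(A \not\sim C\)), so `clusterVariants()`
implements two disambiguations and reports both:

- `connected_components` — transitive closure; order-invariant; the
  default.
- `greedy_sentinel` — sweep SNPs in table order, each unclaimed SNP founds
  a cluster and claims every still-unclaimed SNP correlated with it. This
  is how sentinel-based clumping is usually done, and it is
  order-dependent by construction (the tests exhibit a permutation that
  changes its output).

On the bundled panel at cutoff 0.5 the two rules give 68 and 71 clusters
respectively, bracketing the published figure of 70 independent variants;
since the published tie-handling is unstated, neither count is asserted to
equal 70. Missing R² values (one chromosome-8 variant has an unmeasured
row) contribute no edges by default — an unmeasurable correlation cannot
justify merging — with an `"error"` policy available. Cluster sentinels are
the members with the lowest chromosomal position, a deterministic and
biologically neutral choice. Correctness is checked against a hand-written
union–find oracle on random matrices up to 12×12, plus a monotonicity
property: the cluster count never increases as the cutoff falls.

## Synthetic studies and what the tests do (and do not) show

`simulateStudy()` generates a complete study — OR table, burden table,
optional case-fraction table — with known ground truth. Defaults mirror
the study conditions: 9 long-gTL and 5 short-gTL diseases; OR − 1 drawn
log-normally (median 0.6, log-SD 0.5, spanning roughly OR 1.2–5, the
spread of the published ORs); rates from a gamma model (shape 0.8, scale
25 per 100,000, DALYs ten times larger) covering the fixture's range from
~0.01 (neuroblastoma) to ~200 (coronary heart disease); symmetric 30%
relative CI half-widths. One integer seed drives one named pseudo-random
stream per artifact table, so regenerating one table never perturbs
another; identical seeds give bit-identical studies. `simulateLd()` plants
block clusters in an R² matrix with within/between ranges that must
straddle the cutoff when unambiguous recovery is requested.

Because the excess statistic is deterministic arithmetic, the pipeline must
recover the generator's truth *exactly* (tested at 1e-9, including after a
CSV round trip), and planted LD partitions must be recovered at 100% over
100 seeds. These are self-consistency guarantees: they show the plumbing is
faithful, not that the method is unbiased on real data. In particular the
generator does not emulate correlated OR and burden errors, non-European
registry structure, OR-vs-rate-ratio divergence for common diseases, or LD
estimation noise — so passing tests say nothing about those.

## Numerical choices and degenerate inputs

- Parsing accepts "." decimals and "," thousands separators only; `NA`
  cells are an explicit MISSING sentinel, never silently zero, and a
  missing burden value forces missing bounds.
- All rates are stored at full parsed precision; rounding (half-even, two
  decimals) happens only in display columns and reproduction diffs.
- En-dash and hyphen are both accepted in "OR (L–U)" cells; triangular LD
  input is mirrored, and two-sided input must agree within 1e-9.
- A disease with burden for only one measure contributes only to that
  measure's total; the other measure is excluded with a machine-readable
  reason (the aortic-aneurysm pattern: no incidence rate, DALY present).
- Degenerate cases covered by tests: empty tables (empty report, zero
  totals), OR = 1 (zero excess, CI from the OR bounds), fraction 0 and 1,
  1×1 LD matrices, all-zero LD matrices.

## Problem sizes

Everything runs at desk scale by design: 14 + 7 diseases, 106 SNPs, 18
matrices no larger than 11×11. The property suites use random matrices up
to 12×12, 100-seed LD recovery sweeps, and 20–30-row synthetic tables;
the full test suite and the acceptance script each finish in seconds.

## Limitations

The pipeline consumes published ORs and registry rates; it does not
re-estimate MR effects, propagate burden uncertainty, compute
population-attributable fractions, or perform age- or sex-stratified
allocation. The bounds-summation CI convention is conservative under
positive dependence and should not be read as a calibrated interval. gTL
here is a SNP-score proxy; direct germline transmission of telomere length
is outside what the ORs measure.
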