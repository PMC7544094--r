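# teloburden

Population disease burden attributable to long vs. short genetically
predicted telomere length (gTL).

Mendelian-randomization studies find that longer gTL raises the odds of
several cancers while shorter gTL raises the odds of degenerative diseases
(coronary heart disease, dementias, type I diabetes, interstitial lung
disease). Odds ratios alone make the cancer side look dominant — glioma's
OR is 5.27 per SD longer gTL versus 1.28 per SD shorter for coronary heart
disease — but the degenerative diseases are far more common. `teloburden`
is for epidemiologists and telomere researchers who want to put the two
sides on the same population scale.

## The statistic

For each disease, the excess burden per SD of gTL is

```
E = (OR − 1) × R
```

where OR is the per-SD odds ratio harmonized to the disease's
risk-increasing direction and R is the age-standardized incidence or DALY
rate per 100,000 persons. The 95% CI applies the same formula to the OR's
CI bounds (burden CIs are not propagated), and group totals sum values and
like bounds — the source convention, which assumes perfect dependence.
Around that core the package provides:

- **I/O with strict validation** for OR tables ("5.27 (3.15–8.81)" cells
  or split columns), GBD-Results-Tool-style and simple burden tables,
  square R² LD matrices (triangular input mirrored), and SNP panels.
- **Harmonization**: OR inversion by reciprocal-and-swap (`invertOr`),
  direction normalization, significance filtering, and incidence-weighted
  collapsing of narrow-definition ORs (`collapseOrs`).
- **Definition mapping**: SEER-style case-count fractions
  (`caseFraction`), proportional burden allocation (`allocateBurden`), and
  sub-condition sensitivity subtraction (`subtractSubcondition`).
- **Attribution**: per-disease excess rows, totals, and machine-readable
  exclusions in an S4 `AttributionReport` (`attributeBurden`,
  `runPipeline`, `reproduceStudy`).
- **LD analysis**: thresholded clustering of telomere-length SNPs into
  independent variants under two explicit rules (`clusterVariants`,
  `countIndependentVariants`).
- **Synthetic studies** with exact known truth for download-free testing
  (`simulateStudy`, `simulateLd`).

Transcribed fixtures for the two source meta-analyses (14 + 7 diseases),
the 106-SNP / 18-chromosome telomere-length SNP panel, and its
per-chromosome LD matrices ship under `inst/extdata/`.

## Worked example

```r
library(teloburden)

rep <- reproduceStudy("haycock")
rep$report
#> AttributionReport: 27 excess rows, 1 exclusions
#> Totals (per 100,000 persons per SD of gTL):
#>   incidence  per_sd_longer  94.05 (45.50-168.87)
#>   daly       per_sd_longer  1,255.25 (662.71-2,163.62)
#>   incidence  per_sd_shorter 121.45 (48.38-228.50)
#>   daly       per_sd_shorter 1,007.73 (411.62-1,847.31)
```

Long gTL accounts for an excess 94.05 cases and 1,255.25 DALYs per 100,000
persons per SD from the nine cancers; short gTL accounts for 121.45 cases
and 1,007.73 DALYs from the non-neoplastic diseases — opposite effect
directions of roughly equal population impact, despite the very different
odds ratios. The one exclusion is aortic aneurysm's incidence (no registry
rate available; its DALYs still contribute). The diff against the published
excess columns stays within printed-input rounding:

```r
rep$totals
#>     measure      direction     value  excess computed_2dp deviation  flag
#> 1      daly  per_sd_longer 1255.2450 1255.25      1255.25      0.00 FALSE
#> 2      daly per_sd_shorter 1007.7335 1007.75      1007.73     -0.02 FALSE
#> 3 incidence  per_sd_longer   94.0507   94.04        94.05      0.01 FALSE
#> 4 incidence per_sd_shorter  121.4504  121.49       121.45     -0.04 FALSE
```

Counting independent telomere-length variants from the bundled LD matrices
at the R² ≥ 0.5 threshold:

```r
mats <- readLdMatrixDir(system.file("extdata", "ld", package = "teloburden"))
snps <- readSnpTable(system.file("extdata", "snp_panel.csv", package = "teloburden"))
countIndependentVariants(mats, snps = snps)
#> connected_components      greedy_sentinel
#>                   68                   71
```

The two rules bracket the published count of ~70; the vignette
(`vignettes/telomere-burden-methods.Rmd`) explains why the exact figure is
rule-dependent, along with every other modelling convention.

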