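# Bundled fixture tables

Transcribed from the published summary tables of the source studies; all
values as printed (two-decimal rates and odds ratios), with typographic
defects of the printed tables repaired (one inverted CI, missing
parentheses, thousands-separator artifacts).

- `haycock_associations.csv` — per-SD odds ratios of disease with 95% CIs
  from the Haycock et al. 2017 MR meta-analysis: 9 cancers per SD longer
  gTL, 5 non-neoplastic diseases per SD shorter gTL (as published,
  already inverted onto the risk-increasing direction).
- `haycock_burden.csv` — age-standardized incidence and DALY rates per
  100,000 persons (GBD 2017, Europe) for the same causes; the aortic
  aneurysm incidence rate is unavailable (NA).
- `haycock_printed_excess.csv` — the published per-disease and total excess
  columns, used only by `reproduceStudy()` for side-by-side diffs.
- `li_associations.csv`, `li_burden.csv`, `li_printed_excess.csv` — the
  analogous tables for the 7 conditions of the Li et al. 2020 UK Biobank
  study (point ORs only; no CIs were published).
- `case_fractions.csv` — case-count allocation fractions; ships the
  idiopathic-pulmonary-fibrosis share of interstitial lung disease (0.268,
  Danish National Registry of Patients).
- `snp_panel.csv` — 106 SNPs on 18 chromosomes reported as associated with
  leukocyte telomere length (GRCh38 positions; first-listed study per SNP;
  `telomere_maintenance` flags SNPs in known telomere-maintenance genes).
- `ld/chr*.csv` — per-chromosome R-squared LD matrices over those SNPs
  (five European reference populations); symmetric, `NA` where LD was not
  measurable (chromosome 8, rs28365964).
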