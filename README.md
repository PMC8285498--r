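# mbcenrich

Multi-cohort comparison of somatic alteration frequencies between
metastatic breast cancer (MBC) and primary breast cancer (PBC), across
metastatic-site sets.

Large sequencing cohorts of breast cancer are heterogeneous: different
targeted panels, different clinical vocabularies, different copy-number
call conventions, and different QC pedigrees. `mbcenrich` is for
cancer-genomics analysts who want to pool such cohorts and ask three
questions:

1. **Pan-metastasis enrichment** — which genes are altered more often in
   MBC than in PBC?
2. **Organotropism** — which of those genes prefer a specific metastatic
   site (liver, bone, lymph nodes, ...) over the other sites, and does the
   preference survive adjustment for histology and receptor subtype?
3. **Candidate driver mutations** — which individual variants (oncogene
   hotspot missense changes, tumor-suppressor truncations) carry the
   signal?

## The statistics

For each feature (gene, or variant key) and comparison, carriers are
counted per cohort into 2×2 tables \(a_i, b_i, c_i, d_i\) (case/control ×
carrier/non-carrier). The kernel is a stratified odds-ratio meta-analysis:

- per-stratum log odds ratio \(y_i = \log(a_i d_i / b_i c_i)\) with Wald
  standard error \(se_i = \sqrt{1/a_i + 1/b_i + 1/c_i + 1/d_i}\)
  (Haldane–Anscombe 0.5 correction when a cell is zero);
- fixed-effects pooling by inverse variance,
  \(\hat\theta = \sum w_i y_i / \sum w_i\), \(w_i = 1/se_i^2\);
- heterogeneity via Cochran's \(Q = \sum w_i (y_i - \hat\theta)^2\),
  \(I^2 = \max(0, (Q - df)/Q)\), and a REML estimate of the
  between-cohort variance \(\tau^2\);
- when the FDR-adjusted heterogeneity p-value falls below 0.05 the pooled
  estimate switches to the random-effects model with weights
  \(w_i^* = 1/(se_i^2 + \tau^2)\);
- every meta-analytic result is validated by a cohort-adjusted logistic
  regression (outcome = comparison arm, predictor = carrier status,
  cohort indicators as covariates);
- p-values are Benjamini–Hochberg adjusted within declared families.

An **organotropism call** for (gene, site) requires *both* the
site-vs-PBC meta-analysis and the site-vs-other-metastatic-sites
regression to pass q < 0.05; its direction comes from the sign of the
site-vs-other log odds ratio, and it is labelled `subtype_robust` when
the carrier term stays significant after adding histology and receptor
subtype covariates.

A built-in synthetic-cohort generator simulates carrier status from the
same logistic model (baseline + MBC shift + site tropism + optional
histology confounding), dresses it in MAF-style records with QC fodder
(silent, low-depth, low-VAF, duplicate, hypermutated-outlier records),
and keeps the ground truth for recovery testing.

## Worked example

A published liver-vs-other-sites ESR1 carrier table, straight through the
kernel:

```r
library(mbcenrich)
odds_ratio_2x2(163, 420, 161, 1416)
#> OR 3.413 (95% CI 2.676-4.354), p = 4.97e-23
```

The carriers-at-liver odds are 3.4 times the odds at other metastatic
sites, with a confidence interval well away from 1.

End to end on a synthetic two-cohort study with a known liver-tropic,
MBC-enriched gene:

```r
cfg <- scenario_config("tropism", seed = 2021)
sim <- generate(cfg)
records <- apply_qc(sim$mutations)
attr(records, "qc_summary")
#>              step                reason count
#> 1 filter_variants             duplicate    21
#> 2 filter_variants             low_depth    21
#> 3 filter_variants               low_vaf    13
#> 4 filter_variants class_not_allowlisted    24
#> 5        apply_qc        outlier_sample     0
#> 6        apply_qc              retained   865

d <- mbc_data(records, select_samples(sim$clinical, sim$panels), sim$panels)
plan <- analysis_plan(genes = "TRG")
run_pan_metastasis(d, plan)$meta[, c("feature","k","model","or","ci_low","ci_high","q")]
#>   feature k model       or  ci_low  ci_high            q
#> 1     TRG 2 fixed 5.097449 4.26933 6.086198 1.728798e-72

ss  <- run_site_specific(d, plan)
res <- run_subtype_adjusted(d, ss, plan)
res$calls[res$calls$direction == "enriched",
          c("gene","site_set","vs_pbc_or","vs_other_or","vs_other_q","subtype_robust")]
#>   gene site_set vs_pbc_or vs_other_or  vs_other_q subtype_robust
#> 1  TRG    liver  12.50841    3.831269 1.78618e-45           TRUE
```

The QC accounting matches the injected noise exactly (79 noise records in,
79 removed), the pan-metastasis odds ratio of ~5 reflects the injected
MBC log-odds of ln 4 compounded by the liver tropism, and the caller
emits a liver call that survives subtype adjustment.

## Layout

- `R/` — readers/writers (`read_mutations`, `read_cna`, `read_clinical`,
  `write_report`), QC and harmonization (`apply_qc`,
  `select_concurrent_genes`, `classify_site_set`), counting
  (`build_contingency`, `multi_site_table`), the statistical kernel
  (`odds_ratio_2x2`, `or_meta`, `meta_family`, `logistic_fit`,
  `fisher_exact_2x2`, `bh_fdr`), the analyses (`run_pan_metastasis`,
  `run_site_specific`, `run_subtype_adjusted`,
  `run_treatment_contrasts`, `call_driver_mutations`) and the generator
  (`sim_config`, `generate`, `fixture_from_counts`).
- `vignettes/organotropism-methods.Rmd` — the model, its assumptions,
  parameter choices and limitations.
- `inst/extdata/` — small plain-text example tables for the readers.
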