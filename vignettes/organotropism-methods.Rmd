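---
title: "Methods: multi-cohort mutation enrichment and organotropism analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-cohort mutation enrichment and organotropism analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbcenrich)
```

# The problem

Metastatic breast cancer (MBC) samples accumulate somatic alterations
that primary breast cancer (PBC) samples largely share, so genuinely
MBC-enriched alterations are rare and individually weak signals. Worse,
metastasizing cells show *organotropism* — preferential colonization of
particular organs — so an alteration may matter only at one metastatic
site. Detecting either effect needs thousands of samples, which in
practice means pooling cohorts that were sequenced on different targeted
panels, annotated with different clinical vocabularies, and
quality-controlled to different standards.

`mbcenrich` implements the full path from heterogeneous cohort tables to
calls: harmonization and QC, carrier counting, a stratified odds-ratio
meta-analysis with heterogeneity-driven model switching, cohort-adjusted
logistic regression, a dual-criterion organotropism caller, and a
pattern-based candidate-driver-mutation scorer. A synthetic multi-cohort
generator with known ground truth makes every stage testable without any
restricted-access download.

# Data model and harmonization

Mutation records follow the MAF convention: one row per variant call with
a controlled `Variant_Classification` vocabulary, GRCh37 coordinates and
HGVSp-short protein changes. Readers normalize dialects up front:
chromosome labels lose any `chr` prefix (X/Y/MT uppercased), gene symbols
are rewritten to current HGNC names through an alias table (e.g.
MLL → KMT2A, MLL2 → KMT2D), copy-number labels `AMP`/`HOM_DEL` map to
integer levels +2/−2, and clinical labels pass through per-cohort
vocabulary maps. Parsing is *total*: a row either becomes a record or a
logged rejection with a reason code, and the two counts always sum to the
input row count. Some cohorts correct indel representation before MAF
conversion with rules that are not published; `read_mutations()` exposes
a `normalize` hook for such cohort-specific fixes rather than guessing a
transformation.

Missing depth or VAF stays missing — several cohorts simply lack the
fields, and a record must not be deleted for a field its cohort never
reported. QC therefore treats missingness as "not filterable on that
field".

## QC cascade

Filters run in a fixed order so removal counts are reproducible:
within-sample duplicates (same sample, coordinates and alleles), then
depth < 10, then VAF < 0.01 (both strict inequalities: a record at
exactly the threshold is kept), then the functional-consequence
allowlist (frameshift, in-frame, missense, nonsense, nonstop,
splice-region, splice-site, translation-start-site; flanks, UTRs,
introns and silent calls are removed). Finally, hypermutated outlier
samples are dropped: within each cohort, a sample whose retained variant
count exceeds Q3 + 3·IQR of the cohort's per-sample counts loses all its
variants.

Two numerical choices here deserve a note. Quartiles use linear
interpolation (`stats::quantile` type 7) so the fence is deterministic
across implementations. And the IQR is floored at one mutation: counts
are small integers, and a cohort whose middle quartiles coincide (IQR 0)
would otherwise flag *every* sample above Q3 as hypermutated — in
simulation that deleted exactly the samples carrying two altered genes
and induced spurious depletion of null genes. With the floor, the
worked fence example (counts 2, 3, 3, 4, 50 → fence 4 + 3·1 = 7,
only the 50-variant sample flagged) is unchanged.

## Panels and eligibility

Cohorts target different gene sets, so analyses are restricted to genes
covered by at least `ceil(7/11 × n_panels)` panels
(`select_concurrent_genes()`), and carrier counting excludes samples
whose panel does not cover the gene — an off-panel sample is not a
non-carrier, it is unassessable. Sample eligibility follows the cohort
conventions: female samples only, one biopsy site per patient (patients
with samples from several metastatic sites are analysed separately by
`multi_site_table()`), and no hotspot-only panels.

# The statistical kernel

Carrier status is binary at the sample level: a sample either has ≥ 1
qualifying alteration of a feature or it does not; multiplicity is
discarded. For each feature and comparison, each cohort contributes a
2×2 table, and:

- the per-stratum log odds ratio gets the Haldane–Anscombe 0.5 added to
  all four cells when any cell is zero (applied per affected stratum
  only); strata with zero carriers in both arms carry no information and
  are excluded from pooling; strata missing an entire arm are dropped;
- fixed-effects pooling is inverse-variance on the log scale. The
  random-effects alternative estimates the between-cohort variance τ²
  by REML (the standard fixed-point iteration, floored at zero) and
  re-pools with weights 1/(se² + τ²);
- heterogeneity is summarized by Cochran's Q, its χ² p-value and I².
  Within a test family, heterogeneity p-values are FDR-adjusted and a
  feature switches to the random-effects model when its heterogeneity
  q-value drops below 0.05. The raw-p gate is available for standalone
  fits (`or_meta(..., het_gate = "raw")`);
- confidence intervals and p-values are Wald throughout, matching the
  OR ± 1.96·se presentation convention of the field;
- the logistic validation fits carrier status against the comparison arm
  with cohort indicator covariates by IRLS (`stats::glm.fit`,
  epsilon 1e-10, ≤ 100 iterations). Complete or quasi-complete
  separation (a fitted probability numerically at 0/1 with a diverging
  coefficient) flags the fit and removes it from FDR families. On
  grouped 2×2 data the fit is saturated and reproduces the crude odds
  ratio exactly — one of the oracle checks in the test suite;
- FDR families are explicit: one family per analysis × mutation type
  (all genes of one SNV/indel comparison form a family, amplifications
  another, each site's stage-2 tests another); heterogeneity p-values
  form their own family per analysis. Family labels are recorded in
  every output row.

Two kernel primitives ride on base R by design: the BH step-up is
`stats::p.adjust(method = "BH")` behind a family-aware wrapper, and the
IRLS loop inside `logistic_fit()` is `stats::glm.fit`. The
meta-analytic layer (odds ratios, pooling, Q/I², REML, model switching)
is implemented in the package and cross-checked in the tests against
`metafor` and against a restricted-likelihood grid search.

# The three analyses

**Pan-metastasis** (`run_pan_metastasis`): every plan gene × mutation
type, MBC vs PBC, meta-analysis plus logistic validation; a gene is
reported MBC-enriched when both q-values fall below the threshold
(default 0.05).

**Site-specific** (`run_site_specific` + `run_subtype_adjusted`):
metastatic samples are classified into 15 site sets — pan, local
recurrence vs distant, and 12 specific distant sets (11 named organ sets
plus an `other_distant` catch-all that is excluded from per-site testing).
Ordered case-insensitive matchers resolve free-text biopsy labels;
local-recurrence patterns (ipsilateral breast/chest wall, regional lymph
nodes) match before the distant lymph-node set. Stage 1 tests each
(gene, site) against PBC; stage 2 tests stage-1-significant pairs
against all *other* metastatic sites by cohort-adjusted logistic
regression on the site-resolvable cohort subset. An organotropism call
needs both q < 0.05; direction comes from the stage-2 sign, and genes
depleted in MBC at stage 1 are reported but never called organotropic.
Because stage 2 contrasts one site against the rest, a strong single-site
enrichment mechanically produces complementary depleted calls at other
sites — mirroring how a liver-enriched gene appears depleted in lymph
nodes — so validation scenarios assert on the enriched call.

Subtype adjustment refits stage 2 twice, adding histology and
(separately) receptor subtype; `subtype_robust` requires the carrier
term to stay below the q threshold in both refits (FDR within each refit
family — the package's resolution of an ambiguity in how refits should
be corrected). A two-sided Fisher's exact test of the ILC–carrier
association accompanies each call, since lobular histology is the
classic confounder for ovary/peritoneum tropism. Receptor subtypes come
from (HR, HER2) status; a sample annotated only "HER2-positive" cannot
be placed in a single subtype and belongs to both HER2+ subgroups, so
subtype membership is kept as logical columns rather than one factor.

**Treatment contrasts** (`run_treatment_contrasts`): treatment-naive PBC
vs treatment-naive de novo MBC, and vs post-treatment MBC. A gene
significant in the de novo contrast is metastasis-associated (the
enrichment precedes therapy); significant only post-treatment is
treatment-associated (consistent with treatment selection).

# Driver-mutation patterns

Within the MBC-enriched genes, oncogenes are screened for hotspot
missense variants (protein-position match against a hotspot table;
position only, any substitution counts), tumor suppressors for
truncating variants (nonsense, splice-site, frameshift; splice-region is
configurable and off by default), dual-role genes for both. Missense
keys collapse by amino-acid change; truncating keys collapse per gene
under `Trunc`. The Func score is an integer: oncogene missense sums
three annotation tools (high/medium 2, low 1, neutral/missing 0) plus 1
at a hotspot; TSG truncation scores a base 4 plus literature evidence
(strong 2, weak 1). The exact point breakdown is a package
reconstruction honoring the published facts (three tools for oncogenes,
literature evidence for suppressors, eligibility at score ≥ 5) and every
point value is overridable. Eligibility also requires more than two MBC
carriers by default — the published wording ("more than two carriers")
is ambiguous between ≥ 2 and ≥ 3, so the stricter reading is the default
and `carrier_min = 1` gives the laxer one. Eligible keys get the same
meta-analysis vs PBC and per-site logistic site-preference tests as
genes, with FDR within the candidate family.

# The synthetic generator

`generate()` simulates at the sample × gene level with the same logistic
link the analyses fit:

$$\mathrm{logit}\,P(\text{carrier}) = \mathrm{logit}(p_0)
  + \beta_{\text{MBC}}[\text{MBC}] + \beta_{\text{site}}[\text{site}]
  + \beta_{\text{ILC}}[\text{ILC}]
  + \beta_{\text{post}}[\text{post-treatment}]$$

Defaults describe a realistic study: 4 cohorts of 500 MBC + 500 PBC
samples, 5% baseline carrier probability, a site distribution dominated
by liver/bone/lymph nodes, 13% lobular histology, and noise rates chosen
so each QC filter removes about 2% of records (depth is shifted negative
binomial, VAF is Beta, silent/duplicate records and hypermutated
outlier samples are injected with bookkeeping, so filter-accounting
tests are exact). Per-panel masking suppresses off-panel genes per
cohort; cohorts can lack CNA data or depth/VAF fields, as real ones do.
Three packaged scenarios (`scenario_config`) probe the organotropism
caller: genuine subtype-independent liver tropism, enrichment without
tropism, and an ILC→ovary confounded tropism with no direct site effect.

What the generator does *not* emulate: trinucleotide mutation spectra,
copy-number segments (gene-level calls only), clonality/VAF structure,
within-patient correlation beyond the multi-site mode, and
panel-specific capture artifacts. Passing recovery tests therefore show
that the pipeline estimates what it models — not that real cohort
idiosyncrasies are handled beyond the harmonization layer's explicit
rules.

`fixture_from_counts()` inverts counting: it emits a minimal one-cohort
dataset whose contingency table reproduces exact requested cells, which
is how published carrier tables are replayed through the machinery.

# Validation dimensions and problem sizes

The test suite checks, among others: exact reproduction of five
published site-preference odds ratios from their printed carrier counts;
parameter recovery of an injected ln 3 enrichment (200 replicates of the
default 4×(500+500) study: |mean bias| < 0.05, CI coverage within
[90%, 98%]); type-I error of the unadjusted meta-analysis under the null
(1000 replicates, rejection rate within [0.03, 0.07]); equivalence of
`fisher_exact_2x2` with exhaustive hypergeometric enumeration for all
2×2 tables with N ≤ 30; the grouped-logistic/crude-OR identity to 1e-6;
REML τ² against a likelihood search to 1e-4; byte-identical reports on
identical seeds; and exact QC conservation. These sizes keep the whole
suite under a minute of simulation per property while leaving the
binomial Monte Carlo error well inside the asserted bands.

# Known limitations

- The outlier fence is a stand-in for an unpublished graphical
  threshold; it is exposed in `qc_config()` rather than asserted as the
  "right" rule.
- Published pooled odds ratios that mix cohort adjustment with crude
  counting cannot be reproduced from printed tables alone; only crude
  rows are asserted, the rest are covered by recovery properties.
- The stage-2 one-vs-rest design makes complementary depleted calls a
  structural consequence of any strong single-site enrichment.
- Wald inference is used throughout; for very sparse features
  (carriers < ~5 per arm) exact or penalized methods would be
  preferable and are out of scope.
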