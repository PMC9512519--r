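---
title: "Methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette records how metabopipe's procedures are defined, which
conventions were chosen where several were defensible, and what the synthetic
validation data do and do not establish about real data.

## The container

A `metabolite_set` holds a dense numeric assay matrix (samples × metabolites),
two keyed annotation tibbles, a processing log, and a free-form `misc` list.
Three conventions shape everything downstream:

* **Missingness is `NA` and only `NA`.** Zero is a measurement (or an
  imputation choice); below-detection dropouts are `NA`. Conflating them with
  sentinel values like 0 or −999 silently corrupts medians and SDs, so the
  package never does.
* **Immutability by convention.** Every operation returns a new set and
  appends exactly one log entry (timestamp, operation, parameters, summary
  counts). The log is therefore a complete recipe for the data in hand; there
  is no guard against, say, log-transforming twice, because the audit trail
  makes the question answerable instead of forbidden.
* **Keyed, not positional, annotation.** `feature_id`/`sample_id` are derived
  keys of the tables, matched against the assay dimnames at validation and
  reordered to assay order. Row order in an annotation sheet therefore never
  matters; ID mismatches are errors that name the offending IDs.

`ms_merge()` is deliberately an inner join on the fixed axis: merging two
panels measured on non-identical sample sets would induce missingness
silently, which is exactly the data-quality hazard the container is built to
avoid, so mismatches are errors rather than `NA`s.

## Quality control

**Missing-rate filters** remove a feature/sample when its missing rate is
*strictly greater* than the threshold (default 0.5 on both axes). The strict
inequality means a feature missing in exactly half the samples survives the
default — a deliberate, documented tie-break so the default is permissive
rather than silently aggressive. Feature rates are computed over study
samples only: pooled-QC injections monitor the instrument, not the cohort,
and should not drive cohort-level QC decisions. They are nevertheless carried
through filtering and imputation so that normalization still has them.

**Outlier detection** flags x with |x − μ| > kσ per feature (default k = 5),
using the sample (n−1) SD over observed study values. Features with fewer
than 3 observations or zero SD produce no flags. Detection operates on values
as given — no implicit log — keeping the operation orthogonal to the
transformation step; for multiplicative data, log-transform first.
Winsorization clamps a flagged entry to the μ ± kσ boundary of the detection
pass (deterministic and testable, unlike clamping to the most extreme
unflagged observation); the statistics ride on the returned mask so handling
is always consistent with detection.

**Imputation.** Half-minimum (min/2 per feature) is the default, matching its
role as a stand-in for left-censoring; median and zero are provided for
comparability. KNN is feature-neighbour averaging: features are standardized
on observed values, the distance between two features is the
root-mean-square difference over co-observed samples (RMS rather than a raw
Euclidean sum so that pairs with different overlap sizes are comparable — a
convention this package fixes, since "KNN" alone does not), and a missing
entry takes the mean standardized value of the k nearest features observed at
that sample, back-transformed. Entries with no qualifying neighbour fall back
to the feature median; fully missing features stay missing and are reported.

`qc_pipeline()` applies filter-features → filter-samples → outliers →
imputation, in that order (filters before outlier statistics so hopeless rows
and columns cannot distort μ and σ; imputation last so it sees the cleaned
matrix). The pipeline is defined — and tested — to be exactly the composition
of the four standalone functions.

## Normalization

All four methods are ratio-based, map missing→missing, and leave blocks with
an undefined divisor unchanged (with a logged warning) rather than dropping
or zeroing them.

* **Batch-median:** divide each (feature, batch) block by its study-sample
  median, setting every batch median to 1. QC injections are excluded from
  the divisor — repeated injections of one pooled aliquot would otherwise
  bias the "batch median" toward the pool — but are divided like any other
  row. The method is scale-equivariant and idempotent.
* **QC-median:** same, with the pooled-QC median as divisor; appropriate when
  a common reference material is trusted more than the cohort composition.
* **Nearest-QC:** each value is divided by the feature's value in the QC
  injection nearest in run order within the batch (ties go to the earlier
  injection; QCs missing that feature are skipped for the next nearest),
  then the block is rescaled so the study median is 1, making results
  comparable with the other methods. The nearest-neighbour rule and the
  rescaling are conventions of this package: the method's name alone does
  not pin them down.
* **LOESS drift correction:** per (feature, batch), a degree-1 tricube
  locally weighted regression of **log** QC intensity on injection order
  (span 0.75 by default) estimates the drift curve d(t); values are divided
  by exp(d(t) − median d(t<sub>QC</sub>)), which flattens the QC trend,
  preserves the batch's QC median, and guarantees positive output. The log
  scale is a modelling choice: instrument drift in peak areas is
  multiplicative, and an additive correction could go negative. Predictions
  beyond the QC range extrapolate linearly from the boundary local fits.
  Blocks with fewer than 4 observed QC points cannot support a local fit and
  fall back to QC-median scaling, recorded in the log.

## Transformations

All transformations are per-feature maps over observed values (missing
entries never enter μ, σ, ranks, or n) and preserve within-feature order.
The inverse normal transform uses average ranks and the Blom offset,
Φ⁻¹((r − 0.375)/(n + 0.25)) — the prevailing convention in metabolome- and
genome-wide pipelines; the offset and tie rule are implementation conventions,
fixed and tested (tie-free features of equal n share one exact multiset of
scores, and the middle value of odd n is exactly 0).

## Embeddings

PCA standardizes features first (peak areas span orders of magnitude;
unscaled PCA would be a ranking of abundances, not of structure) — a
`scale = FALSE` escape hatch exists. Component signs follow a fixed
convention (largest-magnitude loading positive), making results exactly
reproducible. UMAP and t-SNE run single-threaded with explicit seeds;
out-of-range neighbourhood sizes are clamped with a warning. Missing values
are a hard error in all three: silent internal imputation would hide a QC
decision the user should make explicitly.

## Association scans

`regress_features()` treats the metabolite as the exposure on the right-hand
side, standardized to mean 0, SD 1 over the analysed samples, so estimates
are per-SD and comparable across metabolites; the reported estimate, SE,
statistic and p-value are for the metabolite term only. Complete cases are
taken per feature (not listwise across the panel), maximizing n per test,
with n reported per record. QC injections are excluded automatically.
Model fitting is delegated to the standard engines (`lm`, `glm`,
`survival::coxph`, `lmerTest::lmer` with Satterthwaite p-values,
`lme4::glmer` with Wald p-values); the scan machinery guarantees that failed
or degenerate fits become status records rather than exceptions, that
Benjamini–Hochberg adjustment spans exactly the successfully fitted features
of the call (failed fits are excluded from m and returned as `NA`), and that
results are bit-identical for any worker count — parallelism is an execution
detail, never a modelling one.

## The synthetic-data generator

`simulate_metabolite_set()` emulates the structure of multi-batch
non-targeted MS peak-area data: per-feature log-normal abundances (log-mean
uniform on 10–20, log-SD on 0.2–0.8, i.e. peak areas of ~2×10⁴–5×10⁸ with
realistic skew), multiplicative per-(batch, feature) factors
exp(N(0, batch_scale_sd)), a linear multiplicative drift ramp from 1 to
1 + drift_amplitude across each batch's injection order, and pooled-QC
injections at every k-th position drawn from the pooled mean profile with
log-SD 0.05 replicate noise. Drift is a linear ramp, not a sinusoid, so the
success of LOESS correction is measurable by a single rank-correlation
statistic. QC injections carry the batch factor and the drift — that is the
premise of QC-based correction; QCs immune to drift would make the method
untestable.

Missingness is MCAR or intensity-dependent (masking probability decreasing
in log-intensity through a logistic link centred at each feature's 20th
percentile, rescaled so the expected overall rate equals `missing_rate`).
Outliers multiply chosen study entries by exp(magnitude × feature log-SD).
Both are restricted to study samples, and injected-outlier entries are exempt
from masking, so the recorded truth stays well-defined. Phenotypes come from
a linear predictor over the true-effect features' standardized *clean* log
abundances — effects are biological, upstream of batch and drift artefacts —
with continuous (unit Gaussian noise), logistic, or exponential-hazard
survival outcomes; survival uses administrative censoring at the 70th
percentile of event times (≈30% censored), simpler than random censoring and
sufficient to exercise the Cox path. A single seed drives one RNG stream;
identical seeds give bit-identical outputs.

What passing on this generator does **not** show: real panels have correlated
metabolites (pathway structure), heteroscedastic and occasionally nonlinear
drift, batch effects that alter missingness patterns, and annotation
idiosyncrasies. Recovery here demonstrates the algorithms implement their
definitions and behave correctly under the stated generative model, not that
any method is optimal for a given instrument.

## Validation scale and numerical conventions

The shipped tests and `scripts/acceptance.R` run at desk scale, chosen to
keep the whole suite around half a minute while leaving comfortable
statistical margins: 300 samples × 50 features × 3 batches for the
normalization and QC-composition checks; 50 random 8×6 matrices for the
KNN-vs-brute-force oracle (agreement to 1e−10); 20 random datasets for the
OLS normal-equation oracle (1e−8); 500 samples × 1001 features for
association calibration (1000 null features give a ±2σ band of roughly
0.036–0.064 around the nominal 0.05 type-I rate); 600 replicates for Wald
coverage. Batch-median exactness is asserted to 1e−12 (the worst observed
deviation is one ulp), LOESS flatness as |Spearman ρ| < 0.2 per feature on
interleaved QCs.

One measured caveat: with the generator's fixed QC replicate noise
(log-SD 0.05) and a +30% drift, the *uncorrected* per-feature Spearman ρ
between QC intensity and run order concentrates around 0.83 — the drift range
(log 1.3 ≈ 0.26) over ~30 rank points cannot push every feature above 0.9,
so a per-feature "ρ > 0.9 before correction" check fails for a minority of
features by construction, while the substantive post-correction flatness
holds. The acceptance suite states both, and the uncorrected clause is the
expected failure.

CSV output uses shortest-round-trip doubles (lossless save→load); annotation
columns that are whole numbers are restored as integers, since CSV carries no
type information. Numbers are parsed in the C locale and thousands separators
are rejected outright. Input missing tokens are blank, `NA`, `NaN`, `N/A`
(case-insensitive), matching common vendor exports.

## Known limitations

* One assay matrix per set; multi-platform studies hold one set per platform
  and combine results, or merge panels with `ms_merge()`.
* No model-based left-censored imputation, no empirical-Bayes batch
  correction, no total-intensity/PQN normalization, no interaction terms or
  penalized regression — the scope is the streamlined core workflow.
* The nearest-QC rule and the inverse-normal offset are fixed conventions;
  both are logged with their parameters so analyses are comparable across
  runs.
* Raw spectral processing (mzML, peak picking, adducts) is upstream of this
  package: it starts from quantified peak-area tables.
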