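---
title: "Methods: lnc-eQTM discovery from paired methylation and lncRNA expression"
author: "lnceqtm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lnc-eQTM discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

DNA methylation at a CpG site can track the expression of a nearby long
non-coding RNA.  Such an association — an *expression quantitative trait
methylation* for a lncRNA, or lnc-eQTM — is interesting in cancer when
the coupling itself changes between tumor and normal tissue: a CpG whose
correlation with its host lncRNA is strong in normal lung and absent in
tumor (or vice versa) points at regulation that the tumor has rewired.
`lnceqtm` implements the full discovery chain for two-condition cohorts
(tumor vs matched normal, optionally for two cancer subtypes):

1. **Annotation.** lncRNA loci from a GENCODE-dialect GTF, classified as
   lincRNA vs other lncRNA biotypes (antisense, sense_overlapping,
   transcribed pseudogenes, ...); 450k-style CpG probes mapped to every
   gene span that contains them (inclusive boundaries, strand ignored).
2. **Preprocessing.** Genes with zero expression in all samples are
   removed; remaining zeros are replaced by the matrix minimum positive
   value and everything is log2-transformed; probes missing in every
   sample are removed.
3. **Differential methylation.** Per mapped probe, a two-tailed
   two-sample Student t-test on beta values, Benjamini–Hochberg FDR over
   the mapped testable probes, and a call when `FDR < 0.05` **and**
   `|mean_tumor − mean_normal| > 0.3` (both strict).
4. **Differential-correlation network.** For every (DMS, host lncRNA)
   pair, the Pearson correlation between methylation and log2 expression
   is computed separately in tumor and normal samples over complete
   observation pairs; the pair becomes an edge when
   `|PCC_tumor − PCC_normal| > 0.3`.  Edges carry a sign class.
5. **Subtype comparison.** Common/specific DMSs and lncRNAs between two
   subtype networks, per-gene DMS load, and the percentage of common
   DMSs whose interaction sign flips between subtypes.
6. **Survival.** Per network lncRNA, a multivariate Cox model over its
   adjacent DMS betas; the integrated risk score
   `RiskScore = Σ_i cox_i · meth_i`; a median split into high/low risk;
   a two-group log-rank test, significant at raw `p < 0.05`.

# Statistical and numerical choices

**Student vs Welch.** The t-test is pooled-variance by default
(`eqtm_thresholds(var_equal = )` switches to Welch).  Tumor and normal
cohorts are unpaired.  A probe is *untestable* — excluded before the FDR
family is formed — when either group has fewer than two observed values,
or both groups are constant with unequal means; two identical constant
groups return `t = 0, p = 1`.

**The FDR family.** Only probes mapped to at least one lncRNA enter
testing, and BH runs across all of them jointly, not per biotype class:
the analysis is explicitly restricted to lncRNA methylation, so that is
the natural single family.

**Strictness.** All decision cut-offs are strict inequalities
(`FDR < 0.05`, `|Δβ| > 0.3`, `|ΔPCC| > 0.3`, `p < 0.05`), so values
exactly at a threshold are not called.

**Correlations and missing data.** Correlations use complete pairs only
and require `min_pairs` (default 10) of them, with non-zero variance on
both sides; failing pairs are excluded with a logged reason rather than
propagating NA into the network.

**Sign classes.** "Positive/negative interaction" is defined here as the
sign of the *tumor-condition* correlation, with ties at exactly 0
counted positive; `sign_mode` offers sign-of-normal and
sign-of-stronger-|PCC| alternatives.  In the two-subtype comparison the
unit is the common DMS probe, which carries the majority sign over its
edges per subtype; probes with an exact sign tie are excluded from the
opposite-direction fraction and counted separately.

**Risk score and ties.** The displayed risk-score formula multiplies Cox
coefficients by *methylation* levels, and that is what is implemented;
patients with a score exactly at the median go to the low-risk group,
deterministically.  Cox models use the Efron tie approximation, at most
100 Newton iterations and tolerance 1e-9; collinear or non-converging
models are skipped per gene with a recorded reason, never fatally.  No
multiple-testing correction is applied across lncRNA models (it is a
screen reported at raw p), but a BH-adjusted column is emitted
alongside.

**Zero replacement scope.** "Minimum value of all samples" is read as
the minimum positive value over the combined tumor+normal expression
matrix of one subtype, after removing all-zero genes.  Replacing zeros
by anything else (e.g. a per-gene minimum) is not supported because the
downstream correlations should see one consistent floor.  Likewise the
all-NA probe filter runs on the combined beta matrix so both conditions
keep one probe universe, which the t-tests need.

**Gene id versions.** Expression row names may carry GENCODE version
suffixes; candidate pairs match gene ids after stripping `.N`.

# The synthetic-study generator

Real level-3 cohorts are replaced by a seeded generator
(`sim_config()` + `generate_study()` / `simulate_study()`) whose planted
signals make every stage testable against ground truth:

* **Annotation.** Non-overlapping gene spans (2–20 kb, 1–10 kb gaps) on
  one synthetic chromosome; a configurable fraction is lincRNA, the rest
  draw antisense/sense_overlapping/transcribed_processed_pseudogene
  biotypes; 1–4 CpG probes per gene plus intergenic probes that map to
  nothing.  Gene ids carry version suffixes on purpose, to exercise the
  version-stripping join.
* **Methylation.** Betas are Beta-distributed around a per-probe mean
  shared by both conditions (concentration 20 → per-probe SD ≈ 0.11 at
  mean 0.5, typical of a variable 450k probe).  Planted DMS probes shift
  the tumor mean by `dms_effect` (default 0.4) in a recorded random
  direction, with both means kept inside (0, 1).  Entry-level NAs and
  fully missing probes are injected at configurable rates.
* **Expression.** Latent log2 expression is a per-gene baseline
  (uniform on 2–8) plus noise.  For a planted eQTM pair the probe's
  standardized beta enters with weight ρ against `sqrt(1 − ρ²)` noise,
  so the *population* correlation between beta and log2 expression
  equals the configured per-condition target exactly (defaults: 0.8 in
  normal, 0 in tumor).  The latent value is exponentiated to a
  non-negative raw scale so the preprocessing stage has real work to do.
  Only a configurable fraction of planted DMS probes is coupled
  (`frac_eqtm`, default 0.5); the uncoupled rest are true-null
  differential-correlation pairs, which is what lets the pipeline's
  false-edge rate be measured inside one study.
* **Survival.** Exponential event times with log-hazard
  `Σ hazard_coef · beta` over the planted prognostic probes (centred;
  baseline median 730 days); an exact fraction of patients is censored
  uniformly before their event.  The default planted coefficient of 6
  per unit beta comes from a power analysis: prognostic probes are DMS
  probes whose tumor betas sit near the unit-interval boundary (SD down
  to ≈ 0.06), and a median-split log-rank test with ≈ 175 events needs a
  between-group log hazard ratio near 0.55 to reach 90% power.
* **Determinism.** Every file kind draws from its own RNG stream derived
  from the master seed, so identical configurations give byte-identical
  bundles and adding probes does not perturb expression draws.

**What the generator does not emulate** — and hence what passing tests
do *not* establish about real data: Illumina type I/II probe chemistry
and its beta-value compression, batch and purity effects, copy-number
contamination of betas, spatially correlated probes within a locus,
heavy-tailed expression counts, and informative censoring.  Zeros and
NAs are injected outside planted-pair genes/probes so that planted
correlations stay exactly at their targets; real missingness is not
that polite.  Recovery rates measured here are statements about the
implementation under a known model, not about 450k biology.

**Default study conditions.** 100 tumor + 100 normal samples, 120 genes,
~300 probes, Δβ = 0.4 at 25% of in-gene probes, planted correlations
0.8 → 0.  At these sizes the t-statistic at a planted DMS is ≈ 18, so
near-perfect DMS sensitivity is the *expected* behaviour, and the
differential-correlation margin (|ΔPCC| ≈ 0.8 against threshold 0.3,
sampling SD ≈ 0.11) likewise implies near-complete edge recovery with a
fraction of null pairs near 3–4%.  Validation suites run 5–25 seeded
replicates of such studies (1,000-probe null matrices with 200
replicates for FDR control); these sizes were chosen so each property
is measured with a Monte-Carlo standard error well below the margin
being asserted.

# Known limitations

* Gene-span overlap is the only probe→gene mapping unit (a `flank`
  argument extends spans symmetrically); promoter- or exon-restricted
  mapping is not implemented.
* No covariate adjustment anywhere: differential methylation ignores
  age/stage/batch, and the Cox models contain methylation only.
* The survival screen splits patients by a score fitted on the same
  patients; with a single-probe model the grouping reduces to a median
  split on the probe itself (label-swap invariant), but with several
  probes the data-driven weighting makes the raw log-rank p slightly
  optimistic.  The emitted BH column does not fix that; an external
  validation cohort would.
* Correlation edges carry no significance filter beyond the |ΔPCC|
  threshold, mirroring the upstream design; at small sample sizes the
  threshold alone controls false edges poorly.
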