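# lnceqtm

Discovery of **lncRNA expression quantitative trait methylations
(lnc-eQTMs)** from paired DNA-methylation and lncRNA-expression cohorts,
as an installable R package plus a numbered analysis workflow.

A lnc-eQTM is an association between the methylation level of a CpG site
and the expression of the lncRNA whose locus contains it.  The package
finds CpGs that are *differentially methylated* between tumor and normal
tissue (DMSs), then keeps the DMS–lncRNA pairs whose methylation–
expression coupling *changes* between conditions, compares the resulting
networks across two cancer subtypes, and screens every network lncRNA
for prognostic value with a Cox-weighted methylation risk score.

The decision rules, in the field's standard notation:

* **DMS call:** two-tailed two-sample Student *t*-test on beta values;
  call iff `FDR < 0.05` (Benjamini–Hochberg over mapped, testable
  probes) and `|β̄_tumor − β̄_normal| > 0.3`.
* **eQTM edge:** per-condition Pearson correlation `r` between beta and
  log2 expression over complete pairs; edge iff
  `|r_tumor − r_normal| > 0.3`; sign class = sign of `r_tumor`.
* **Risk score:** `RiskScore_p = Σ_i cox_i · meth_i(p)` with `cox_i` the
  multivariate Cox coefficients of a lncRNA's DMSs; median split into
  high/low risk; two-group log-rank test, significant at `p < 0.05`.

Because the original level-3 cohorts are not redistributable, the
package ships a seeded synthetic-study generator (`sim_config()`,
`generate_study()`) that emulates all five inputs — GTF annotation,
probe manifest, beta matrices, expression matrices, clinical follow-up —
with *planted* DMSs, condition-specific couplings, and
methylation-linked hazards, so every stage is tested against known
ground truth.

## Worked example

The `analysis/` scripts run the whole study in order:

```sh
Rscript analysis/01_simulate.R   # seeded two-subtype synthetic study
Rscript analysis/02_dms.R        # preprocessing, mapping, DMS calling
Rscript analysis/03_networks.R   # differential-correlation networks
Rscript analysis/04_compare.R    # subtype comparison
Rscript analysis/05_survival.R   # Cox risk-score prognostic screen
```

Output of a run (all tables land under `results/`):

```
subtype A: 8 probes removed (all-NA), 6 genes removed (all-zero)
  315 probe-gene pairs, 307 tested, 79 DMSs called
  lincRNA: 44 DMSs in 31 genes, 56.8% up
  other_lncRNA: 35 DMSs in 26 genes, 48.6% up
  planted-DMS sensitivity: 100.0%
...
lnc-eQTM network [A]: 40 edges (23 positive, 17 negative), 40 DMSs, 40 lncRNAs
  planted-pair recovery: 100.0% (40 planted)
...
common DMSs: 12 (A-specific 28, B-specific 28)
opposite-direction fraction among common DMSs: 58.33% (0 ties excluded)
...
subtype A: 40 models fitted, 4 significant (log-rank p < 0.05), 0 skipped
  SYNG00000070.5  p = 0.0025  *  [planted hazard]
```

Reading this: the 79 called DMSs are exactly the planted ones (Δβ = 0.4
at n = 100/100 gives a t-statistic near 18, so full sensitivity is the
expected behaviour, not a surprise); all 40 planted coupling pairs
survive as network edges; the subtype comparison recovers the designed
50% sharing of planted signal after network filtering; and both planted
prognostic lncRNAs rank at the top of the survival screen, with the
remaining significant models consistent with the 5% false-flag rate of
an uncorrected screen (~2 of 38 null models).

The same machinery is callable directly:

```r
library(lnceqtm)
res <- run_study(sim_config(seed = 1), subtypes = c("A", "B"))
res$runs$A$stats          # edge/sign/node counts
res$comparison$opposite_fraction
res$runs$A$survival$models
```

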