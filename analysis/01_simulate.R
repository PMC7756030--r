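#!/usr/bin/env Rscript
# Step 1 — simulate the two-subtype synthetic study that stands in for
# the tumor/normal methylation + lncRNA expression + follow-up cohorts.
# Writes the full input bundle (GTF, probe manifest, beta/expression
# matrices, clinical tables, planted-truth JSON) under results/study/.

suppressPackageStartupMessages(library(lnceqtm))

cfg <- sim_config(seed = 20260923)
out <- generate_study(cfg, "results/study", subtypes = c("A", "B"))

cat("Simulated study written to results/study\n")
cat(sprintf("  genes: %d (%d lincRNA), probes: %d\n",
            nrow(out$study$genes),
            sum(out$study$genes$biotype_class == "lincRNA"),
            nrow(out$study$probes)))
for (s in c("A", "B")) {
  tr <- out$study$subtypes[[s]]$truth
  cat(sprintf("  subtype %s: %d planted DMSs, %d eQTM pairs, %d prognostic probes\n",
              s, nrow(tr$dms), nrow(tr$eqtm), nrow(tr$prognostic)))
}
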