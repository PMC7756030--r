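#!/usr/bin/env Rscript
# Step 5 — prognostic screen: for every network lncRNA, a multivariate
# Cox model over its DMS betas, the integrated risk score
# sum_i cox_i * meth_i, a median split, and a log-rank test.  Writes the
# ranked model table and KM curves for significant models.

suppressPackageStartupMessages(library(lnceqtm))

for (s in c("A", "B")) {
  st <- load_study("results/study", s)
  pp <- preprocess_subtype(st$expr_tumor, st$expr_normal,
                           st$beta_tumor, st$beta_normal)
  pairs <- map_probes(st$probes, st$genes)
  dms <- call_dms(pp$beta_tumor, pp$beta_normal, pairs)
  net <- build_network(dms, pairs, pp$beta_tumor, pp$beta_normal,
                       pp$expr_tumor, pp$expr_normal, subtype = s)
  scr <- screen_prognostic(net, pp$beta_tumor, st$clinical)
  write_tsv(scr$models, sprintf("results/survival_models_%s.tsv", s))
  write_tsv(scr$skipped, sprintf("results/survival_skipped_%s.tsv", s))
  sig <- scr$models[scr$models$significant, ]
  cat(sprintf("subtype %s: %d models fitted, %d significant (log-rank p < 0.05), %d skipped\n",
              s, nrow(scr$models), nrow(sig), nrow(scr$skipped)))
  planted <- st$truth$eqtm$gene_id[st$truth$eqtm$probe_id %in%
                                   st$truth$prognostic$probe_id]
  for (i in seq_len(min(5, nrow(scr$models)))) {
    m <- scr$models[i, ]
    cat(sprintf("  %s  p = %.2g%s%s\n", m$gene_id, m$logrank_p,
                if (m$significant) "  *" else "",
                if (m$gene_id %in% planted) "  [planted hazard]" else ""))
  }
  for (g in sig$gene_id) {
    km <- scr$fits[[g]]$km
    write_tsv(km, sprintf("results/km_%s_%s.tsv", s,
                                    gsub("[^A-Za-z0-9_.-]", "_", g)))
  }
}
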