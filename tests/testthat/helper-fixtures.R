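# Small in-code fixtures shared across test files.

# A hand-buildable eqtm_network from an edge table with per-condition
# correlations; mirrors what build_network assembles.
make_net <- function(edges, subtype = "X",
                     thresholds = eqtm_thresholds()) {
  edges$delta_pcc <- abs(edges$pcc_tumor - edges$pcc_normal)
  edges$sign_class <- ifelse(edges$pcc_tumor >= 0, "positive", "negative")
  structure(list(edges = edges,
                 dms_nodes = unique(edges$probe_id),
                 lncRNA_nodes = unique(edges$gene_id),
                 candidates = edges, dropped = edges[0, ],
                 subtype = subtype, thresholds = thresholds),
            class = "eqtm_network")
}

edge_row <- function(probe, gene, pcc_t, pcc_n) {
  data.frame(probe_id = probe, gene_id = gene,
             biotype_class = "lincRNA",
             pcc_tumor = pcc_t, pcc_normal = pcc_n,
             n_tumor = 50L, n_normal = 50L,
             stringsAsFactors = FALSE)
}

# Random small probe/gene tables (possibly overlapping genes) for
# mapping property tests.
random_annotation <- function(n_probes = 100, n_genes = 20) {
  genes <- data.frame(
    gene_id = sprintf("G%03d", seq_len(n_genes)),
    symbol = sprintf("G%03d", seq_len(n_genes)),
    chrom = sample(c("chr1", "chr2"), n_genes, replace = TRUE),
    start = sample.int(5000, n_genes),
    strand = "+",
    biotype_raw = "lincRNA", biotype_class = "lincRNA",
    stringsAsFactors = FALSE)
  genes$end <- genes$start + sample.int(800, n_genes)
  probes <- data.frame(
    probe_id = sprintf("cg%05d", seq_len(n_probes)),
    chrom = sample(c("chr1", "chr2"), n_probes, replace = TRUE),
    pos = sample.int(6000, n_probes),
    stringsAsFactors = FALSE)
  list(probes = probes, genes = genes)
}

# One-subtype simulation flattened so annotation travels with the data.
sim_one <- function(cfg) {
  res <- simulate_study(cfg, "A")
  c(res$subtypes$A, list(probes = res$probes, genes = res$genes))
}

# A tiny study configuration that keeps full-pipeline tests fast.
small_config <- function(seed = 1, ...) {
  sim_config(seed = seed, n_tumor = 40, n_normal = 40, n_genes = 40,
             n_intergenic_probes = 20, ...)
}
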