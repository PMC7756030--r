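#' Compare two subtype-specific lnc-eQTM networks
#'
#' Set algebra on node identities, matching of common edges by
#' (probe_id, gene_id), and the opposite-direction fraction.  The
#' comparison unit for the opposite fraction is the common DMS probe:
#' each probe carries, per subtype, the majority sign class over its
#' edges; probes with an exact sign tie in either network are excluded
#' from the fraction (their count is reported).
#'
#' @param net_a,net_b `eqtm_network` objects built on the same
#'   annotation universe.
#' @return a `ComparisonResult` list: common/specific gene and probe
#'   sets, matched common edges, per-probe signs, `opposite_fraction`
#'   (percent, NA when no comparable common probes) and the number of
#'   tie-excluded probes.
#' @export
compare_networks <- function(net_a, net_b) {
  ga <- net_a$lncRNA_nodes; gb <- net_b$lncRNA_nodes
  pa <- net_a$dms_nodes; pb <- net_b$dms_nodes
  common_genes <- intersect(ga, gb)
  common_probes <- intersect(pa, pb)

  ea <- net_a$edges; eb <- net_b$edges
  key_a <- paste(ea$probe_id, ea$gene_id)
  key_b <- paste(eb$probe_id, eb$gene_id)
  ck <- intersect(key_a, key_b)
  common_edges <- if (length(ck)) {
    ia <- match(ck, key_a); ib <- match(ck, key_b)
    data.frame(probe_id = ea$probe_id[ia], gene_id = ea$gene_id[ia],
               pcc_a_tumor = ea$pcc_tumor[ia], pcc_b_tumor = eb$pcc_tumor[ib],
               sign_a = ea$sign_class[ia], sign_b = eb$sign_class[ib],
               stringsAsFactors = FALSE)
  } else {
    data.frame(probe_id = character(), gene_id = character(),
               pcc_a_tumor = numeric(), pcc_b_tumor = numeric(),
               sign_a = character(), sign_b = character(),
               stringsAsFactors = FALSE)
  }

  sign_a <- probe_majority_sign(ea, common_probes)
  sign_b <- probe_majority_sign(eb, common_probes)
  comparable <- !is.na(sign_a) & !is.na(sign_b)
  n_tied <- sum(!comparable)
  opposite_fraction <- if (any(comparable)) {
    100 * mean(sign_a[comparable] != sign_b[comparable])
  } else NA_real_

  list(
    common_genes = common_genes,
    specific_genes_a = setdiff(ga, gb),
    specific_genes_b = setdiff(gb, ga),
    common_probes = common_probes,
    specific_probes_a = setdiff(pa, pb),
    specific_probes_b = setdiff(pb, pa),
    common_edges = common_edges,
    probe_signs = data.frame(probe_id = common_probes,
                             sign_a = sign_a, sign_b = sign_b,
                             stringsAsFactors = FALSE),
    opposite_fraction = opposite_fraction,
    n_tie_excluded = n_tied,
    per_gene = per_gene_dms_profile(net_a, net_b, common_genes)
  )
}

# Majority sign class over a probe's edges; exact tie -> NA.
probe_majority_sign <- function(edges, probe_ids) {
  vapply(probe_ids, function(p) {
    s <- edges$sign_class[edges$probe_id == p]
    npos <- sum(s == "positive"); nneg <- sum(s == "negative")
    if (npos == nneg) NA_character_
    else if (npos > nneg) "positive" else "negative"
  }, character(1), USE.NAMES = FALSE)
}

#' Per-gene DMS counts in each of two networks
#'
#' For each common gene, the number of distinct DMS probes adjacent to it
#' in each network.
#'
#' @param net_a,net_b `eqtm_network` objects.
#' @param common_genes genes present in both networks.
#' @return data.frame with `gene_id`, `count_a`, `count_b`.
#' @export
per_gene_dms_profile <- function(net_a, net_b,
                                 common_genes = intersect(net_a$lncRNA_nodes,
                                                          net_b$lncRNA_nodes)) {
  cnt <- function(edges, g)
    length(unique(edges$probe_id[edges$gene_id == g]))
  data.frame(
    gene_id = common_genes,
    count_a = vapply(common_genes, cnt, integer(1), edges = net_a$edges),
    count_b = vapply(common_genes, cnt, integer(1), edges = net_b$edges),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
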