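#' Pearson correlation over complete observation pairs
#'
#' @param x,y numeric vectors of equal length; pairs with an NA in either
#'   vector are dropped.
#' @param min_pairs minimum complete pairs required.
#' @return the Pearson product-moment coefficient, or `NA` (with
#'   attribute `reason`) when fewer than `min_pairs` complete pairs
#'   remain or either vector is constant over them.
#' @export
pcc <- function(x, y, min_pairs = 10L) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < min_pairs) {
    return(structure(NA_real_, reason = "too few complete pairs", n = n))
  }
  xs <- x[ok]; ys <- y[ok]
  if (stats::var(xs) == 0 || stats::var(ys) == 0) {
    return(structure(NA_real_, reason = "zero variance", n = n))
  }
  structure(stats::cor(xs, ys), n = n)
}

#' Absolute difference of two Pearson correlations
#'
#' @param pcc_tumor,pcc_normal correlations in `[-1, 1]`.
#' @return `|pcc_tumor - pcc_normal|`.
#' @export
pcc_difference <- function(pcc_tumor, pcc_normal) {
  stopifnot(all(abs(pcc_tumor) <= 1, na.rm = TRUE),
            all(abs(pcc_normal) <= 1, na.rm = TRUE))
  abs(pcc_tumor - pcc_normal)
}

edge_sign_class <- function(pcc_tumor, pcc_normal, sign_mode = "tumor") {
  ref <- switch(sign_mode,
    tumor = pcc_tumor,
    normal = pcc_normal,
    strongest = ifelse(abs(pcc_tumor) >= abs(pcc_normal),
                       pcc_tumor, pcc_normal))
  ifelse(ref >= 0, "positive", "negative")
}

#' Build a condition-specific lnc-eQTM network
#'
#' Candidate pairs are every (DMS probe, mapped lncRNA) combination whose
#' gene has an expression row (gene ids matched after stripping version
#' suffixes).  For each candidate the Pearson correlation between
#' methylation and log2 expression is computed per condition over
#' complete pairs; an edge is retained when the absolute difference of
#' the two correlations exceeds `thresholds$delta_pcc` (strict).  Each
#' edge carries a sign class (by default the sign of the tumor-condition
#' correlation, ties at 0 counted positive).
#'
#' @param dms result of [call_dms()].
#' @param pairs probe-gene pairs from [map_probes()].
#' @param beta_tumor,beta_normal beta matrices.
#' @param expr_tumor,expr_normal log2 expression matrices.
#' @param thresholds an [eqtm_thresholds()] object.
#' @param subtype label stored on the network.
#' @return an `eqtm_network` object: list with `edges` (data.frame of
#'   retained EQTMEdge rows), `dms_nodes`, `lncRNA_nodes`, `candidates`
#'   (all computable candidate pairs with their correlations) and
#'   `dropped` (uncomputable pairs with reasons).
#' @export
build_network <- function(dms, pairs, beta_tumor, beta_normal,
                          expr_tumor, expr_normal,
                          thresholds = eqtm_thresholds(),
                          subtype = "tumor") {
  stopifnot(inherits(thresholds, "eqtm_thresholds"))
  cand <- pairs[pairs$probe_id %in% dms$records$probe_id,
                c("probe_id", "gene_id", "biotype_class"), drop = FALSE]
  expr_ids <- strip_gene_version(rownames(expr_tumor))
  gi <- match(strip_gene_version(cand$gene_id), expr_ids)
  cand <- cand[!is.na(gi), , drop = FALSE]
  gi <- gi[!is.na(gi)]
  n <- nrow(cand)
  pt <- pn <- numeric(n); nt <- nn <- integer(n)
  drop_reason <- character(n)
  for (i in seq_len(n)) {
    b_t <- beta_tumor[cand$probe_id[i], ]
    b_n <- beta_normal[cand$probe_id[i], ]
    e_t <- expr_tumor[gi[i], ]
    e_n <- expr_normal[gi[i], ]
    ct <- pcc(b_t, e_t, thresholds$min_pairs)
    cn <- pcc(b_n, e_n, thresholds$min_pairs)
    pt[i] <- ct; pn[i] <- cn
    nt[i] <- attr(ct, "n"); nn[i] <- attr(cn, "n")
    drop_reason[i] <- if (is.na(ct)) attr(ct, "reason")
                      else if (is.na(cn)) attr(cn, "reason") else ""
  }
  cand$pcc_tumor <- pt
  cand$pcc_normal <- pn
  cand$n_tumor <- nt
  cand$n_normal <- nn
  dropped <- cand[drop_reason != "", , drop = FALSE]
  dropped$reason <- drop_reason[drop_reason != ""]
  cand <- cand[drop_reason == "", , drop = FALSE]
  cand$delta_pcc <- pcc_difference(cand$pcc_tumor, cand$pcc_normal)
  edges <- cand[cand$delta_pcc > thresholds$delta_pcc, , drop = FALSE]
  if (nrow(edges) == 0L)
    warning("build_network: no edges retained at delta_pcc > ",
            thresholds$delta_pcc, call. = FALSE)
  edges$sign_class <- edge_sign_class(edges$pcc_tumor, edges$pcc_normal,
                                      thresholds$sign_mode)
  rownames(edges) <- rownames(cand) <- NULL
  structure(list(
    edges = edges,
    dms_nodes = unique(edges$probe_id),
    lncRNA_nodes = unique(edges$gene_id),
    candidates = cand,
    dropped = dropped,
    subtype = subtype,
    thresholds = thresholds
  ), class = "eqtm_network")
}

#' @export
print.eqtm_network <- function(x, ...) {
  s <- network_stats(x)
  cat("lnc-eQTM network [", x$subtype, "]: ", s$n_edges, " edges (",
      s$n_positive, " positive, ", s$n_negative, " negative), ",
      s$n_dms, " DMSs, ", s$n_lncRNA, " lncRNAs\n", sep = "")
  invisible(x)
}

#' Summary counts and node degrees of an lnc-eQTM network
#'
#' @param net an `eqtm_network`.
#' @return list with edge/sign/node counts and a `degree` data.frame
#'   (node, kind, degree) sorted by decreasing degree.
#' @export
network_stats <- function(net) {
  e <- net$edges
  deg <- if (nrow(e)) {
    d1 <- as.data.frame(table(e$probe_id), stringsAsFactors = FALSE)
    d2 <- as.data.frame(table(e$gene_id), stringsAsFactors = FALSE)
    colnames(d1) <- colnames(d2) <- c("node", "degree")
    d1$kind <- "DMS"; d2$kind <- "lncRNA"
    d <- rbind(d1, d2)
    d <- d[order(-d$degree, d$node), c("node", "kind", "degree")]
    rownames(d) <- NULL
    d
  } else {
    data.frame(node = character(), kind = character(), degree = integer())
  }
  list(n_edges = nrow(e),
       n_positive = sum(e$sign_class == "positive"),
       n_negative = sum(e$sign_class == "negative"),
       n_dms = length(net$dms_nodes),
       n_lncRNA = length(net$lncRNA_nodes),
       degree = deg)
}

network_igraph <- function(net) {
  e <- net$edges
  g <- igraph::graph_from_data_frame(
    data.frame(from = e$probe_id, to = e$gene_id,
               sign_class = e$sign_class, delta_pcc = e$delta_pcc,
               pcc_tumor = e$pcc_tumor, pcc_normal = e$pcc_normal,
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(
      name = c(net$dms_nodes, net$lncRNA_nodes),
      kind = c(rep("DMS", length(net$dms_nodes)),
               rep("lncRNA", length(net$lncRNA_nodes))),
      stringsAsFactors = FALSE))
  g
}

#' Export a network in Cytoscape-readable SIF format
#'
#' One line per edge: `probe <sign_class> gene`.
#'
#' @param net an `eqtm_network`.
#' @param path output path.
#' @export
write_sif <- function(net, path) {
  e <- net$edges
  writeLines(paste(e$probe_id, e$sign_class, e$gene_id, sep = "\t"), path)
  invisible(path)
}

#' Export a network as GraphML
#'
#' @param net an `eqtm_network`.
#' @param path output path.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(network_igraph(net), path, format = "graphml")
  invisible(path)
}

#' Export node attributes (kind, degree) as TSV
#'
#' @param net an `eqtm_network`.
#' @param path output path.
#' @export
write_node_attributes <- function(net, path) {
  write_tsv(network_stats(net)$degree, path)
}
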