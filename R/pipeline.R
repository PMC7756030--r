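#' Run the full lnc-eQTM analysis for one subtype
#'
#' Executes, in order: matrix preprocessing (zero-gene filter, zero
#' replacement + log2, all-NA probe filter), probe-to-lncRNA mapping,
#' DMS calling, differential-correlation network construction, and the
#' Cox risk-score survival screen.  Every stage is a pure function of
#' its inputs and the thresholds, so a rerun on the same inputs is
#' byte-identical.  When `clinical` is `NULL` (or the file is absent)
#' the survival stage is skipped with a warning and earlier stages
#' complete normally.
#'
#' @param genes,probes annotation tables ([read_gtf()],
#'   [read_probe_manifest()] or the synthetic generator).
#' @param beta_tumor,beta_normal raw beta matrices.
#' @param expr_tumor,expr_normal raw-scale expression matrices.
#' @param clinical clinical data.frame or `NULL`.
#' @param thresholds an [eqtm_thresholds()] object.
#' @param subtype label carried through the outputs.
#' @param out_dir optional directory; when given, every stage table is
#'   written there (TSV, SIF, GraphML) together with a run manifest.
#' @return list with `preprocessed`, `pairs`, `dms`, `summary`,
#'   `network`, `stats`, `survival` (or `NULL`), and `manifest` (stage
#'   in/out counts).
#' @export
run_subtype <- function(genes, probes, beta_tumor, beta_normal,
                        expr_tumor, expr_normal, clinical = NULL,
                        thresholds = eqtm_thresholds(),
                        subtype = "A", out_dir = NULL) {
  pp <- preprocess_subtype(expr_tumor, expr_normal,
                           beta_tumor, beta_normal)
  pairs <- map_probes(probes, genes)
  dms <- call_dms(pp$beta_tumor, pp$beta_normal, pairs, thresholds)
  summary <- summarize_dms(dms)
  net <- suppressWarnings(
    build_network(dms, pairs, pp$beta_tumor, pp$beta_normal,
                  pp$expr_tumor, pp$expr_normal, thresholds,
                  subtype = subtype))
  stats <- network_stats(net)
  surv <- NULL
  if (is.null(clinical)) {
    warning("run_subtype[", subtype,
            "]: no clinical table; survival stage skipped", call. = FALSE)
  } else {
    surv <- screen_prognostic(net, pp$beta_tumor, clinical, thresholds)
  }
  manifest <- data.frame(
    stage = c("genes_in", "genes_removed_all_zero", "probes_in",
              "probes_removed_all_na", "probe_gene_pairs",
              "probes_tested", "dms_called", "network_candidates",
              "network_edges", "edges_positive", "edges_negative",
              "survival_models", "survival_significant"),
    count = c(nrow(expr_tumor), length(pp$removed_genes),
              nrow(beta_tumor), length(pp$removed_probes), nrow(pairs),
              nrow(dms$tested), nrow(dms$records), nrow(net$candidates),
              stats$n_edges, stats$n_positive, stats$n_negative,
              if (is.null(surv)) NA_integer_ else nrow(surv$models),
              if (is.null(surv)) NA_integer_
              else sum(surv$models$significant)),
    stringsAsFactors = FALSE
  )
  res <- list(preprocessed = pp, pairs = pairs, dms = dms,
              summary = summary, network = net, stats = stats,
              survival = surv, manifest = manifest, subtype = subtype,
              thresholds = thresholds)
  if (!is.null(out_dir)) write_subtype_outputs(res, out_dir)
  res
}

write_subtype_outputs <- function(res, out_dir) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  s <- res$subtype
  fp <- function(name) file.path(out_dir, sprintf("%s_%s.tsv", name, s))
  write_tsv(res$pairs, fp("probe_gene_pairs"))
  write_tsv(res$dms$records, fp("dms_probes"))
  write_tsv(res$dms$links, fp("dms_probe_gene_links"))
  write_tsv(res$summary$by_class, fp("dms_summary_by_class"))
  write_tsv(res$summary$per_gene, fp("dms_per_gene"))
  write_tsv(res$network$edges, fp("eqtm_edges"))
  write_sif(res$network, file.path(out_dir, sprintf("network_%s.sif", s)))
  write_graphml(res$network,
                file.path(out_dir, sprintf("network_%s.graphml", s)))
  write_node_attributes(res$network, fp("network_nodes"))
  if (!is.null(res$survival)) {
    write_tsv(res$survival$models, fp("survival_models"))
    write_tsv(res$survival$skipped, fp("survival_skipped"))
    sig <- res$survival$models$gene_id[res$survival$models$significant]
    for (g in sig) {
      km <- res$survival$fits[[g]]$km
      write_tsv(km, file.path(out_dir,
                              sprintf("km_%s_%s.tsv", s, gsub("[^A-Za-z0-9_.-]", "_", g))))
    }
  }
  write_tsv(res$manifest, fp("manifest"))
  invisible(out_dir)
}

#' Compare two completed subtype runs
#'
#' Checks the runs share one annotation universe, compares their
#' networks ([compare_networks()]) and writes a structured report.
#'
#' @param res_a,res_b results of [run_subtype()].
#' @param out_dir optional output directory for the report files.
#' @return the [compare_networks()] result.
#' @export
run_compare <- function(res_a, res_b, out_dir = NULL) {
  ua <- sort(unique(res_a$pairs$probe_id))
  ub <- sort(unique(res_b$pairs$probe_id))
  if (!identical(ua, ub) ||
      !identical(sort(unique(res_a$pairs$gene_id)),
                 sort(unique(res_b$pairs$gene_id))))
    stop("run_compare: the two runs use different annotation universes",
         call. = FALSE)
  cmp <- compare_networks(res_a$network, res_b$network)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir))
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(cmp$per_gene, file.path(out_dir, "common_gene_dms_counts.tsv"))
    write_tsv(cmp$probe_signs, file.path(out_dir, "common_probe_signs.tsv"))
    write_tsv(cmp$common_edges, file.path(out_dir, "common_edges.tsv"))
    jsonlite::write_json(
      list(common_genes = cmp$common_genes,
           specific_genes_a = cmp$specific_genes_a,
           specific_genes_b = cmp$specific_genes_b,
           common_probes = cmp$common_probes,
           specific_probes_a = cmp$specific_probes_a,
           specific_probes_b = cmp$specific_probes_b,
           opposite_fraction = round(cmp$opposite_fraction, 2),
           n_tie_excluded = cmp$n_tie_excluded),
      file.path(out_dir, "comparison.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  cmp
}

#' Run a whole synthetic study end to end
#'
#' Convenience wrapper: simulates (or loads) a study, runs each subtype
#' and, for two-subtype studies, the cross-subtype comparison.
#'
#' @param config a [sim_config()] object.
#' @param subtypes 1 or 2 subtype labels.
#' @param thresholds an [eqtm_thresholds()] object.
#' @param out_dir optional output directory.
#' @return list with per-subtype results and `comparison` (or `NULL`).
#' @export
run_study <- function(config, subtypes = c("A", "B"),
                      thresholds = eqtm_thresholds(), out_dir = NULL) {
  study <- simulate_study(config, subtypes)
  runs <- list()
  for (s in subtypes) {
    d <- study$subtypes[[s]]
    runs[[s]] <- run_subtype(study$genes, study$probes,
                             d$beta_tumor, d$beta_normal,
                             d$expr_tumor, d$expr_normal, d$clinical,
                             thresholds, subtype = s,
                             out_dir = out_dir)
  }
  comparison <- if (length(subtypes) == 2L) {
    run_compare(runs[[subtypes[1]]], runs[[subtypes[2]]],
                out_dir = out_dir)
  } else NULL
  list(study = study, runs = runs, comparison = comparison)
}

#' Load a study bundle written by [generate_study()]
#'
#' @param dir bundle directory.
#' @param subtype subtype label to load.
#' @return list with `genes`, `probes`, matrices, `clinical` (NULL when
#'   the file is missing) and `truth`.
#' @export
load_study <- function(dir, subtype = "A") {
  clin_path <- file.path(dir, paste0("clinical_", subtype, ".tsv"))
  list(
    genes = read_gtf(file.path(dir, "annotation.gtf")),
    probes = read_probe_manifest(file.path(dir, "probes.tsv")),
    beta_tumor = read_matrix_tsv(file.path(dir, paste0("beta_tumor_", subtype, ".tsv"))),
    beta_normal = read_matrix_tsv(file.path(dir, paste0("beta_normal_", subtype, ".tsv"))),
    expr_tumor = read_matrix_tsv(file.path(dir, paste0("expr_tumor_", subtype, ".tsv"))),
    expr_normal = read_matrix_tsv(file.path(dir, paste0("expr_normal_", subtype, ".tsv"))),
    clinical = if (file.exists(clin_path)) read_clinical(clin_path) else NULL,
    truth = jsonlite::read_json(file.path(dir, paste0("truth_", subtype, ".json")),
                                simplifyVector = TRUE)
  )
}
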