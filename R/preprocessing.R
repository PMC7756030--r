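#' Remove genes with zero expression in every sample
#'
#' @param expr raw-scale expression matrix (genes x samples).
#' @return list with `matrix` (filtered), `removed` (character vector of
#'   dropped gene ids).
#' @export
filter_zero_genes <- function(expr) {
  stopifnot(is.matrix(expr))
  all_zero <- rowSums(expr != 0, na.rm = TRUE) == 0L
  if (all(all_zero))
    stop("filter_zero_genes: every gene is zero in all samples",
         call. = FALSE)
  list(matrix = expr[!all_zero, , drop = FALSE],
       removed = rownames(expr)[all_zero])
}

#' Replace remaining zeros by the matrix minimum positive value, then log2
#'
#' Zeros are set to the smallest positive value observed anywhere in the
#' matrix (computed per dataset, i.e. over all samples of the cohort pair
#' being processed), after which every entry is log2-transformed.  The
#' output contains no zero, `NA` or `-Inf` entries, and the within-matrix
#' value ordering is preserved (ties are created only at the replaced
#' minimum).
#'
#' @param expr raw-scale expression matrix with all-zero rows already
#'   removed.
#' @return log2-scale expression matrix.
#' @export
log2_with_zero_replacement <- function(expr) {
  stopifnot(is.matrix(expr))
  pos <- expr[!is.na(expr) & expr > 0]
  if (length(pos) == 0L)
    stop("log2_with_zero_replacement: no positive values in matrix",
         call. = FALSE)
  min_pos <- min(pos)
  expr[!is.na(expr) & expr == 0] <- min_pos
  log2(expr)
}

#' Remove probes that are NA in every sample
#'
#' Probes with at least one observed beta are kept; only fully missing
#' rows are dropped.
#'
#' @param beta methylation beta matrix (probes x samples).
#' @return list with `matrix` (filtered), `removed` (dropped probe ids).
#' @export
filter_all_na_probes <- function(beta) {
  stopifnot(is.matrix(beta))
  all_na <- rowSums(!is.na(beta)) == 0L
  list(matrix = beta[!all_na, , drop = FALSE],
       removed = rownames(beta)[all_na])
}

#' Preprocess one subtype's expression and methylation matrices
#'
#' Applies the cohort-pair filters in the documented scope: the zero-gene
#' filter and the zero-replacement minimum act on the combined
#' tumor+normal expression matrix of the subtype, and the all-NA probe
#' filter acts on the combined beta matrix, so both conditions share one
#' feature universe.
#'
#' @param expr_tumor,expr_normal raw expression matrices with identical
#'   gene rows.
#' @param beta_tumor,beta_normal beta matrices with identical probe rows.
#' @return list with log2 `expr_tumor`/`expr_normal`, filtered
#'   `beta_tumor`/`beta_normal`, and `removed_genes`/`removed_probes`.
#' @export
preprocess_subtype <- function(expr_tumor, expr_normal,
                               beta_tumor, beta_normal) {
  stopifnot(identical(rownames(expr_tumor), rownames(expr_normal)),
            identical(rownames(beta_tumor), rownames(beta_normal)))
  expr_all <- cbind(expr_tumor, expr_normal)
  fz <- filter_zero_genes(expr_all)
  logged <- log2_with_zero_replacement(fz$matrix)
  nt <- ncol(expr_tumor)
  fn <- filter_all_na_probes(cbind(beta_tumor, beta_normal))
  keep_probes <- rownames(fn$matrix)
  list(
    expr_tumor = logged[, seq_len(nt), drop = FALSE],
    expr_normal = logged[, -seq_len(nt), drop = FALSE],
    beta_tumor = beta_tumor[keep_probes, , drop = FALSE],
    beta_normal = beta_normal[keep_probes, , drop = FALSE],
    removed_genes = fz$removed,
    removed_probes = fn$removed
  )
}
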