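#' Two-sample t-test for a single CpG probe
#'
#' Student's two-tailed two-sample test on beta values, pooled variance by
#' default (Welch optional).  NAs are dropped within each group.
#'
#' @param tumor_values,normal_values numeric vectors of beta values.
#' @param var_equal pooled-variance Student test (default) or Welch.
#' @return list with `t_stat`, `p_value`, `mean_tumor`, `mean_normal`,
#'   `delta` and `testable`.  A probe is untestable when either group has
#'   fewer than 2 observed values, or both groups are constant (the
#'   degenerate zero-variance case with unequal means).
#' @export
test_probe <- function(tumor_values, normal_values, var_equal = TRUE) {
  x <- tumor_values[!is.na(tumor_values)]
  y <- normal_values[!is.na(normal_values)]
  mt <- if (length(x)) mean(x) else NA_real_
  mn <- if (length(y)) mean(y) else NA_real_
  out <- list(t_stat = NA_real_, p_value = NA_real_,
              mean_tumor = mt, mean_normal = mn,
              delta = mt - mn, testable = FALSE)
  if (length(x) < 2L || length(y) < 2L) return(out)
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    if (mt == mn) {
      out$t_stat <- 0; out$p_value <- 1; out$testable <- TRUE
    }
    return(out)
  }
  nx <- length(x); ny <- length(y)
  if (var_equal) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  tt <- (mt - mn) / se
  out$t_stat <- tt
  out$p_value <- 2 * stats::pt(-abs(tt), df)
  out$testable <- TRUE
  out
}

# Vectorised row-wise two-sample t (pooled or Welch) used by call_dms.
# Returns a data.frame aligned with the rows of the inputs.
row_ttest <- function(mat_tumor, mat_normal, var_equal = TRUE) {
  nT <- rowSums(!is.na(mat_tumor))
  nN <- rowSums(!is.na(mat_normal))
  mT <- rowMeans(mat_tumor, na.rm = TRUE)
  mN <- rowMeans(mat_normal, na.rm = TRUE)
  vT <- rowSums((mat_tumor - mT)^2, na.rm = TRUE) / pmax(nT - 1, 1)
  vN <- rowSums((mat_normal - mN)^2, na.rm = TRUE) / pmax(nN - 1, 1)
  testable <- nT >= 2L & nN >= 2L
  if (var_equal) {
    sp2 <- ((nT - 1) * vT + (nN - 1) * vN) / (nT + nN - 2)
    se <- sqrt(sp2 * (1 / nT + 1 / nN))
    df <- nT + nN - 2
  } else {
    se <- sqrt(vT / nT + vN / nN)
    df <- (vT / nT + vN / nN)^2 /
      ((vT / nT)^2 / pmax(nT - 1, 1) + (vN / nN)^2 / pmax(nN - 1, 1))
  }
  tt <- (mT - mN) / se
  p <- 2 * stats::pt(-abs(tt), df)
  zero_var <- testable & (vT + vN) == 0
  eq <- zero_var & (mT == mN)
  tt[eq] <- 0; p[eq] <- 1
  testable[zero_var & !eq] <- FALSE
  tt[!testable] <- NA_real_; p[!testable] <- NA_real_
  data.frame(t_stat = tt, p_value = p, mean_tumor = mT, mean_normal = mN,
             delta = mT - mN, n_tumor = nT, n_normal = nN,
             testable = testable)
}

#' Call differential methylation sites between tumor and normal cohorts
#'
#' Tests every lncRNA-mapped probe shared by both matrices with a
#' two-tailed two-sample t-test, applies Benjamini-Hochberg FDR over the
#' testable mapped probes jointly, and emits probes with `fdr_q <
#' fdr_alpha` and `|delta| > delta_beta` (both strict).  Probes without a
#' gene mapping never enter the test family.
#'
#' @param beta_tumor,beta_normal beta matrices sharing a probe universe.
#' @param pairs probe-gene pairs from [map_probes()].
#' @param thresholds an [eqtm_thresholds()] object.
#' @return list with `records` (probe-level data.frame of DMSs, with
#'   `direction` = "up" iff delta > 0), `links` (one row per DMS
#'   probe-gene pair), `tested` (all testable probes with q-values) and
#'   `untestable` (probe ids excluded, with reason).
#' @export
call_dms <- function(beta_tumor, beta_normal, pairs,
                     thresholds = eqtm_thresholds()) {
  stopifnot(inherits(thresholds, "eqtm_thresholds"))
  common <- intersect(rownames(beta_tumor), rownames(beta_normal))
  mapped <- intersect(common, unique(pairs$probe_id))
  if (length(mapped) == 0L)
    stop("call_dms: no mapped probes shared by both matrices",
         call. = FALSE)
  tt <- row_ttest(beta_tumor[mapped, , drop = FALSE],
                  beta_normal[mapped, , drop = FALSE],
                  var_equal = thresholds$var_equal)
  tt$probe_id <- mapped
  untestable <- data.frame(
    probe_id = tt$probe_id[!tt$testable],
    reason = rep("fewer than 2 observations per group or zero variance in both groups",
                 sum(!tt$testable)),
    stringsAsFactors = FALSE)
  tested <- tt[tt$testable, , drop = FALSE]
  if (nrow(tested) == 0L)
    stop("call_dms: zero testable probes", call. = FALSE)
  tested$fdr_q <- stats::p.adjust(tested$p_value, method = "BH")
  hit <- tested$fdr_q < thresholds$fdr_alpha &
    abs(tested$delta) > thresholds$delta_beta
  records <- tested[hit, , drop = FALSE]
  records$direction <- ifelse(records$delta > 0, "up", "down")
  cols <- c("probe_id", "mean_tumor", "mean_normal", "delta", "t_stat",
            "p_value", "fdr_q", "direction", "n_tumor", "n_normal")
  records <- records[, cols]
  rownames(records) <- NULL
  links <- merge(records, pairs[, c("probe_id", "gene_id", "biotype_class")],
                 by = "probe_id", sort = FALSE)
  links <- links[order(links$probe_id, links$gene_id), ]
  rownames(links) <- NULL
  list(records = records, links = links,
       tested = tested[, c("probe_id", setdiff(colnames(tested), "probe_id"))],
       untestable = untestable)
}

#' Summarise DMS calls per lncRNA biotype class
#'
#' A probe mapped to genes of both classes contributes to each class; a
#' probe mapped to several genes of one class is counted once in that
#' class's DMS tally, while every distinct gene enters the gene tally.
#'
#' @param dms result of [call_dms()].
#' @return list with `by_class` (per-class DMS count, gene count and
#'   percent upregulated; percent is NA for an empty class) and
#'   `per_gene` (distinct DMS probes per gene, ranked).
#' @export
summarize_dms <- function(dms) {
  links <- dms$links
  classes <- c("lincRNA", "other_lncRNA")
  by_class <- do.call(rbind, lapply(classes, function(cl) {
    sub <- links[links$biotype_class == cl, , drop = FALSE]
    probes <- unique(sub$probe_id)
    dirs <- dms$records$direction[match(probes, dms$records$probe_id)]
    data.frame(
      biotype_class = cl,
      n_dms = length(probes),
      n_genes = length(unique(sub$gene_id)),
      pct_up = if (length(probes)) 100 * mean(dirs == "up") else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
  if (nrow(links)) {
    per_gene <- stats::aggregate(probe_id ~ gene_id + biotype_class,
                                 data = links,
                                 FUN = function(p) length(unique(p)))
    names(per_gene)[3L] <- "n_dms"
    per_gene <- per_gene[order(-per_gene$n_dms, per_gene$gene_id), ]
    rownames(per_gene) <- NULL
  } else {
    per_gene <- data.frame(gene_id = character(), biotype_class = character(),
                           n_dms = integer(), stringsAsFactors = FALSE)
  }
  list(by_class = by_class, per_gene = per_gene)
}
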