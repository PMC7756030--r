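#' Read a feature x sample matrix from TSV
#'
#' First column holds feature ids, header holds sample ids, `NA` is the
#' missing-value literal.
#'
#' @param path TSV file path.
#' @return numeric matrix with feature rownames and sample colnames.
#' @export
read_matrix_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = "NA", data.table = FALSE)
  if (ncol(dt) < 2L)
    stop("matrix file `", path, "` needs a feature column plus >=1 sample",
         call. = FALSE)
  ids <- as.character(dt[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate feature ids in `", path, "`", call. = FALSE)
  m <- as.matrix(dt[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Write a feature x sample matrix to TSV
#'
#' @param m numeric matrix with rownames and colnames.
#' @param path output path.
#' @param id_col name for the feature-id column.
#' @export
write_matrix_tsv <- function(m, path, id_col = "feature_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_col
  data.table::fwrite(df, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a CpG probe manifest
#'
#' Expects columns `probe_id`, `chrom`, `pos` (1-based CpG coordinate) and
#' optionally `strand`.
#'
#' @param path TSV path.
#' @return data.frame of probe annotation.
#' @export
read_probe_manifest <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  need <- c("probe_id", "chrom", "pos")
  if (!all(need %in% colnames(df)))
    stop("probe manifest `", path, "` must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$probe_id))
    stop("duplicate probe_id in manifest `", path, "`", call. = FALSE)
  if (any(df$pos < 1L))
    stop("probe positions must be 1-based (>= 1)", call. = FALSE)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df
}

#' Read a clinical follow-up table
#'
#' Expects columns `sample_id`, `time` (positive follow-up duration) and
#' `event` (1 = death observed, 0 = censored).
#'
#' @param path TSV path.
#' @return data.frame of clinical records.
#' @export
read_clinical <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  need <- c("sample_id", "time", "event")
  if (!all(need %in% colnames(df)))
    stop("clinical file `", path, "` must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (any(df$time <= 0))
    stop("clinical follow-up times must be positive", call. = FALSE)
  if (!all(df$event %in% c(0L, 1L)))
    stop("clinical `event` must be 0/1", call. = FALSE)
  df
}

#' Write a data.frame as TSV with NA literal
#'
#' @param df data.frame.
#' @param path output path.
#' @export
write_tsv <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

# GENCODE-dialect gene lines; coordinates 1-based inclusive.
write_gtf <- function(genes, path) {
  attrs <- sprintf(
    'gene_id "%s"; gene_name "%s"; gene_type "%s";',
    genes$gene_id, genes$symbol, genes$biotype_raw)
  lines <- paste(genes$chrom, "lnceqtm_sim", "gene",
                 genes$start, genes$end, ".", genes$strand, ".",
                 attrs, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
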