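#' Default non-lincRNA lncRNA biotypes
#'
#' GENCODE biotype strings treated as "other lncRNA".  The list is
#' configurable in [classify_biotype()] and [read_gtf()]; the default
#' covers antisense, sense_overlapping and transcribed pseudogene classes
#' plus the other common lncRNA biotypes of the GENCODE dialect.
#'
#' @export
OTHER_LNCRNA_BIOTYPES <- c(
  "antisense", "sense_overlapping", "sense_intronic",
  "transcribed_processed_pseudogene", "transcribed_unprocessed_pseudogene",
  "processed_transcript", "3prime_overlapping_ncRNA",
  "bidirectional_promoter_lncRNA", "macro_lncRNA", "lncRNA"
)

#' Classify a raw biotype string into lincRNA / other_lncRNA
#'
#' @param biotype_raw character vector of GENCODE `gene_type` strings.
#' @param other_biotypes biotypes mapped to `other_lncRNA`.
#' @return character vector with values `"lincRNA"`, `"other_lncRNA"` or
#'   `NA` for biotypes that are not lncRNAs (excluded).
#' @export
classify_biotype <- function(biotype_raw,
                             other_biotypes = OTHER_LNCRNA_BIOTYPES) {
  out <- rep(NA_character_, length(biotype_raw))
  out[biotype_raw == "lincRNA"] <- "lincRNA"
  out[biotype_raw %in% setdiff(other_biotypes, "lincRNA")] <- "other_lncRNA"
  out
}

#' Read lncRNA gene annotation from a GTF file
#'
#' Parses GENCODE-dialect gene lines and keeps genes whose `gene_type` is
#' an accepted lncRNA biotype; other biotypes are dropped with a message
#' giving the count.
#'
#' @param path GTF path.
#' @param other_biotypes see [classify_biotype()].
#' @return data.frame with columns `gene_id`, `symbol`, `chrom`, `start`,
#'   `end`, `strand`, `biotype_raw`, `biotype_class` (1-based inclusive
#'   coordinates).
#' @export
read_gtf <- function(path, other_biotypes = OTHER_LNCRNA_BIOTYPES) {
  if (!file.exists(path)) stop("GTF file not found: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  if ("type" %in% colnames(md)) {
    keep <- as.character(md$type) == "gene"
    gr <- gr[keep]
    md <- S4Vectors::mcols(gr)
  }
  if (length(gr) == 0L)
    stop("no gene records in GTF `", path, "`", call. = FALSE)
  if (!"gene_id" %in% colnames(md) || anyNA(md$gene_id))
    stop("GTF `", path, "` has gene records without a gene_id attribute",
         call. = FALSE)
  biotype <- if ("gene_type" %in% colnames(md)) as.character(md$gene_type)
             else as.character(md$gene_biotype)
  cls <- classify_biotype(biotype, other_biotypes)
  dropped <- sum(is.na(cls))
  if (dropped > 0L)
    message("read_gtf: dropped ", dropped,
            " gene(s) with non-lncRNA biotypes")
  keep <- !is.na(cls)
  symbol <- if ("gene_name" %in% colnames(md)) as.character(md$gene_name)
            else as.character(md$gene_id)
  out <- data.frame(
    gene_id = as.character(md$gene_id)[keep],
    symbol = symbol[keep],
    chrom = as.character(GenomicRanges::seqnames(gr))[keep],
    start = GenomicRanges::start(gr)[keep],
    end = GenomicRanges::end(gr)[keep],
    strand = as.character(GenomicRanges::strand(gr))[keep],
    biotype_raw = biotype[keep],
    biotype_class = cls[keep],
    stringsAsFactors = FALSE
  )
  out$strand[!out$strand %in% c("+", "-")] <- "+"
  rownames(out) <- NULL
  out
}

#' Strip a trailing GENCODE version suffix from gene ids
#'
#' `ENSG00000123456.7` becomes `ENSG00000123456`; ids without a version
#' are returned unchanged.
#'
#' @param ids character vector of gene ids.
#' @export
strip_gene_version <- function(ids) {
  sub("\\.[0-9]+$", "", ids)
}

#' Map CpG probes to overlapping lncRNA gene spans
#'
#' A probe maps to a gene when it lies on the same chromosome and its
#' position falls inside the gene span, boundaries inclusive.  Probes
#' overlapping k genes yield k pairs; strand is ignored.
#'
#' @param probes data.frame with `probe_id`, `chrom`, `pos`.
#' @param genes data.frame as returned by [read_gtf()].
#' @param flank symmetric extension (bp) of each gene span before
#'   overlap; 0 keeps the plain gene body.
#' @return data.frame with columns `probe_id`, `gene_id`, `biotype_class`,
#'   sorted by (chrom, pos, gene_id).
#' @export
map_probes <- function(probes, genes, flank = 0L) {
  if (nrow(probes) == 0L || nrow(genes) == 0L)
    stop("map_probes: probe and gene tables must be non-empty",
         call. = FALSE)
  pc <- unique(probes$chrom)
  gc <- unique(genes$chrom)
  if (length(intersect(pc, gc)) == 0L) {
    has_chr <- function(x) any(grepl("^chr", x))
    if (has_chr(pc) != has_chr(gc))
      stop("chromosome naming mismatch: probes use `", pc[1],
           "`-style names but genes use `", gc[1],
           "`-style names; harmonise the dialects before mapping",
           call. = FALSE)
  }
  probe_gr <- GenomicRanges::GRanges(
    seqnames = probes$chrom,
    ranges = IRanges::IRanges(start = probes$pos, width = 1L))
  gene_gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = pmax(1L, genes$start - flank),
                              end = genes$end + flank))
  hits <- GenomicRanges::findOverlaps(probe_gr, gene_gr,
                                      ignore.strand = TRUE)
  pi <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  out <- data.frame(
    probe_id = probes$probe_id[pi],
    gene_id = genes$gene_id[gi],
    biotype_class = genes$biotype_class[gi],
    chrom = probes$chrom[pi],
    pos = probes$pos[pi],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$pos, out$gene_id), ]
  rownames(out) <- NULL
  out[, c("probe_id", "gene_id", "biotype_class", "chrom", "pos")]
}

#' Export probe positions as BED
#'
#' BED uses 0-based half-open coordinates, so a CpG at 1-based position p
#' becomes the interval [p-1, p).
#'
#' @param probes data.frame with `probe_id`, `chrom`, `pos`.
#' @param path output path.
#' @export
write_probe_bed <- function(probes, path) {
  bed <- data.frame(chrom = probes$chrom,
                    start = probes$pos - 1L,
                    end = probes$pos,
                    name = probes$probe_id,
                    stringsAsFactors = FALSE)
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
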