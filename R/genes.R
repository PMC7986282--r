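# Gene models and representative-TSS selection.
#
# Gene tables are plain data.frames with columns:
#   gene_id, chrom, strand (+/-), cds_start, cds_end (0-based half-open),
#   tss (0-based coordinate of the first transcribed base, NA when unknown),
#   essential (logical, NA allowed), mode ("TSS" or "CDS").

.checkGenes <- function(genes) {
  need <- c("gene_id", "chrom", "strand", "cds_start", "cds_end")
  miss <- setdiff(need, names(genes))
  if (length(miss)) stop("gene table missing columns: ", paste(miss, collapse = ", "))
  if (any(!genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(genes$cds_start >= genes$cds_end)) stop("cds_start must be < cds_end")
  if (is.null(genes$tss)) genes$tss <- NA_integer_
  if (is.null(genes$essential)) genes$essential <- NA
  genes$mode <- ifelse(is.na(genes$tss), "CDS", "TSS")
  genes
}

#' Read gene models from a BED-like TSV
#'
#' Six tab-separated columns without header, BED-style:
#' chrom, cds_start, cds_end (0-based half-open), gene_id, essential
#' (0/1 or `.` for unknown), strand.
#'
#' @param path Input file.
#' @return data.frame of gene models (TSS unset; see [annotateTss()]).
#' @export
readGeneModels <- function(path) {
  d <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                  col.names = c("chrom", "cds_start", "cds_end", "gene_id",
                                "essential", "strand"))
  ess <- suppressWarnings(as.integer(d$essential))
  genes <- data.frame(gene_id = as.character(d$gene_id),
                      chrom = as.character(d$chrom),
                      strand = as.character(d$strand),
                      cds_start = as.integer(d$cds_start),
                      cds_end = as.integer(d$cds_end),
                      tss = NA_integer_,
                      essential = ifelse(is.na(ess), NA, ess == 1L),
                      stringsAsFactors = FALSE)
  .checkGenes(genes)
}

#' Write gene models as a BED-like TSV
#' @param genes Gene table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeGeneModels <- function(genes, path) {
  ess <- ifelse(is.na(genes$essential), ".", as.integer(genes$essential))
  write.table(data.frame(genes$chrom, genes$cds_start, genes$cds_end,
                         genes$gene_id, ess, genes$strand),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a transcript-isoform TSS table
#'
#' Tab-separated with header: gene_id, chrom, position (0-based coordinate of
#' the first transcribed base), count (supporting read count).
#'
#' @param path Input file.
#' @return data.frame with those columns.
#' @export
readTssTable <- function(path) {
  d <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "position", "count")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("TSS table missing columns: ", paste(miss, collapse = ", "))
  if (any(d$count < 0)) stop("TSS read counts must be non-negative")
  d
}

#' Write a TSS table
#' @param tss data.frame with gene_id, chrom, position, count.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeTssTable <- function(tss, path) {
  write.table(tss, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# 0-based position of the first CDS base in transcription direction.
.cdsAnchor <- function(gene) {
  if (gene$strand == "+") gene$cds_start else gene$cds_end - 1L
}

# Gene anchor: TSS when annotated, else CDS start.
.anchor <- function(gene) {
  if (!is.na(gene$tss)) gene$tss else .cdsAnchor(gene)
}

#' Representative TSS for one gene
#'
#' Among the isoform rows of a gene, picks the modal (highest read count)
#' transcription start site. Ties are broken by proximity to the CDS start,
#' then by smaller genomic coordinate, so selection is deterministic under
#' row permutation. Returns `NA` when the gene has no isoform rows (the gene
#' then falls back to CDS-anchored design).
#'
#' @param tss TSS table (all genes; filtered internally).
#' @param gene One-row gene data.frame.
#' @return Integer coordinate or `NA`.
#' @export
selectRepresentativeTss <- function(tss, gene) {
  rows <- tss[tss$gene_id == gene$gene_id, , drop = FALSE]
  if (!nrow(rows)) return(NA_integer_)
  rows <- rows[rows$count == max(rows$count), , drop = FALSE]
  if (nrow(rows) > 1L) {
    d <- abs(rows$position - .cdsAnchor(gene))
    rows <- rows[order(d, rows$position), , drop = FALSE]
  }
  as.integer(rows$position[1])
}

#' Annotate genes with representative TSSs
#'
#' Sets `tss` and `mode` for every gene with isoform evidence; genes without
#' any isoform keep `mode = "CDS"`.
#'
#' @param genes Gene table.
#' @param tss TSS table.
#' @return Updated gene table.
#' @export
annotateTss <- function(genes, tss) {
  genes <- .checkGenes(genes)
  for (i in seq_len(nrow(genes))) {
    genes$tss[i] <- selectRepresentativeTss(tss, genes[i, , drop = FALSE])
  }
  genes$mode <- ifelse(is.na(genes$tss), "CDS", "TSS")
  genes
}
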