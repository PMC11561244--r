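#' Assign genomic region labels to sites
#'
#' Labels each site with exactly one region by fixed priority
#' `CDS > UTR3 > UTR5 > INTRON > INTERGENIC`: a recoding (CDS) context wins
#' over untranslated regions, exonic contexts win over intronic, and a site
#' outside every annotated gene is `INTERGENIC`. `INTRON` means inside a
#' gene body but in no exon.
#'
#' @param x an [EditingMatrix-class], or a data.frame with `chrom` and `pos`
#'   columns.
#' @param genes gene model as a [GenomicRanges::GRanges] with a `type`
#'   column using GFF3 terms (`gene`, `exon`, `CDS`, `five_prime_UTR`,
#'   `three_prime_UTR`), e.g. the `genes` element of [generateReference()]
#'   or an imported GFF3.
#' @return `x` with a `region` column added (for an `EditingMatrix`, in its
#'   `rowData`).
#' @export
annotateRegion <- function(x, genes) {
  if (is(x, "EditingMatrix")) {
    rd <- SummarizedExperiment::rowData(x)
    rd$region <- .annotate_positions(rd$chrom, rd$pos, genes)
    SummarizedExperiment::rowData(x) <- rd
    return(x)
  }
  stopifnot(is.data.frame(x), all(c("chrom", "pos") %in% names(x)))
  x$region <- .annotate_positions(x$chrom, x$pos, genes)
  x
}

.annotate_positions <- function(chrom, pos, genes) {
  sites <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  hit <- function(type) {
    feats <- genes[genes$type %in% type]
    GenomicRanges::countOverlaps(sites, feats, ignore.strand = TRUE) > 0
  }
  in_cds <- hit("CDS")
  in_utr3 <- hit("three_prime_UTR")
  in_utr5 <- hit("five_prime_UTR")
  in_gene <- hit("gene")
  ifelse(in_cds, "CDS",
  ifelse(in_utr3, "UTR3",
  ifelse(in_utr5, "UTR5",
  ifelse(in_gene, "INTRON", "INTERGENIC"))))
}
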