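#' Read aligned reads from a SAM or BAM file
#'
#' Loads single-end alignments with everything downstream quantification
#' needs: read id, flag, mapping quality, base calls, base qualities, and
#' `CB`/`UB` (cell barcode / UMI) tags when present. SAM input is converted
#' through BAM internally.
#'
#' @param path a `.sam` or `.bam` file.
#' @return a [GenomicAlignments::GAlignments] with metadata columns
#'   `qname`, `flag`, `mapq`, `seq`, `qual`, `CB`, `UB`.
#' @export
readAlignments <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(path, destination = tempfile(),
                             overwrite = TRUE, indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "mapq", "seq", "qual"),
    tag = c("CB", "UB"))
  GenomicAlignments::readGAlignments(path, param = param)
}

# TRUE if alignments are coordinate-sorted.
.is_sorted <- function(aln) {
  if (length(aln) < 2L) return(TRUE)
  sq <- as.integer(GenomicRanges::seqnames(aln))
  st <- GenomicRanges::start(aln)
  all(diff(sq) > 0 | (diff(sq) == 0 & diff(st) >= 0))
}

#' Write a GAlignments back to SAM
#'
#' Used to persist pseudobulk splits and deduplicated streams. Requires the
#' metadata columns produced by [readAlignments()].
#'
#' @param aln a [GenomicAlignments::GAlignments] with `qname`, `flag`,
#'   `mapq`, `seq`, `qual` (and optionally `CB`, `UB`) metadata columns.
#' @param path output SAM path.
#' @return invisibly, `path`.
#' @export
writeAlignments <- function(aln, path) {
  mc <- S4Vectors::mcols(aln)
  sl <- GenomeInfoDb::seqlengths(aln)
  if (any(is.na(sl)))
    sl[is.na(sl)] <- vapply(names(sl)[is.na(sl)], function(ch)
      max(GenomicRanges::end(aln)[as.character(
        GenomicRanges::seqnames(aln)) == ch], 0L), numeric(1))
  reads <- data.frame(
    qname = mc$qname, flag = mc$flag,
    chrom = as.character(GenomicRanges::seqnames(aln)),
    pos = GenomicRanges::start(aln), mapq = mc$mapq,
    cigar = GenomicAlignments::cigar(aln),
    seq = as.character(mc$seq), qual = as.character(mc$qual))
  if (!is.null(mc$CB)) reads$cb <- mc$CB
  if (!is.null(mc$UB)) reads$ub <- mc$UB
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(sl), as.integer(sl)))
  ord <- order(match(reads$chrom, names(sl)), reads$pos)
  reads <- reads[ord, , drop = FALSE]
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                  reads$qname, reads$flag, reads$chrom, reads$pos,
                  reads$mapq, reads$cigar, reads$seq, reads$qual)
  if (!is.null(reads$cb)) {
    has <- !is.na(reads$cb)
    body[has] <- paste0(body[has], "\tCB:Z:", reads$cb[has])
  }
  if (!is.null(reads$ub)) {
    has <- !is.na(reads$ub)
    body[has] <- paste0(body[has], "\tUB:Z:", reads$ub[has])
  }
  writeLines(c(header, body), path)
  invisible(path)
}
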