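#' Compute the Alu Editing Index
#'
#' The Alu Editing Index (AEI) is a global editing measure: over every
#' unmasked position inside the supplied stranded Alu intervals whose
#' strand-frame reference base is adenosine, it accumulates
#' `numerator += edited (G-frame) read bases` and
#' `denominator += A+G-frame read bases`, then reports
#' `aei = numerator / denominator`. On a `+` interval that means ref-`A`
#' positions contribute `n_G` and `n_A + n_G`; on a `-` interval ref-`T`
#' positions contribute `n_C` and `n_T + n_C`. Positions in the SNP panel
#' are skipped entirely. Because it aggregates mismatches rather than
#' calling individual sites, the AEI remains robust at the shallow,
#' 3'-biased coverage of droplet single-cell data.
#'
#' Each interval is processed in its own strand frame, so overlapping
#' antisense Alus each contribute independently at shared positions.
#'
#' @param aln coordinate-sorted [GenomicAlignments::GAlignments].
#' @param alu stranded [GenomicRanges::GRanges] of Alu intervals.
#' @param reference [Biostrings::DNAStringSet] of the genome.
#' @param snps optional SNP panel data.frame (`chrom`, `pos`).
#' @param config a [quantConfig()].
#' @param sample_id label for the output row.
#' @return one-row data.frame: `sample_id`, `numerator`, `denominator`,
#'   `aei`. A zero denominator yields `aei = NA` (flagged, not an error).
#' @export
computeAEI <- function(aln, alu, reference, snps = NULL,
                       config = quantConfig(), sample_id = "sample") {
  counts <- pileupBases(aln, region = alu, reference = reference,
                        config = config)
  num <- 0; den <- 0
  if (nrow(counts)) {
    snp_key <- if (is.null(snps) || !nrow(snps)) character(0) else
      paste0(snps$chrom, ":", snps$pos)
    cnt_key <- paste0(counts$chrom, ":", counts$pos)
    for (i in seq_along(alu)) {
      ch <- as.character(GenomicRanges::seqnames(alu))[i]
      st <- as.character(GenomicRanges::strand(alu))[i]
      lo <- GenomicRanges::start(alu)[i]
      hi <- GenomicRanges::end(alu)[i]
      sel <- counts$chrom == ch & counts$pos >= lo & counts$pos <= hi
      if (!any(sel)) next
      sub <- counts[sel, , drop = FALSE]
      refb <- strsplit(as.character(
        Biostrings::subseq(reference[[ch]], lo, hi)), "")[[1]]
      want <- if (st == "+") "A" else "T"
      isA <- refb[sub$pos - lo + 1L] == want
      notsnp <- !(cnt_key[sel] %in% snp_key)
      use <- isA & notsnp
      if (!any(use)) next
      if (st == "+") {
        num <- num + sum(sub$n_G[use])
        den <- den + sum(sub$n_A[use] + sub$n_G[use])
      } else {
        num <- num + sum(sub$n_C[use])
        den <- den + sum(sub$n_T[use] + sub$n_C[use])
      }
    }
  }
  data.frame(sample_id = sample_id, numerator = num, denominator = den,
             aei = if (den > 0) num / den else NA_real_)
}
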