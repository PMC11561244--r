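#' Call editing levels at cataloged sites
#'
#' Looks up each catalog site in a masked pileup and calls its editing
#' level in the site's strand frame: for a `+` site coverage is
#' `n_A + n_G` and the edited count `n_G`; for a `-` site coverage is
#' `n_T + n_C` and the edited count `n_C` (an A-to-I edit on the minus
#' strand reads as T-to-C in reference frame). Reads carrying other bases
#' at the site are treated as errors or variants and excluded from both
#' counts, so `level = edited / coverage` stays interpretable as
#' edited/(edited+unedited).
#'
#' Status per site: `SNP_MASKED` if the position is in the SNP exclusion
#' panel (regardless of counts); otherwise `NOT_DETECTED` at zero coverage,
#' `LOW_COVERAGE` below `min_coverage`, `LOW_EDITED` below `min_edited`,
#' else `CALLED`. `level` is only defined for `CALLED` sites.
#'
#' @param counts data.frame from [pileupBases()].
#' @param catalog data.frame of known sites: `site_id`, `chrom`, `pos`
#'   (1-based), `strand`.
#' @param snps optional SNP panel data.frame (`chrom`, `pos`).
#' @param reference optional [Biostrings::DNAStringSet]; when supplied,
#'   each catalog site is checked to be a strand-frame adenosine (`A` on
#'   `+`, `T` on `-`) and a mismatch raises a catalog-consistency error.
#' @param config a [quantConfig()].
#' @return data.frame with `site_id`, `chrom`, `pos`, `strand`,
#'   `coverage`, `edited`, `level`, `status`.
#' @export
callSites <- function(counts, catalog, snps = NULL, reference = NULL,
                      config = quantConfig()) {
  stopifnot(inherits(config, "QuantConfig"),
            all(c("site_id", "chrom", "pos", "strand") %in% names(catalog)))
  if (!is.null(reference)) {
    refbase <- vapply(seq_len(nrow(catalog)), function(i) {
      as.character(Biostrings::subseq(reference[[catalog$chrom[i]]],
                                      catalog$pos[i], catalog$pos[i]))
    }, character(1))
    want <- ifelse(catalog$strand == "+", "A", "T")
    bad <- refbase != want
    if (any(bad))
      stop(sprintf(
        "catalog inconsistency: %d site(s) are not strand-frame adenosines (e.g. %s)",
        sum(bad), catalog$site_id[which(bad)[1L]]), call. = FALSE)
  }
  idx <- match(paste0(catalog$chrom, ":", catalog$pos),
               paste0(counts$chrom, ":", counts$pos))
  plus <- catalog$strand == "+"
  cov <- integer(nrow(catalog))
  edi <- integer(nrow(catalog))
  hit <- !is.na(idx)
  cov[hit & plus] <- counts$n_A[idx[hit & plus]] + counts$n_G[idx[hit & plus]]
  edi[hit & plus] <- counts$n_G[idx[hit & plus]]
  cov[hit & !plus] <- counts$n_T[idx[hit & !plus]] +
    counts$n_C[idx[hit & !plus]]
  edi[hit & !plus] <- counts$n_C[idx[hit & !plus]]

  in_snp <- if (is.null(snps) || !nrow(snps)) rep(FALSE, nrow(catalog)) else
    paste0(catalog$chrom, ":", catalog$pos) %in%
      paste0(snps$chrom, ":", snps$pos)

  status <- ifelse(in_snp, "SNP_MASKED",
            ifelse(cov == 0L, "NOT_DETECTED",
            ifelse(cov < config$min_coverage, "LOW_COVERAGE",
            ifelse(edi < config$min_edited, "LOW_EDITED", "CALLED"))))
  level <- ifelse(status == "CALLED", edi / cov, NA_real_)
  data.frame(site_id = catalog$site_id, chrom = catalog$chrom,
             pos = catalog$pos, strand = catalog$strand,
             coverage = cov, edited = edi, level = level, status = status)
}

#' Partition sites by repeat class
#'
#' Adds a `repeat_class` column partitioning sites into `ALU`,
#' `NONALU_REP` and `NONREP` by interval overlap, with priority
#' `ALU > NONALU_REP` when annotations overlap and `NONREP` as the default
#' for unannotated positions. The partition is total and disjoint.
#'
#' @param calls data.frame with `chrom` and `pos` columns (e.g. from
#'   [callSites()]).
#' @param repeats stranded [GenomicRanges::GRanges] with a `repeat_class`
#'   column (`"ALU"` / `"NONALU_REP"`), e.g. from [generateReference()] or
#'   [readRepeatBed()].
#' @return `calls` with a `repeat_class` column added.
#' @export
stratifyByRepeat <- function(calls, repeats) {
  gr <- GenomicRanges::GRanges(calls$chrom,
                               IRanges::IRanges(calls$pos, calls$pos))
  in_alu <- IRanges::overlapsAny(
    gr, repeats[repeats$repeat_class == "ALU"], ignore.strand = TRUE)
  in_rep <- IRanges::overlapsAny(
    gr, repeats[repeats$repeat_class != "ALU"], ignore.strand = TRUE)
  calls$repeat_class <- ifelse(in_alu, "ALU",
                        ifelse(in_rep, "NONALU_REP", "NONREP"))
  calls
}
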