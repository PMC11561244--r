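#' Quantification thresholds and masks
#'
#' Bundles the filters used by [pileupBases()], [callSites()] and
#' [computeAEI()]. Defaults follow common practice for A-to-I calling:
#' bases within 5 bp of a read end or of a splice-gap boundary are masked
#' (alignment artifacts cluster there), base calls below Q20 and reads
#' below MAPQ 20 are discarded, and a site call requires at least 5
#' covering reads with at least 3 edited.
#'
#' "Within `end_mask_bp`" is inclusive: with the default 5, query offsets
#' 1..5 from either read end are masked and offset 6 is kept; likewise a
#' base 1..5 bp from a splice-gap boundary (distance counted in read
#' coordinates) is masked and 6 bp is kept.
#'
#' @param end_mask_bp bases masked at each read end.
#' @param splice_mask_bp bases masked next to each splice-gap boundary.
#' @param min_base_quality minimum Phred base quality.
#' @param min_mapq minimum mapping quality.
#' @param min_coverage minimum strand-frame (A+G) reads to call a site.
#' @param min_edited minimum edited reads to call a site.
#' @return a list of class `"QuantConfig"`.
#' @export
quantConfig <- function(end_mask_bp = 5L, splice_mask_bp = 5L,
                        min_base_quality = 20L, min_mapq = 20L,
                        min_coverage = 5L, min_edited = 3L) {
  cfg <- list(end_mask_bp = .assert_count(end_mask_bp, "end_mask_bp"),
              splice_mask_bp = .assert_count(splice_mask_bp, "splice_mask_bp"),
              min_base_quality =
                .assert_count(min_base_quality, "min_base_quality"),
              min_mapq = .assert_count(min_mapq, "min_mapq"),
              min_coverage = .assert_count(min_coverage, "min_coverage"),
              min_edited = .assert_count(min_edited, "min_edited"))
  class(cfg) <- "QuantConfig"
  cfg
}

# Expand alignments into one row per retained query base.
# Returns list(chrom=..., rpos=..., base=...) after all masking filters.
.expand_bases <- function(aln, config) {
  keep_read <- S4Vectors::mcols(aln)$mapq >= config$min_mapq
  aln <- aln[keep_read]
  if (!length(aln)) {
    return(list(chrom = character(0), rpos = integer(0), base = character(0)))
  }
  cig <- GenomicAlignments::cigar(aln)
  qr <- GenomicAlignments::cigarRangesAlongQuerySpace(
    cig, ops = c("M", "=", "X"))
  rr <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cig, pos = GenomicRanges::start(aln), ops = c("M", "=", "X"))

  nblk <- S4Vectors::elementNROWS(qr)
  read_of_blk <- rep(seq_along(aln), nblk)
  qstart <- unlist(IRanges::start(qr), use.names = FALSE)
  qend <- unlist(IRanges::end(qr), use.names = FALSE)
  rstart <- unlist(IRanges::start(rr), use.names = FALSE)
  w <- qend - qstart + 1L

  base_read <- rep(read_of_blk, w)
  qpos <- sequence(w, from = qstart)
  rpos <- sequence(w, from = rstart)

  # read-end mask (offsets counted on the full query incl. soft clips)
  L <- GenomicAlignments::qwidth(aln)[base_read]
  keep <- qpos > config$end_mask_bp & qpos <= L - config$end_mask_bp

  # splice mask: distance in read coordinates to the nearest N-gap boundary.
  # A boundary sits between consecutive M blocks whose reference positions
  # jump; in query space it lies at qend of the left block (that base has
  # distance 1, the first base after the gap distance 1 on the other side).
  if (config$splice_mask_bp > 0L) {
    has_gap <- grepl("N", cig, fixed = TRUE)
    if (any(has_gap)) {
      cw <- cumsum(w)
      first_blk <- cumsum(c(1L, nblk))
      for (r in which(has_gap)) {
        blks <- first_blk[r]:(first_blk[r + 1L] - 1L)
        if (length(blks) < 2L) next
        b0 <- cw[blks[1L]] - w[blks[1L]]
        base_idx <- (b0 + 1L):cw[blks[length(blks)]]
        qp <- qpos[base_idx]
        for (b in blks[-length(blks)]) {
          gap_len <- rstart[b + 1L] - (rstart[b] + w[b])
          if (gap_len > 0L) {
            e <- qend[b]
            d <- ifelse(qp <= e, e - qp + 1L, qp - e)
            keep[base_idx] <- keep[base_idx] & d > config$splice_mask_bp
          }
        }
      }
    }
  }

  # base quality
  quals <- as(S4Vectors::mcols(aln)$qual, "IntegerList")
  qlen <- S4Vectors::elementNROWS(quals)
  qoff <- c(0L, cumsum(qlen))[base_read]
  qvec <- unlist(quals, use.names = FALSE)
  keep <- keep & qvec[qoff + qpos] >= config$min_base_quality

  # base calls
  seqs <- as.character(S4Vectors::mcols(aln)$seq)
  chars <- strsplit(paste(seqs, collapse = ""), "", fixed = TRUE)[[1]]
  soff <- c(0L, cumsum(nchar(seqs)))[base_read]
  bvec <- chars[soff + qpos]

  chromv <- as.character(GenomicRanges::seqnames(aln))[base_read]
  list(chrom = chromv[keep], rpos = rpos[keep], base = bvec[keep])
}

#' Base counts per position from masked pileup
#'
#' Counts reference-frame read bases at each covered position, applying the
#' masking rules of [quantConfig()]: a read contributes its base at a
#' position only if the position falls in an aligned match block, lies more
#' than `end_mask_bp` bases from both read termini and more than
#' `splice_mask_bp` bases (in read coordinates) from every splice-gap
#' boundary, and passes the base-quality and mapping-quality thresholds.
#' Deleted positions and gaps contribute nothing.
#'
#' @param aln coordinate-sorted [GenomicAlignments::GAlignments] from
#'   [readAlignments()].
#' @param region optional [GenomicRanges::GRanges] restricting the counted
#'   positions.
#' @param reference optional [Biostrings::DNAStringSet]; when given,
#'   regions/positions are checked against chromosome bounds.
#' @param config a [quantConfig()].
#' @return data.frame with `chrom`, `pos` (1-based) and counts `n_A`,
#'   `n_C`, `n_G`, `n_T`; only positions with at least one retained base
#'   appear.
#' @export
pileupBases <- function(aln, region = NULL, reference = NULL,
                        config = quantConfig()) {
  stopifnot(inherits(config, "QuantConfig"))
  if (!.is_sorted(aln))
    stop("alignments must be coordinate-sorted", call. = FALSE)
  if (!is.null(region) && !is.null(reference)) {
    idx <- match(as.character(GenomicRanges::seqnames(region)),
                 names(reference))
    if (anyNA(idx) ||
        any(GenomicRanges::end(region) > Biostrings::width(reference)[idx]) ||
        any(GenomicRanges::start(region) < 1L))
      stop("region lies outside the reference", call. = FALSE)
  }
  if (!is.null(region)) {
    aln <- aln[IRanges::overlapsAny(GenomicRanges::granges(aln), region,
                                    ignore.strand = TRUE)]
  }
  ex <- .expand_bases(aln, config)
  if (!is.null(region) && length(ex$rpos)) {
    gr <- GenomicRanges::GRanges(ex$chrom, IRanges::IRanges(ex$rpos, ex$rpos))
    inr <- IRanges::overlapsAny(gr, region, ignore.strand = TRUE)
    ex <- lapply(ex, `[`, inr)
  }
  if (!length(ex$rpos)) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      n_A = integer(0), n_C = integer(0),
                      n_G = integer(0), n_T = integer(0)))
  }
  chroms_u <- unique(ex$chrom)
  key <- (match(ex$chrom, chroms_u) - 1) * 2^32 + ex$rpos
  ukey <- sort(unique(key))
  ki <- match(key, ukey)
  counts <- matrix(0L, length(ukey), 4L,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  for (b in c("A", "C", "G", "T"))
    counts[, b] <- tabulate(ki[ex$base == b], nbins = length(ukey))
  out <- data.frame(chrom = chroms_u[ukey %/% 2^32 + 1],
                    pos = as.integer(ukey %% 2^32),
                    n_A = counts[, "A"], n_C = counts[, "C"],
                    n_G = counts[, "G"], n_T = counts[, "T"])
  rownames(out) <- NULL
  out
}
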