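#' Split barcoded alignments into pseudobulk streams
#'
#' Routes each read to the cell state (cell type, batch, knockout
#' condition...) its cell barcode maps to, producing one bulk-like
#' alignment stream per state. Reads whose barcode is absent from the map,
#' or which carry no `CB` tag at all, go to the `"unassigned"` sink; the
#' count of tag-less reads is attached as attribute `n_missing_barcode`
#' and reported with a warning.
#'
#' @param aln [GenomicAlignments::GAlignments] with a `CB` metadata column.
#' @param map data.frame (`barcode`, `state`); one state per barcode.
#' @return named list of `GAlignments`, one per state (plus
#'   `"unassigned"` when non-empty), each preserving coordinate order.
#' @export
splitByState <- function(aln, map) {
  stopifnot(all(c("barcode", "state") %in% names(map)))
  if (anyDuplicated(map$barcode))
    stop("each barcode must map to exactly one state", call. = FALSE)
  cb <- S4Vectors::mcols(aln)$CB
  if (is.null(cb)) cb <- rep(NA_character_, length(aln))
  n_missing <- sum(is.na(cb))
  if (n_missing > 0)
    warning(sprintf("%d read(s) without a CB tag routed to 'unassigned'",
                    n_missing), call. = FALSE)
  state <- map$state[match(cb, map$barcode)]
  state[is.na(state)] <- "unassigned"
  out <- lapply(split(seq_along(aln), state), function(i) aln[i])
  attr(out, "n_missing_barcode") <- n_missing
  out
}

#' UMI deduplication settings
#'
#' `exact` mode keeps one read per distinct UMI within each duplicate
#' group; `directional` mode first collapses likely sequencing-error UMIs:
#' UMI `u2` is absorbed into a Hamming-distance-1 neighbor `u1` when
#' `count(u1) >= 2 * count(u2) - 1`, with the highest-count UMI absorbing
#' (the published umitools network rule).
#'
#' @param mode `"exact"` or `"directional"`.
#' @param max_hamming neighbor distance for directional collapse (fixed 1).
#' @return a list of class `"DedupConfig"`.
#' @export
dedupConfig <- function(mode = c("exact", "directional"), max_hamming = 1L) {
  mode <- match.arg(mode)
  stopifnot(max_hamming == 1L)
  structure(list(mode = mode, max_hamming = 1L), class = "DedupConfig")
}

.hamming1 <- function(a, b) {
  if (nchar(a) != nchar(b)) return(FALSE)
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]) == 1L
}

# Directional UMI clustering within one duplicate group.
# Returns, for each input UMI, the representative UMI of its cluster.
.cluster_umis <- function(umis) {
  counts <- sort(table(umis), decreasing = TRUE)
  us <- names(counts)
  # stable order: by count desc, then lexicographic
  us <- us[order(-as.integer(counts), us)]
  cnt <- as.integer(counts[us])
  rep_of <- setNames(us, us)
  assigned <- setNames(rep(FALSE, length(us)), us)
  for (i in seq_along(us)) {
    if (assigned[us[i]]) next
    assigned[us[i]] <- TRUE
    queue <- us[i]
    while (length(queue)) {
      u <- queue[1L]; queue <- queue[-1L]
      cu <- cnt[match(u, us)]
      for (j in seq_along(us)) {
        v <- us[j]
        if (assigned[v]) next
        if (.hamming1(u, v) && cu >= 2L * cnt[j] - 1L) {
          rep_of[v] <- rep_of[us[i]]
          assigned[v] <- TRUE
          queue <- c(queue, v)
        }
      }
    }
  }
  rep_of[umis]
}

#' Remove PCR duplicates by UMI
#'
#' Groups reads by (chromosome, alignment start, strand, cell barcode) and
#' keeps one read per distinct (exact mode) or surviving (directional
#' mode, see [dedupConfig()]) UMI. Within a UMI the retained read is the
#' one with the highest mean base quality, ties broken by lexicographically
#' smallest read id. Reads without a `UB` tag raise an error naming the
#' read.
#'
#' @param aln coordinate-sorted [GenomicAlignments::GAlignments] with
#'   `UB` (and usually `CB`) metadata columns.
#' @param config a [dedupConfig()].
#' @return the deduplicated `GAlignments`, coordinate order preserved; the
#'   number of reads removed is attached as attribute `n_removed`.
#' @export
dedupUmi <- function(aln, config = dedupConfig()) {
  stopifnot(inherits(config, "DedupConfig"))
  if (!length(aln)) return(aln)
  mc <- S4Vectors::mcols(aln)
  ub <- mc$UB
  if (is.null(ub) || anyNA(ub) || any(!nzchar(ub))) {
    bad <- if (is.null(ub)) mc$qname[1L] else
      mc$qname[which(is.na(ub) | !nzchar(ub))[1L]]
    stop(sprintf("read '%s' carries no UMI (UB tag)", bad), call. = FALSE)
  }
  cb <- mc$CB
  if (is.null(cb)) cb <- ""
  cb[is.na(cb)] <- ""
  grp <- paste(as.character(GenomicRanges::seqnames(aln)),
               GenomicRanges::start(aln),
               as.character(GenomicRanges::strand(aln)), cb, sep = "\r")
  qual_mean <- vapply(as(mc$qual, "IntegerList"), mean, numeric(1))
  keep <- logical(length(aln))
  for (idx in split(seq_along(aln), grp)) {
    umis <- ub[idx]
    reps <- if (config$mode == "exact") umis else .cluster_umis(umis)
    for (u in unique(reps)) {
      cand <- idx[reps == u & umis == u]
      if (!length(cand)) cand <- idx[reps == u]  # representative UMI absent
      best <- cand[order(-qual_mean[cand], mc$qname[cand])][1L]
      keep[best] <- TRUE
    }
  }
  out <- aln[keep]
  attr(out, "n_removed") <- length(aln) - length(out)
  out
}
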