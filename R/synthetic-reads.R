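#' Write alignments to a SAM file
#'
#' Minimal coordinate-sorted SAM emitter for the simulator's output. Reads
#' are single-end; spliced reads use `M`/`N` CIGARs; cell barcodes and UMIs
#' travel in `CB`/`UB` tags.
#'
#' @param reads data.frame with columns `qname`, `flag`, `chrom`, `pos`,
#'   `mapq`, `cigar`, `seq`, `qual`, and optionally `cb`, `ub`.
#' @param reference [Biostrings::DNAStringSet] supplying `@SQ` headers.
#' @param path output path (conventionally `.sam`).
#' @return invisibly, `path`.
#' @export
writeSamFile <- function(reads, reference, path) {
  ord <- order(match(reads$chrom, names(reference)), reads$pos)
  reads <- reads[ord, , drop = FALSE]
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(reference),
                      Biostrings::width(reference)))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                  reads$qname, reads$flag, reads$chrom, reads$pos,
                  reads$mapq, reads$cigar, reads$seq, reads$qual)
  if (!is.null(reads$cb)) {
    has <- !is.na(reads$cb) & nzchar(reads$cb)
    body[has] <- paste0(body[has], "\tCB:Z:", reads$cb[has])
  }
  if (!is.null(reads$ub)) {
    has <- !is.na(reads$ub) & nzchar(reads$ub)
    body[has] <- paste0(body[has], "\tUB:Z:", reads$ub[has])
  }
  writeLines(c(header, body), path)
  invisible(path)
}

.random_umis <- function(n, width = 8L) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * width, replace = TRUE),
              nrow = n)
  apply(m, 1L, paste0, collapse = "")
}

#' Simulate aligned reads for one sample
#'
#' Draws single-end reads over the synthetic reference, flips bases at truth
#' sites with the site's per-sample editing rate (strand frame: `A->G` on
#' `+` sites appears as `A->G` in the reference, on `-` sites as `T->C`),
#' adds uniform substitution sequencing errors, optionally routes a
#' fraction of reads across annotated splice junctions (gapped `N` CIGARs),
#' and — for single-cell/single-nucleus modalities — attaches cell barcodes
#' and UMIs with Poisson-distributed PCR duplicate copies. Output is a
#' coordinate-sorted SAM.
#'
#' At an edited site with rate `r`, each overlapping read carries the edited
#' base independently with probability `r`, so the number of edited reads at
#' coverage `n` is Binomial(`n`, `r`).
#'
#' @param truth an `"EditingTruth"` (see [simulateTruth()]).
#' @param ref the `"SyntheticReference"` the truth was drawn on.
#' @param sample_id which design row to simulate.
#' @param depth mean coverage.
#' @param read_length read length in bases.
#' @param error_rate per-base substitution error rate.
#' @param spliced_fraction fraction of junction-eligible reads made spliced.
#' @param three_prime_bias if `TRUE`, 60% of reads start inside 3' UTRs
#'   (poly-A capture bias of droplet single-cell protocols).
#' @param barcodes optional data.frame (`barcode`, `state`) of cells to
#'   assign reads to; defaults to 8 generic cells for single-cell
#'   modalities.
#' @param dup_rate mean number of extra PCR copies per molecule (UMI
#'   modalities only).
#' @param sam_path output SAM path; default a tempfile.
#' @param seed integer seed.
#' @return invisibly, the SAM path.
#' @export
simulateReads <- function(truth, ref, sample_id, depth = 30,
                          read_length = 100L, error_rate = 0.001,
                          spliced_fraction = 0.15, three_prime_bias = NULL,
                          barcodes = NULL, dup_rate = 0,
                          sam_path = tempfile(fileext = ".sam"), seed = 1L) {
  stopifnot(inherits(truth, "EditingTruth"),
            inherits(ref, "SyntheticReference"))
  if (depth <= 0) stop("'depth' must be positive", call. = FALSE)
  read_length <- .assert_count(read_length, "read_length", 20L)
  .assert_fraction(error_rate, "error_rate")
  design <- truth$designs[truth$designs$sample_id == sample_id, , drop = FALSE]
  if (nrow(design) != 1L)
    stop(sprintf("sample '%s' not in truth design", sample_id), call. = FALSE)
  modality <- design$modality
  umi_mode <- modality %in% c("single_cell", "single_nucleus")
  if (is.null(three_prime_bias)) three_prime_bias <- umi_mode
  if (umi_mode && is.null(barcodes))
    barcodes <- data.frame(barcode = sprintf("BC%02d", 1:8),
                           state = "cell")

  chroms <- names(ref$reference)
  chrom_chars <- lapply(as.character(ref$reference), function(s)
    strsplit(s, "", fixed = TRUE)[[1]])

  # per-chromosome editing rate and edited-base lookups
  rate_vec <- lapply(chrom_chars, function(ch) numeric(length(ch)))
  ebase_vec <- lapply(chrom_chars, function(ch) character(length(ch)))
  s <- truth$sites
  r <- truth$rates[, sample_id]
  for (i in seq_len(nrow(s))) {
    rate_vec[[s$chrom[i]]][s$pos[i]] <- r[i]
    ebase_vec[[s$chrom[i]]][s$pos[i]] <- if (s$strand[i] == "+") "G" else "C"
  }

  utr3 <- ref$genes[ref$genes$type == "three_prime_UTR"]

  with_seed(seed, {
    all_reads <- list()
    for (ch in chroms) {
      L <- length(chrom_chars[[ch]])
      n_reads <- max(1L, as.integer(round(depth * L / read_length)))
      max_start <- L - read_length + 1L
      starts <- sample.int(max_start, n_reads, replace = TRUE)
      if (three_prime_bias) {
        u3 <- utr3[GenomicRanges::seqnames(utr3) == ch]
        if (length(u3)) {
          biased <- runif(n_reads) < 0.6
          pick <- sample.int(length(u3), sum(biased), replace = TRUE)
          us <- GenomicRanges::start(u3)[pick]
          uw <- pmax(1L, GenomicRanges::width(u3)[pick] - read_length + 1L)
          starts[biased] <- pmin(max_start,
                                 us + floor(runif(sum(biased)) * uw))
        }
      }

      # splice assignment: read is eligible if a junction's left end falls
      # well inside it; spliced reads keep the same query length
      jn <- ref$junctions[ref$junctions$chrom == ch, , drop = FALSE]
      cigar <- rep(sprintf("%dM", read_length), n_reads)
      rpos_list <- NULL
      spliced <- rep(FALSE, n_reads)
      a_len <- integer(n_reads); gap <- integer(n_reads)
      if (nrow(jn) && spliced_fraction > 0) {
        for (j in seq_len(nrow(jn))) {
          le <- jn$left_end[j]; rs <- jn$right_start[j]
          elig <- !spliced & starts <= le - 10L &
            starts >= le - read_length + 11L &
            (rs + (read_length - (le - starts + 1L)) - 1L) <= L
          make <- elig & runif(n_reads) < spliced_fraction
          a_len[make] <- le - starts[make] + 1L
          gap[make] <- rs - le - 1L
          spliced <- spliced | make
        }
        cigar[spliced] <- sprintf("%dM%dN%dM", a_len[spliced], gap[spliced],
                                  read_length - a_len[spliced])
      }

      # reference positions of each read's query bases, read-major order
      off <- seq_len(read_length) - 1L
      rpos <- rep(starts, each = read_length) +
        rep.int(off, n_reads)
      if (any(spliced)) {
        idx <- which(spliced)
        bump <- integer(n_reads * read_length)
        for (i in idx) {
          b0 <- (i - 1L) * read_length
          bump[(b0 + a_len[i] + 1L):(b0 + read_length)] <- gap[i]
        }
        rpos <- rpos + bump
      }

      base <- chrom_chars[[ch]][rpos]
      pr <- rate_vec[[ch]][rpos]
      ed <- pr > 0 & runif(length(rpos)) < pr
      base[ed] <- ebase_vec[[ch]][rpos[ed]]
      if (error_rate > 0) {
        er <- which(runif(length(rpos)) < error_rate)
        if (length(er)) {
          alt <- c("A", "C", "G", "T")
          base[er] <- vapply(base[er], function(b)
            sample(setdiff(alt, b), 1L), character(1))
        }
      }
      seq_all <- paste(base, collapse = "")
      seqs <- substring(seq_all, (seq_len(n_reads) - 1L) * read_length + 1L,
                        seq_len(n_reads) * read_length)

      reads <- data.frame(
        qname = sprintf("%s_%s_%06d", sample_id, ch, seq_len(n_reads)),
        flag = ifelse(runif(n_reads) < 0.5, 0L, 16L),
        chrom = ch, pos = starts, mapq = 60L, cigar = cigar,
        seq = seqs, qual = strrep("F", read_length))
      all_reads[[ch]] <- reads
    }
    reads <- do.call(rbind, all_reads)

    if (umi_mode) {
      n <- nrow(reads)
      reads$cb <- sample(barcodes$barcode, n, replace = TRUE)
      reads$ub <- .random_umis(n)
      if (dup_rate > 0) {
        copies <- rpois(n, dup_rate)
        extra <- reads[rep(seq_len(n), copies), , drop = FALSE]
        if (nrow(extra)) {
          extra$qname <- sprintf("%s_dup%05d", extra$qname,
                                 seq_len(nrow(extra)))
          reads <- rbind(reads, extra)
        }
      }
    }
    writeSamFile(reads, ref$reference, sam_path)
  })
  invisible(sam_path)
}
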