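# Shared fixture builders and independent oracles.
#
# The oracles here deliberately re-derive results by naive per-read,
# per-base loops from a plain data.frame description of the reads, so they
# share no code path with the package's vectorized implementations.

# Build a GAlignments from a plain read table.
# df columns: qname, chrom, pos, cigar, seq, qual, mapq, flag; optional cb, ub.
make_aln <- function(df, seqlengths) {
  aln <- GenomicAlignments::GAlignments(
    seqnames = factor(df$chrom, levels = names(seqlengths)),
    pos = as.integer(df$pos), cigar = df$cigar,
    strand = factor(ifelse(bitwAnd(df$flag, 16L) > 0L, "-", "+"),
                    levels = c("+", "-", "*")),
    seqlengths = seqlengths)
  S4Vectors::mcols(aln) <- S4Vectors::DataFrame(
    qname = df$qname, flag = as.integer(df$flag),
    mapq = as.integer(df$mapq),
    seq = Biostrings::DNAStringSet(df$seq),
    qual = Biostrings::PhredQuality(df$qual),
    CB = if (is.null(df$cb)) NA_character_ else df$cb,
    UB = if (is.null(df$ub)) NA_character_ else df$ub)
  ord <- order(match(df$chrom, names(seqlengths)), df$pos)
  aln[ord]
}

# Simple uniform-quality read rows.
read_row <- function(qname, chrom, pos, seq, cigar = NULL, qual = NULL,
                     mapq = 60L, flag = 0L, cb = NA, ub = NA) {
  data.frame(qname = qname, chrom = chrom, pos = pos,
             cigar = cigar %||% paste0(nchar(seq), "M"),
             seq = seq, qual = qual %||% strrep("F", nchar(seq)),
             mapq = mapq, flag = flag, cb = cb, ub = ub)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# --- independent pileup oracle -------------------------------------------
# Walks each read base by base, applying the masking rules literally.
brute_force_pileup <- function(df, config = quantConfig()) {
  counts <- new.env()
  bump <- function(key, base) {
    cur <- if (is.null(counts[[key]])) c(A = 0L, C = 0L, G = 0L, T = 0L)
           else counts[[key]]
    cur[base] <- cur[base] + 1L
    counts[[key]] <- cur
  }
  for (i in seq_len(nrow(df))) {
    if (df$mapq[i] < config$min_mapq) next
    ops <- regmatches(df$cigar[i],
                      gregexpr("\\d+[MIDNSHP=X]", df$cigar[i]))[[1]]
    lens <- as.integer(sub("[A-Z=]", "", ops))
    typs <- sub("\\d+", "", ops)
    qchars <- strsplit(df$seq[i], "")[[1]]
    quals <- as.integer(charToRaw(df$qual[i])) - 33L
    L <- sum(lens[typs %in% c("M", "I", "S", "=", "X")])
    # locate splice boundaries in query coordinates
    qpos <- 0L; boundaries <- integer(0)
    for (k in seq_along(typs)) {
      if (typs[k] %in% c("M", "I", "S", "=", "X")) qpos <- qpos + lens[k]
      if (typs[k] == "N") boundaries <- c(boundaries, qpos)
    }
    qpos <- 0L; rpos <- df$pos[i] - 1L
    for (k in seq_along(typs)) {
      if (typs[k] %in% c("M", "=", "X")) {
        for (j in seq_len(lens[k])) {
          qpos <- qpos + 1L; rpos <- rpos + 1L
          if (qpos <= config$end_mask_bp) next
          if (qpos > L - config$end_mask_bp) next
          if (length(boundaries)) {
            d <- min(ifelse(qpos <= boundaries, boundaries - qpos + 1L,
                            qpos - boundaries))
            if (d <= config$splice_mask_bp) next
          }
          if (quals[qpos] < config$min_base_quality) next
          b <- qchars[qpos]
          if (b %in% c("A", "C", "G", "T"))
            bump(paste0(df$chrom[i], ":", rpos), b)
        }
      } else if (typs[k] %in% c("I", "S")) {
        qpos <- qpos + lens[k]
      } else if (typs[k] %in% c("D", "N")) {
        rpos <- rpos + lens[k]
      }
    }
  }
  keys <- ls(counts)
  if (!length(keys)) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      n_A = integer(0), n_C = integer(0), n_G = integer(0),
                      n_T = integer(0)))
  }
  parts <- strsplit(keys, ":", fixed = TRUE)
  out <- data.frame(
    chrom = vapply(parts, `[`, character(1), 1L),
    pos = as.integer(vapply(parts, `[`, character(1), 2L)),
    n_A = vapply(keys, function(k) counts[[k]][["A"]], integer(1)),
    n_C = vapply(keys, function(k) counts[[k]][["C"]], integer(1)),
    n_G = vapply(keys, function(k) counts[[k]][["G"]], integer(1)),
    n_T = vapply(keys, function(k) counts[[k]][["T"]], integer(1)))
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Random small fixtures for the oracle-equivalence checks.
random_read_fixture <- function(seed, max_reads = 50L, chrom_len = 300L) {
  set.seed(seed)
  n <- sample.int(max_reads, 1L)
  rows <- lapply(seq_len(n), function(i) {
    rl <- sample(12:40, 1L)
    spliced <- runif(1) < 0.3 && rl >= 20L
    if (spliced) {
      a <- sample(5:(rl - 5), 1L)
      gap <- sample(5:40, 1L)
      cigar <- sprintf("%dM%dN%dM", a, gap, rl - a)
      span <- rl + gap
    } else {
      cigar <- sprintf("%dM", rl)
      span <- rl
    }
    pos <- sample.int(chrom_len - span, 1L)
    read_row(sprintf("r%03d", i), "chr1", pos,
             seq = paste(sample(c("A", "C", "G", "T"), rl, TRUE),
                         collapse = ""),
             cigar = cigar,
             qual = paste(sample(c("!", "5", "F", "I"), rl, TRUE),
                          collapse = ""),
             mapq = sample(c(0L, 10L, 30L, 60L), 1L),
             flag = sample(c(0L, 16L), 1L))
  })
  do.call(rbind, rows)
}

# --- strand-mirror helpers (for the symmetry checks) ---------------------
revcomp_str <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

mirror_reads <- function(df, chrom_len) {
  out <- df
  for (i in seq_len(nrow(df))) {
    ops <- regmatches(df$cigar[i],
                      gregexpr("\\d+[MIDNSHP=X]", df$cigar[i]))[[1]]
    lens <- as.integer(sub("[A-Z=]", "", ops))
    typs <- sub("\\d+", "", ops)
    span <- sum(lens[typs %in% c("M", "D", "N", "=", "X")])
    out$pos[i] <- chrom_len - (df$pos[i] + span - 1L) + 1L
    out$cigar[i] <- paste0(rev(paste0(lens, typs)), collapse = "")
    out$seq[i] <- revcomp_str(df$seq[i])
    out$qual[i] <- paste(rev(strsplit(df$qual[i], "")[[1]]), collapse = "")
    out$flag[i] <- bitwXor(df$flag[i], 16L)
  }
  out
}

mirror_granges <- function(gr, chrom_len) {
  new_start <- chrom_len - GenomicRanges::end(gr) + 1L
  new_end <- chrom_len - GenomicRanges::start(gr) + 1L
  st <- as.character(GenomicRanges::strand(gr))
  out <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(gr), IRanges::IRanges(new_start, new_end),
    strand = ifelse(st == "+", "-", ifelse(st == "-", "+", "*")))
  S4Vectors::mcols(out) <- S4Vectors::mcols(gr)
  out
}

# --- small editing-matrix builder ----------------------------------------
em_from_matrix <- function(Y, design = NULL) {
  Y <- pmin(pmax(Y, 0), 1)
  if (is.null(rownames(Y))) rownames(Y) <- sprintf("s%04d", seq_len(nrow(Y)))
  if (is.null(colnames(Y))) colnames(Y) <- sprintf("S%03d", seq_len(ncol(Y)))
  si <- data.frame(site_id = rownames(Y), chrom = "chr1",
                   pos = seq_len(nrow(Y)), strand = "+")
  if (is.null(design)) design <- data.frame(sample_id = colnames(Y))
  design$sample_id <- colnames(Y)
  EditingMatrix(Y, siteInfo = si, sampleInfo = design)
}

# Balanced two-group design with independent covariates.
two_group_design <- function(n_per_group, seed = 1L) {
  set.seed(seed)
  data.frame(
    sample_id = sprintf("S%03d", seq_len(2L * n_per_group)),
    group = rep(c("prenatal", "postnatal"), each = n_per_group),
    sex = sample(c("M", "F"), 2L * n_per_group, TRUE),
    adar_expr = rnorm(2L * n_per_group, 5, 0.5),
    adarb1_expr = rnorm(2L * n_per_group, 3, 0.5))
}

# Brute-force BH step-up (independent of stats::p.adjust).
brute_force_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  if (m > 1L) for (i in (m - 1L):1L) adj[i] <- min(adj[i], adj[i + 1L])
  pmin(adj, 1)[order(o)]
}

# Correlated sites-by-samples matrix with missingness-at-random driven by
# the (fully observed) group covariate, plus the complete ground truth.
mar_matrix <- function(n_sites = 40L, n_per_group = 12L, seed = 1L) {
  set.seed(seed)
  design <- two_group_design(n_per_group, seed = seed)
  n <- 2L * n_per_group
  f <- rnorm(n, sd = 0.08) + 0.1 * (design$group == "postnatal")
  load <- runif(n_sites, 0.5, 1.5)
  Y <- 0.3 + outer(load, f) + matrix(rnorm(n_sites * n, sd = 0.02),
                                     n_sites, n)
  Y <- pmin(pmax(Y, 0.01), 0.99)
  rownames(Y) <- sprintf("s%03d", seq_len(n_sites))
  colnames(Y) <- design$sample_id
  p_miss <- ifelse(design$group == "prenatal", 0.25, 0.05)
  mask <- matrix(runif(n_sites * n), n_sites, n) <
    matrix(p_miss, n_sites, n, byrow = TRUE)
  # never mask a whole site
  for (i in which(rowSums(!mask) < 6L)) mask[i, ] <- FALSE
  Yobs <- Y
  Yobs[mask] <- NA
  list(truth = Y, observed = Yobs, mask = mask, design = design)
}
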