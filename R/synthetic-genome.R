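#' Specify a miniature synthetic genome
#'
#' Defines the reference that the simulator builds: a few short chromosomes
#' seeded with non-overlapping, stranded Alu-like repeats (A-rich on the
#' repeat's own strand, so they carry plenty of editable adenosines), a
#' handful of non-Alu repeats, a simple two-exon gene model per locus and a
#' small SNP exclusion panel. Everything is deterministic given `seed`.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_length chromosome length in bases.
#' @param n_alus total number of Alu intervals across the genome.
#' @param alu_length Alu interval length in bases (real Alus are ~300 bp).
#' @param alu_strand_fraction_plus fraction of Alus placed on the + strand.
#' @param gc_content background GC fraction outside repeats.
#' @param n_nonalu_repeats number of non-Alu repeat intervals.
#' @param nonalu_length length of non-Alu repeat intervals.
#' @param n_snps number of positions in the SNP exclusion panel.
#' @param seed integer seed.
#' @return a validated list of class `"GenomeSpec"`.
#' @export
genomeSpec <- function(n_chroms = 2L, chrom_length = 20000L, n_alus = 30L,
                       alu_length = 300L, alu_strand_fraction_plus = 0.5,
                       gc_content = 0.42, n_nonalu_repeats = 4L,
                       nonalu_length = 200L, n_snps = 30L, seed = 1L) {
  spec <- list(
    n_chroms = .assert_count(n_chroms, "n_chroms", 1L),
    chrom_length = .assert_count(chrom_length, "chrom_length", 100L),
    n_alus = .assert_count(n_alus, "n_alus", 0L),
    alu_length = .assert_count(alu_length, "alu_length", 10L),
    alu_strand_fraction_plus =
      .assert_fraction(alu_strand_fraction_plus, "alu_strand_fraction_plus"),
    gc_content = .assert_fraction(gc_content, "gc_content"),
    n_nonalu_repeats = .assert_count(n_nonalu_repeats, "n_nonalu_repeats"),
    nonalu_length = .assert_count(nonalu_length, "nonalu_length", 10L),
    n_snps = .assert_count(n_snps, "n_snps"),
    seed = .assert_count(seed, "seed", 0L))
  total_repeat <- spec$n_alus * spec$alu_length +
    spec$n_nonalu_repeats * spec$nonalu_length
  if (total_repeat >= spec$n_chroms * spec$chrom_length)
    stop("infeasible packing: repeats do not fit in the genome", call. = FALSE)
  class(spec) <- "GenomeSpec"
  spec
}

# Place non-overlapping intervals of the given widths uniformly in [1, L]
# by drawing a random composition of the free space into gaps.
.pack_intervals <- function(L, widths) {
  k <- length(widths)
  if (k == 0L) return(integer(0))
  free <- L - sum(widths)
  if (free < 0) stop("infeasible packing on one chromosome", call. = FALSE)
  gaps <- as.vector(rmultinom(1L, free, rep(1, k + 1L)))
  starts <- integer(k)
  pos <- 1L
  for (i in seq_len(k)) {
    pos <- pos + gaps[i]
    starts[i] <- pos
    pos <- pos + widths[i]
  }
  starts
}

.sample_bases <- function(n, probs) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs)
}

# Two-exon gene with UTRs and CDS; coordinates are 1-based inclusive.
# `strand` mirrors the layout within the 4 kb gene body.
.gene_features <- function(chrom, s, strand, gene_id) {
  e <- s + 3999L
  if (strand == "+") {
    feats <- data.frame(
      type  = c("gene", "exon", "exon", "five_prime_UTR", "CDS", "CDS",
                "three_prime_UTR"),
      start = c(s, s, s + 2000L, s, s + 200L, s + 2000L, s + 2400L),
      end   = c(e, s + 999L, e, s + 199L, s + 999L, s + 2399L, e))
    junction <- c(left_end = s + 999L, right_start = s + 2000L)
  } else {
    feats <- data.frame(
      type  = c("gene", "exon", "exon", "five_prime_UTR", "CDS", "CDS",
                "three_prime_UTR"),
      start = c(s, s + 3000L, s, s + 3800L, s + 3000L, s + 1600L, s),
      end   = c(e, e, s + 1999L, e, s + 3799L, s + 1999L, s + 1599L))
    junction <- c(left_end = s + 1999L, right_start = s + 3000L)
  }
  feats$chrom <- chrom
  feats$strand <- strand
  feats$gene_id <- gene_id
  list(features = feats, junction = junction)
}

#' Generate a synthetic reference with annotations
#'
#' Builds the reference sequences and every annotation layer downstream
#' stages consume: stranded Alu and non-Alu repeat intervals, a gene model
#' with exons, CDS and UTRs (3' UTRs are deliberately long, where most
#' real A-to-I sites sit), splice junctions, and a SNP exclusion panel whose
#' positions record the reference base.
#'
#' @param spec a [genomeSpec()].
#' @return a list of class `"SyntheticReference"` with elements `reference`
#'   ([Biostrings::DNAStringSet]), `alu` and `repeats` (stranded
#'   [GenomicRanges::GRanges]; `repeats` covers both classes with a
#'   `repeat_class` column), `genes` (GRanges with `type` and `gene_id`),
#'   `snps` (data.frame `chrom`, `pos`, `ref`), `junctions` (data.frame
#'   `chrom`, `left_end`, `right_start`, `gene_id`, `strand`) and `spec`.
#' @export
generateReference <- function(spec) {
  stopifnot(inherits(spec, "GenomeSpec"))
  with_seed(spec$seed, {
    chroms <- paste0("chr", seq_len(spec$n_chroms))
    bg_probs <- c((1 - spec$gc_content) / 2, spec$gc_content / 2,
                  spec$gc_content / 2, (1 - spec$gc_content) / 2)
    # A-rich profile in the repeat's own strand frame
    alu_probs <- c(A = 0.42, C = 0.18, G = 0.20, T = 0.20)

    seqs <- lapply(chroms, function(ch)
      .sample_bases(spec$chrom_length, bg_probs))
    names(seqs) <- chroms

    # distribute repeats over chromosomes, then pack per chromosome
    n_rep <- spec$n_alus + spec$n_nonalu_repeats
    rep_class <- sample(c(rep("ALU", spec$n_alus),
                          rep("NONALU_REP", spec$n_nonalu_repeats)))
    rep_chrom <- sort(sample(seq_len(spec$n_chroms), n_rep, replace = TRUE))
    widths <- ifelse(rep_class == "ALU", spec$alu_length, spec$nonalu_length)

    rep_df <- data.frame(chrom = chroms[rep_chrom], class = rep_class,
                         width = widths, start = NA_integer_)
    for (ci in seq_len(spec$n_chroms)) {
      idx <- which(rep_chrom == ci)
      if (!length(idx)) next
      rep_df$start[idx] <- .pack_intervals(spec$chrom_length,
                                           rep_df$width[idx])
    }
    rep_df$end <- rep_df$start + rep_df$width - 1L
    rep_df$strand <- ifelse(
      runif(n_rep) < spec$alu_strand_fraction_plus, "+", "-")
    rep_df$name <- sprintf("%s_%03d", tolower(rep_df$class), seq_len(n_rep))

    # overwrite repeat sequence: A-rich in the repeat's strand frame
    for (i in seq_len(n_rep)) {
      b <- .sample_bases(rep_df$width[i], alu_probs)
      if (rep_df$strand[i] == "-")
        b <- chartr("ACGT", "TGCA", b)  # per-base complement, order kept
      seqs[[rep_df$chrom[i]]][rep_df$start[i]:rep_df$end[i]] <- b
    }

    # gene model: one 4 kb two-exon gene every 5 kb, alternating strand
    feats <- list(); juncs <- list(); gi <- 0L
    for (ch in chroms) {
      gs <- if (spec$chrom_length >= 5000L)
        seq(500L, spec$chrom_length - 4500L, by = 5000L) else integer(0)
      for (s in gs) {
        gi <- gi + 1L
        gf <- .gene_features(ch, s, if (gi %% 2L) "+" else "-",
                             sprintf("gene_%03d", gi))
        feats[[gi]] <- gf$features
        juncs[[gi]] <- data.frame(chrom = ch,
                                  left_end = gf$junction["left_end"],
                                  right_start = gf$junction["right_start"],
                                  gene_id = sprintf("gene_%03d", gi),
                                  strand = if (gi %% 2L) "+" else "-")
      }
    }
    feats <- if (length(feats)) do.call(rbind, feats) else
      data.frame(type = character(0), start = integer(0), end = integer(0),
                 chrom = character(0), strand = character(0),
                 gene_id = character(0))
    junctions <- if (length(juncs)) do.call(rbind, juncs) else
      data.frame(chrom = character(0), left_end = integer(0),
                 right_start = integer(0), gene_id = character(0),
                 strand = character(0))
    rownames(junctions) <- NULL

    reference <- Biostrings::DNAStringSet(vapply(
      seqs, paste, character(1), collapse = ""))
    names(reference) <- chroms

    repeats <- GenomicRanges::GRanges(
      rep_df$chrom,
      IRanges::IRanges(rep_df$start, rep_df$end),
      strand = rep_df$strand,
      repeat_class = rep_df$class, name = rep_df$name,
      seqlengths = setNames(rep(spec$chrom_length, spec$n_chroms), chroms))
    alu <- repeats[repeats$repeat_class == "ALU"]

    genes <- GenomicRanges::GRanges(
      feats$chrom, IRanges::IRanges(feats$start, feats$end),
      strand = feats$strand, type = feats$type, gene_id = feats$gene_id,
      seqlengths = setNames(rep(spec$chrom_length, spec$n_chroms), chroms))

    snp_pos <- data.frame(chrom = character(0), pos = integer(0))
    if (spec$n_snps > 0) {
      sc <- sample(chroms, spec$n_snps, replace = TRUE)
      sp <- sample.int(spec$chrom_length, spec$n_snps, replace = TRUE)
      keep <- !duplicated(paste(sc, sp))
      snp_pos <- data.frame(chrom = sc[keep], pos = sp[keep])
    }
    snp_pos$ref <- vapply(seq_len(nrow(snp_pos)), function(i)
      seqs[[snp_pos$chrom[i]]][snp_pos$pos[i]], character(1))
    snp_pos <- snp_pos[order(snp_pos$chrom, snp_pos$pos), , drop = FALSE]
    rownames(snp_pos) <- NULL

    structure(list(reference = reference, alu = alu, repeats = repeats,
                   genes = genes, snps = snp_pos, junctions = junctions,
                   spec = spec),
              class = "SyntheticReference")
  })
}

#' Write a synthetic reference bundle to disk
#'
#' Emits the standard plain-text forms: reference FASTA, stranded 6-column
#' BED for Alu and all repeats (0-based half-open), GFF3 gene model, and
#' 1-based TSV tables for the SNP panel and splice junctions.
#'
#' @param ref a `"SyntheticReference"` from [generateReference()].
#' @param dir output directory (created if needed).
#' @return invisibly, a named character vector of the paths written.
#' @export
writeReference <- function(ref, dir) {
  stopifnot(inherits(ref, "SyntheticReference"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "reference.fa"),
             alu = file.path(dir, "alu.bed"),
             repeats = file.path(dir, "repeats.bed"),
             genes = file.path(dir, "genes.gff3"),
             snps = file.path(dir, "snps.tsv"),
             junctions = file.path(dir, "junctions.tsv"))
  Biostrings::writeXStringSet(ref$reference, paths["fasta"])
  .write_bed6 <- function(gr, path) {
    out <- gr
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(name = gr$name,
                                                  score = 0L)
    rtracklayer::export(out, path, format = "bed")
  }
  .write_bed6(ref$alu, paths["alu"])
  .write_bed6(ref$repeats, paths["repeats"])
  .write_gff3(ref$genes, paths["genes"])
  write.table(ref$snps, paths["snps"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(ref$junctions, paths["junctions"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}

.write_gff3 <- function(genes, path) {
  out <- genes
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    type = genes$type,
    ID = ifelse(genes$type == "gene", genes$gene_id, NA_character_),
    Parent = ifelse(genes$type == "gene", NA_character_, genes$gene_id),
    phase = ifelse(genes$type == "CDS", 0L, NA_integer_))
  rtracklayer::export(out, path, format = "gff3")
}

#' Read a stranded BED file of repeat intervals
#'
#' @param path 6-column BED (0-based half-open) as written by
#'   [writeReference()] or any RepeatMasker-style export.
#' @param repeat_class class label to attach (`"ALU"` or `"NONALU_REP"`);
#'   if `NA`, inferred from the name column prefix.
#' @return a stranded [GenomicRanges::GRanges] with `repeat_class` and
#'   `name` columns.
#' @export
readRepeatBed <- function(path, repeat_class = NA_character_) {
  gr <- rtracklayer::import(path, format = "bed")
  gr$repeat_class <- if (is.na(repeat_class))
    ifelse(grepl("^alu", gr$name), "ALU", "NONALU_REP") else repeat_class
  gr$score <- NULL
  gr
}
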