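sl <- c(chr1 = 1000L)

tagged_read <- function(qname, pos, cb, ub, qual = NULL, seq = NULL) {
  read_row(qname, "chr1", pos, seq %||% strrep("A", 30L), qual = qual,
           cb = cb, ub = ub)
}

test_that("splitByState routes every read to exactly one stream", {
  df <- do.call(rbind, c(
    lapply(1:10, function(i) tagged_read(sprintf("a%02d", i), 100L + i,
                                         "BC01", "AAAAAAAA")),
    lapply(1:10, function(i) tagged_read(sprintf("b%02d", i), 200L + i,
                                         "BC02", "CCCCCCCC")),
    list(tagged_read("x01", 300L, "BC99", "GGGGGGGG"))))
  aln <- make_aln(df, sl)
  map <- data.frame(barcode = c("BC01", "BC02"),
                    state = c("neural", "muscle"))
  out <- splitByState(aln, map)
  expect_setequal(names(out), c("neural", "muscle", "unassigned"))
  expect_length(out$neural, 10L)
  expect_length(out$muscle, 10L)
  expect_length(out$unassigned, 1L)
  expect_equal(sum(lengths(out)), length(aln))
  # coordinate order preserved within each stream
  for (st in names(out))
    expect_true(!is.unsorted(GenomicRanges::start(out[[st]])))

  # empty map: everything lands in the sink
  empty <- splitByState(aln, data.frame(barcode = character(0),
                                        state = character(0)))
  expect_length(empty$unassigned, length(aln))

  # missing CB tags are counted and warned about
  df2 <- df; df2$cb[1] <- NA
  expect_warning(out2 <- splitByState(make_aln(df2, sl), map),
                 "without a CB tag")
  expect_equal(attr(out2, "n_missing_barcode"), 1L)

  expect_error(splitByState(aln, data.frame(barcode = c("BC01", "BC01"),
                                            state = c("a", "b"))),
               "exactly one state")
})

test_that("exact dedup keeps one read per distinct UMI", {
  df <- rbind(tagged_read("r1", 100L, "BC01", "ACGTACGT",
                          qual = strrep("F", 30L)),
              tagged_read("r2", 100L, "BC01", "ACGTACGT",
                          qual = strrep("5", 30L)),
              tagged_read("r3", 100L, "BC01", "ACGTACGT",
                          qual = strrep("5", 30L)),
              tagged_read("r4", 100L, "BC01", "TGCATGCA"))
  out <- dedupUmi(make_aln(df, sl))
  expect_length(out, 2L)
  # the highest-quality read of the triplicate UMI is the one retained
  expect_setequal(S4Vectors::mcols(out)$qname, c("r1", "r4"))
  expect_equal(attr(out, "n_removed"), 2L)

  # different positions or barcodes are separate groups
  df2 <- rbind(tagged_read("r1", 100L, "BC01", "ACGTACGT"),
               tagged_read("r2", 101L, "BC01", "ACGTACGT"),
               tagged_read("r3", 100L, "BC02", "ACGTACGT"))
  expect_length(dedupUmi(make_aln(df2, sl)), 3L)

  # opposite strands are separate groups
  df3 <- rbind(tagged_read("r1", 100L, "BC01", "ACGTACGT"),
               tagged_read("r2", 100L, "BC01", "ACGTACGT"))
  df3$flag[2] <- 16L
  expect_length(dedupUmi(make_aln(df3, sl)), 2L)

  # ties on quality break by lexicographically smallest read id
  df4 <- rbind(tagged_read("zz", 100L, "BC01", "ACGTACGT"),
               tagged_read("aa", 100L, "BC01", "ACGTACGT"))
  out4 <- dedupUmi(make_aln(df4, sl))
  expect_equal(S4Vectors::mcols(out4)$qname, "aa")

  # missing UMI is an error naming the read
  df5 <- tagged_read("orphan", 100L, "BC01", NA)
  expect_error(dedupUmi(make_aln(df5, sl)), "orphan")
})

test_that("directional dedup applies the 2n-1 count-ratio rule", {
  # hand trace: ACGT x10 and ACGA x1 at one position -> one read kept
  df <- do.call(rbind, c(
    lapply(1:10, function(i) tagged_read(sprintf("m%02d", i), 100L, "BC01",
                                         "ACGT", seq = strrep("A", 20L))),
    list(tagged_read("err", 100L, "BC01", "ACGA",
                     seq = strrep("A", 20L)))))
  out <- dedupUmi(make_aln(df, sl), dedupConfig("directional"))
  expect_length(out, 1L)
  expect_equal(S4Vectors::mcols(out)$UB, "ACGT")

  # counts 5 and 4: 5 < 2*4 - 1, so both UMIs survive
  df2 <- do.call(rbind, c(
    lapply(1:5, function(i) tagged_read(sprintf("a%d", i), 100L, "BC01",
                                        "ACGT", seq = strrep("A", 20L))),
    lapply(1:4, function(i) tagged_read(sprintf("b%d", i), 100L, "BC01",
                                        "ACGA", seq = strrep("A", 20L)))))
  out2 <- dedupUmi(make_aln(df2, sl), dedupConfig("directional"))
  expect_length(out2, 2L)

  # counts 5 and 3 but Hamming distance 2: both survive regardless
  df3 <- df2
  df3$ub[df3$ub == "ACGA"] <- "ACCA"
  out3 <- dedupUmi(make_aln(df3, sl), dedupConfig("directional"))
  expect_length(out3, 2L)

  # transitive absorption: 16, 8, 4 in a Hamming chain collapse to one
  mk <- function(n, umi, tag) lapply(seq_len(n), function(i)
    tagged_read(sprintf("%s%02d", tag, i), 100L, "BC01", umi,
                seq = strrep("A", 20L)))
  df4 <- do.call(rbind, c(mk(16L, "AAAA", "x"), mk(8L, "AAAT", "y"),
                          mk(4L, "AATT", "z")))
  out4 <- dedupUmi(make_aln(df4, sl), dedupConfig("directional"))
  expect_length(out4, 1L)
  expect_equal(S4Vectors::mcols(out4)$UB, "AAAA")
})

test_that("dedup is conservative and (exact mode) idempotent", {
  set.seed(77)
  for (rep in 1:10) {
    n <- sample(20:60, 1L)
    df <- do.call(rbind, lapply(seq_len(n), function(i)
      tagged_read(sprintf("r%03d", i), sample(100:105, 1L),
                  sample(c("BC01", "BC02"), 1L),
                  paste(sample(c("A", "C", "G", "T"), 4L, TRUE),
                        collapse = ""))))
    aln <- make_aln(df, sl)
    for (mode in c("exact", "directional")) {
      out <- dedupUmi(aln, dedupConfig(mode))
      # conservation: no invented reads, never grows
      expect_lte(length(out), length(aln))
      expect_true(all(S4Vectors::mcols(out)$qname %in% df$qname))
    }
    once <- dedupUmi(aln, dedupConfig("exact"))
    twice <- dedupUmi(once, dedupConfig("exact"))
    expect_identical(S4Vectors::mcols(twice)$qname,
                     S4Vectors::mcols(once)$qname)
  }
})

test_that("AEI commutes with pseudobulk splitting", {
  ref <- generateReference(genomeSpec(n_chroms = 1L, chrom_length = 6000L,
                                      n_alus = 6L, seed = 31L))
  d <- simulateDesigns(1L, 0L, modality = "single_cell", seed = 1L)
  tr <- simulateTruth(ref, d, trajectoryModel(0.35, 0, "constant"),
                      sites_per_class = c(ALU = 20L), seed = 2L)
  bcs <- data.frame(barcode = sprintf("BC%02d", 1:6),
                    state = rep(c("sA", "sB"), 3L))
  sam <- simulateReads(tr, ref, "S01", depth = 12, barcodes = bcs,
                       seed = 3L)
  aln <- readAlignments(sam)
  states <- splitByState(aln, bcs)
  aei_split <- computeAEI(states$sA, ref$alu, ref$reference,
                          snps = ref$snps)
  keep <- S4Vectors::mcols(aln)$CB %in%
    bcs$barcode[bcs$state == "sA"]
  aei_filter <- computeAEI(aln[keep], ref$alu, ref$reference,
                           snps = ref$snps)
  expect_identical(aei_split$numerator, aei_filter$numerator)
  expect_identical(aei_split$denominator, aei_filter$denominator)
})
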