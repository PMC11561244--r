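test_that("reference generation is deterministic and honors the spec", {
  spec <- genomeSpec(n_chroms = 2L, chrom_length = 5000L, n_alus = 8L,
                     alu_length = 300L, seed = 42L)
  r1 <- generateReference(spec)
  r2 <- generateReference(spec)
  expect_identical(as.character(r1$reference), as.character(r2$reference))
  expect_identical(as.data.frame(r1$alu), as.data.frame(r2$alu))
  expect_identical(r1$snps, r2$snps)

  d1 <- file.path(tempdir(), "refA"); d2 <- file.path(tempdir(), "refB")
  writeReference(r1, d1); writeReference(r2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))

  expect_length(r1$alu, 8L)
  expect_true(all(GenomicRanges::width(r1$alu) == 300L))
  # non-overlapping, within bounds
  expect_equal(sum(GenomicRanges::countOverlaps(r1$repeats, r1$repeats)),
               length(r1$repeats))
  expect_true(all(GenomicRanges::start(r1$alu) >= 1L))
  expect_true(all(GenomicRanges::end(r1$alu) <= 5000L))

  all_plus <- generateReference(genomeSpec(
    n_chroms = 1L, chrom_length = 5000L, n_alus = 10L, alu_length = 300L,
    alu_strand_fraction_plus = 1, seed = 3L))
  expect_true(all(as.character(GenomicRanges::strand(all_plus$alu)) == "+"))

  # SNP panel positions carry the true reference base
  for (i in seq_len(nrow(r1$snps))) {
    expect_identical(r1$snps$ref[i], as.character(Biostrings::subseq(
      r1$reference[[r1$snps$chrom[i]]], r1$snps$pos[i], r1$snps$pos[i])))
  }

  expect_error(genomeSpec(n_chroms = 1L, chrom_length = 1000L,
                          n_alus = 10L, alu_length = 300L),
               "infeasible")
})

test_that("BED round trip preserves Alu intervals and strands", {
  ref <- generateReference(genomeSpec(n_chroms = 1L, chrom_length = 6000L,
                                      n_alus = 6L, seed = 9L))
  dir <- file.path(tempdir(), "bedrt")
  paths <- writeReference(ref, dir)
  back <- readRepeatBed(paths[["alu"]])
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(ref$alu))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(ref$alu))
  expect_equal(as.character(GenomicRanges::strand(back)),
               as.character(GenomicRanges::strand(ref$alu)))
  expect_true(all(back$repeat_class == "ALU"))
})

test_that("truth rates follow trajectory shape, covariates and deltas", {
  ref <- generateReference(genomeSpec(seed = 5L))
  designs <- simulateDesigns(6L, 6L, seed = 2L)

  # constant, noiseless: every rate equals the baseline
  tr <- simulateTruth(ref, designs, trajectoryModel(0.2, 0, "constant"),
                      sites_per_class = c(ALU = 10L), seed = 1L)
  expect_true(all(tr$rates == 0.2))
  expect_true(all(tr$rates >= 0 & tr$rates <= 1))

  # logistic increase: postnatal mean exceeds prenatal mean
  tr2 <- simulateTruth(ref, designs,
                       trajectoryModel(0.1, 0.2, "logistic_increase"),
                       sites_per_class = c(ALU = 10L), seed = 1L)
  post <- designs$group == "postnatal"
  expect_gt(mean(tr2$rates[, post]), mean(tr2$rates[, !post]))

  # covariate effect: 1-unit adar_expr difference moves the rate by slope
  d2 <- designs[1:2, ]
  d2$adar_expr <- c(1, 2)
  m <- trajectoryModel(0.2, 0, "constant",
                       covariate_effects = list(adar_expr = 0.1))
  tr3 <- simulateTruth(ref, d2, m, sites_per_class = c(ALU = 5L), seed = 1L)
  expect_equal(unname(tr3$rates[, 2] - tr3$rates[, 1]), rep(0.1, 5L))

  # injected group delta of stated size
  tr4 <- simulateTruth(ref, designs, trajectoryModel(0.2, 0, "constant"),
                       sites_per_class = c(ALU = 20L),
                       delta_fraction = 0.5, delta_size = 0.15, seed = 1L)
  expect_equal(sum(tr4$sites$is_differential), 10L)
  hit <- tr4$sites$is_differential
  expect_equal(unname(rowMeans(tr4$rates[hit, post]) -
                        rowMeans(tr4$rates[hit, !post])),
               rep(0.15, 10L))

  # sites sit on strand-frame adenosines
  for (i in seq_len(nrow(tr$sites))) {
    b <- as.character(Biostrings::subseq(
      ref$reference[[tr$sites$chrom[i]]], tr$sites$pos[i], tr$sites$pos[i]))
    expect_identical(b, if (tr$sites$strand[i] == "+") "A" else "T")
  }

  # requesting more sites than available fails loudly
  expect_error(simulateTruth(ref, designs,
                             trajectoryModel(0.2, 0, "constant"),
                             sites_per_class = c(NONALU_REP = 10000L)),
               "available")
})

test_that("simulated reads carry edits at the programmed rate", {
  ref <- generateReference(genomeSpec(n_chroms = 1L, chrom_length = 4000L,
                                      n_alus = 4L, seed = 11L))
  designs <- simulateDesigns(1L, 0L, seed = 1L)

  count_bases_at <- function(sam, chrom, pos) {
    aln <- readAlignments(sam)
    counts <- pileupBases(aln, config = quantConfig(
      end_mask_bp = 0L, splice_mask_bp = 0L, min_base_quality = 0L,
      min_mapq = 0L))
    counts[counts$chrom == chrom & counts$pos == pos, ]
  }

  # rate 1, no errors: every overlapping read shows the edited base
  tr <- simulateTruth(ref, designs, trajectoryModel(1.0, 0, "constant"),
                      sites_per_class = c(ALU = 5L), seed = 2L)
  sam <- simulateReads(tr, ref, "S01", depth = 20, error_rate = 0,
                       seed = 3L)
  s1 <- tr$sites[1L, ]
  cb <- count_bases_at(sam, s1$chrom, s1$pos)
  if (s1$strand == "+") {
    expect_equal(cb$n_A, 0L); expect_gt(cb$n_G, 0L)
  } else {
    expect_equal(cb$n_T, 0L); expect_gt(cb$n_C, 0L)
  }

  # rate 0, no errors: zero mismatches at the site
  tr0 <- simulateTruth(ref, designs, trajectoryModel(0, 0, "constant"),
                       sites_per_class = c(ALU = 5L), seed = 2L)
  sam0 <- simulateReads(tr0, ref, "S01", depth = 20, error_rate = 0,
                        seed = 3L)
  s0 <- tr0$sites[1L, ]
  cb0 <- count_bases_at(sam0, s0$chrom, s0$pos)
  mism <- if (s0$strand == "+") cb0$n_G else cb0$n_C
  expect_equal(mism, 0L)

  # rate 0.5 at high depth: observed fraction within binomial error
  tr5 <- simulateTruth(ref, designs, trajectoryModel(0.5, 0, "constant"),
                       sites_per_class = c(ALU = 3L), seed = 2L)
  sam5 <- simulateReads(tr5, ref, "S01", depth = 400, error_rate = 0,
                        read_length = 50L, seed = 7L)
  aln5 <- readAlignments(sam5)
  cfg0 <- quantConfig(end_mask_bp = 0L, splice_mask_bp = 0L,
                      min_base_quality = 0L, min_mapq = 0L)
  counts5 <- pileupBases(aln5, config = cfg0)
  cl <- callSites(counts5, tr5$sites[, c("site_id", "chrom", "pos",
                                         "strand")],
                  reference = ref$reference, config = cfg0)
  frac <- sum(cl$edited) / sum(cl$coverage)  # ~1200 draws at p = 0.5
  expect_lt(abs(frac - 0.5), 0.05)

  expect_error(simulateReads(tr, ref, "S01", depth = 0), "positive")
  expect_error(simulateReads(tr, ref, "nope", depth = 5), "not in truth")
})

test_that("strand duality: minus-strand sites edit as T->C in ref frame", {
  ref <- generateReference(genomeSpec(
    n_chroms = 1L, chrom_length = 4000L, n_alus = 4L,
    alu_strand_fraction_plus = 0, seed = 13L))
  designs <- simulateDesigns(1L, 0L, seed = 1L)
  tr <- simulateTruth(ref, designs, trajectoryModel(1.0, 0, "constant"),
                      sites_per_class = c(ALU = 8L), seed = 2L)
  expect_true(all(tr$sites$strand == "-"))
  sam <- simulateReads(tr, ref, "S01", depth = 25, error_rate = 0,
                       seed = 3L)
  counts <- pileupBases(readAlignments(sam), config = quantConfig(
    end_mask_bp = 0L, splice_mask_bp = 0L, min_base_quality = 0L,
    min_mapq = 0L))
  hit <- merge(tr$sites, counts, by = c("chrom", "pos"))
  expect_gt(nrow(hit), 0L)
  expect_true(all(hit$n_T == 0L))
  expect_true(all(hit$n_C > 0L))
})

test_that("expression simulation follows the coupling trajectories", {
  designs <- simulateDesigns(4L, 4L, seed = 5L)
  const <- simulateExpression(designs,
                              list(ADAR = trajectoryModel(5, 0, "constant")),
                              seed = 1L)
  expect_true(all(const["ADAR", ] == 5))

  rising <- simulateExpression(
    designs, list(ADARB1 = trajectoryModel(2, 3, "logistic_increase")),
    seed = 1L)
  t_ord <- order(ifelse(designs$age_unit == "wpc",
                        (designs$age_value - 40) / 52, designs$age_value))
  expect_true(all(diff(rising["ADARB1", t_ord]) >= 0))

  noisy1 <- simulateExpression(
    designs, list(ADAR = trajectoryModel(5, 0, "constant", noise_sd = 1)),
    seed = 1L)
  noisy2 <- simulateExpression(
    designs, list(ADAR = trajectoryModel(5, 0, "constant", noise_sd = 1)),
    seed = 2L)
  expect_false(identical(noisy1, noisy2))
})
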