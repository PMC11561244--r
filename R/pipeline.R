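#' Default pipeline configuration
#'
#' One nested list drives the full synthetic run: genome, design, editing
#' trajectory, read simulation, quantification, harmonization, imputation
#' and the knockout fitness demo. Sizes are kept small enough that the
#' whole simulate-to-integrate run finishes in minutes on one CPU while
#' every stage still has data to chew on.
#'
#' @param seed master seed; every stage derives child seeds from it.
#' @return nested list of class `"PipelineConfig"`.
#' @export
defaultPipelineConfig <- function(seed = 1L) {
  cfg <- list(
    seed = as.integer(seed),
    genome = list(n_chroms = 2L, chrom_length = 20000L, n_alus = 24L,
                  alu_length = 300L, alu_strand_fraction_plus = 0.5,
                  gc_content = 0.42, n_nonalu_repeats = 4L,
                  nonalu_length = 200L, n_snps = 25L),
    design = list(n_prenatal = 6L, n_postnatal = 6L),
    truth = list(sites_per_class = c(ALU = 40L, NONALU_REP = 6L,
                                     NONREP = 6L),
                 baseline = 0.15, amplitude = 0.15,
                 shape = "logistic_increase", noise_sd = 0.02,
                 site_sd = 0.04, delta_fraction = 0.2, delta_size = 0.15),
    reads = list(depth = 40, read_length = 100L, error_rate = 0.001,
                 spliced_fraction = 0.15),
    single_cell = list(enabled = TRUE, depth = 15, n_cells = 8L,
                       dup_rate = 0.6),
    quant = list(end_mask_bp = 5L, splice_mask_bp = 5L,
                 min_base_quality = 20L, min_mapq = 20L,
                 min_coverage = 5L, min_edited = 3L),
    harmonize = list(min_detection = 0.60, min_mean_editing = 0.05,
                     max_sample_missing = 0.20),
    impute = list(m = 5L, max_iter = 10L, donors = 5L, k_sites = 10L),
    differential = list(moderation = TRUE, pooling = "average"),
    fitness = list(conditions = c("AAVS1", "ADAR", "ADARB1", "ADARB2"),
                   strata = c("ectoderm", "mesoderm", "endoderm"),
                   n_replicates = 4L, base_count = 400L,
                   adar_depletion = 0.5))
  class(cfg) <- c("PipelineConfig", "list")
  cfg
}

#' Read / write pipeline configuration as YAML
#'
#' @param path YAML file.
#' @return [readPipelineConfig()]: a `"PipelineConfig"` (defaults fill any
#'   keys the file omits).
#' @export
readPipelineConfig <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- defaultPipelineConfig(seed = user$seed %||% 1L)
  for (section in intersect(names(user), names(cfg))) {
    if (is.list(cfg[[section]])) {
      for (k in intersect(names(user[[section]]), names(cfg[[section]])))
        cfg[[section]][[k]] <- user[[section]][[k]]
    } else {
      cfg[[section]] <- user[[section]]
    }
  }
  # YAML turns the named count vector into a list
  spc <- cfg$truth$sites_per_class
  if (is.list(spc)) cfg$truth$sites_per_class <- unlist(spc)
  cfg
}

#' @rdname readPipelineConfig
#' @param config a `"PipelineConfig"`.
#' @export
writePipelineConfig <- function(config, path) {
  cfg <- unclass(config)
  cfg$truth$sites_per_class <- as.list(cfg$truth$sites_per_class)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full synthetic pipeline
#'
#' Executes simulate -> quantify -> pseudobulk -> matrix -> differential ->
#' integrate on generated data and writes every declared output under
#' `outdir`: the reference bundle, per-sample SAMs and site calls, the AEI
#' table, the harmonized editing matrix with site annotation and filter
#' report, the differential table, developmental-stage contrasts, the
#' cross-layer correlation summaries, the knockout fitness tables, and a
#' run log with every resolved parameter and seed.
#'
#' @param config a `"PipelineConfig"` (see [defaultPipelineConfig()]).
#' @param outdir output directory.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the main in-memory results (`ref`,
#'   `designs`, `truth`, `aei`, `matrix`, `differential`, `contrasts`,
#'   `integration`, `fitness`, `paths`).
#' @export
runPipeline <- function(config = defaultPipelineConfig(),
                        outdir = tempfile("editdev_run_"), quiet = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  seeds <- splitSeed(config$seed, 8L)

  say("[1/7] generating reference and annotations")
  g <- config$genome
  spec <- genomeSpec(n_chroms = g$n_chroms, chrom_length = g$chrom_length,
                     n_alus = g$n_alus, alu_length = g$alu_length,
                     alu_strand_fraction_plus = g$alu_strand_fraction_plus,
                     gc_content = g$gc_content,
                     n_nonalu_repeats = g$n_nonalu_repeats,
                     nonalu_length = g$nonalu_length, n_snps = g$n_snps,
                     seed = seeds[1L])
  ref <- generateReference(spec)
  ref_paths <- writeReference(ref, file.path(outdir, "reference"))

  say("[2/7] simulating design, truth and expression")
  designs <- simulateDesigns(config$design$n_prenatal,
                             config$design$n_postnatal, seed = seeds[2L])
  tr <- config$truth
  model <- trajectoryModel(baseline = tr$baseline, amplitude = tr$amplitude,
                           shape = tr$shape, noise_sd = tr$noise_sd)
  truth <- simulateTruth(ref, designs, model,
                         sites_per_class = tr$sites_per_class,
                         delta_fraction = tr$delta_fraction,
                         delta_size = tr$delta_size, site_sd = tr$site_sd,
                         seed = seeds[3L])
  coupling <- list(
    ADAR = trajectoryModel(5, 0, "constant", noise_sd = 0.3),
    ADARB1 = trajectoryModel(2, 2, "logistic_increase", noise_sd = 0.3),
    ADARB2 = trajectoryModel(1, 1.5, "logistic_increase", noise_sd = 0.3),
    VIRALRESP1 = trajectoryModel(6, -2, "logistic_increase", noise_sd = 0.3),
    VIRALRESP2 = trajectoryModel(5, -2, "logistic_increase", noise_sd = 0.3),
    DNAREP1 = trajectoryModel(7, -1.5, "logistic_increase", noise_sd = 0.3),
    DNAREP2 = trajectoryModel(6, -1.5, "logistic_increase", noise_sd = 0.3))
  expr <- simulateExpression(designs, coupling, seed = seeds[4L])
  paths <- list(reference = ref_paths,
                design = .write_tsv(designs, file.path(outdir, "design.tsv")),
                truth = .write_tsv(cbind(truth$sites,
                                         as.data.frame(truth$rates)),
                                   file.path(outdir, "truth.tsv")),
                expression = .write_tsv(
                  data.frame(gene = rownames(expr), expr,
                             check.names = FALSE),
                  file.path(outdir, "expression.tsv")))

  say("[3/7] simulating reads and quantifying %d bulk samples",
      nrow(designs))
  q <- config$quant
  qcfg <- quantConfig(q$end_mask_bp, q$splice_mask_bp, q$min_base_quality,
                      q$min_mapq, q$min_coverage, q$min_edited)
  catalog <- truth$sites[, c("site_id", "chrom", "pos", "strand")]
  site_region <- GenomicRanges::GRanges(
    catalog$chrom, IRanges::IRanges(catalog$pos, catalog$pos))
  sam_dir <- file.path(outdir, "alignments")
  call_dir <- file.path(outdir, "calls")
  dir.create(sam_dir, showWarnings = FALSE)
  dir.create(call_dir, showWarnings = FALSE)
  read_seeds <- splitSeed(seeds[5L], nrow(designs))
  calls <- list(); aei <- list()
  for (i in seq_len(nrow(designs))) {
    sid <- designs$sample_id[i]
    sam <- file.path(sam_dir, paste0(sid, ".sam"))
    simulateReads(truth, ref, sid, depth = config$reads$depth,
                  read_length = config$reads$read_length,
                  error_rate = config$reads$error_rate,
                  spliced_fraction = config$reads$spliced_fraction,
                  sam_path = sam, seed = read_seeds[i])
    aln <- readAlignments(sam)
    counts <- pileupBases(aln, region = site_region,
                          reference = ref$reference, config = qcfg)
    cl <- callSites(counts, catalog, snps = ref$snps,
                    reference = ref$reference, config = qcfg)
    calls[[sid]] <- cl
    .write_tsv(cl, file.path(call_dir, paste0(sid, ".tsv")))
    aei[[sid]] <- computeAEI(aln, ref$alu, ref$reference, snps = ref$snps,
                             config = qcfg, sample_id = sid)
  }
  aei <- do.call(rbind, aei)
  rownames(aei) <- NULL
  paths$aei <- .write_tsv(aei, file.path(outdir, "aei.tsv"))

  dedup_report <- NULL
  if (isTRUE(config$single_cell$enabled)) {
    say("[4/7] single-cell sample: pseudobulk split + UMI dedup")
    sc_design <- designs[1L, ]
    sc_design$sample_id <- "SC01"
    sc_design$modality <- "single_cell"
    sc_truth <- truth
    sc_truth$designs <- rbind(truth$designs, sc_design)
    sc_truth$rates <- cbind(truth$rates,
                            SC01 = truth$rates[, designs$sample_id[1L]])
    bcs <- data.frame(
      barcode = sprintf("BC%02d", seq_len(config$single_cell$n_cells)),
      state = rep(c("neural", "mesenchymal"),
                  length.out = config$single_cell$n_cells))
    sc_sam <- file.path(sam_dir, "SC01.sam")
    simulateReads(sc_truth, ref, "SC01", depth = config$single_cell$depth,
                  read_length = config$reads$read_length,
                  error_rate = config$reads$error_rate,
                  spliced_fraction = config$reads$spliced_fraction,
                  barcodes = bcs, dup_rate = config$single_cell$dup_rate,
                  sam_path = sc_sam, seed = seeds[6L])
    sc_aln <- readAlignments(sc_sam)
    states <- splitByState(sc_aln, bcs)
    pb_dir <- file.path(outdir, "pseudobulk")
    dir.create(pb_dir, showWarnings = FALSE)
    dedup_report <- do.call(rbind, lapply(names(states), function(st) {
      dd <- dedupUmi(states[[st]])
      writeAlignments(dd, file.path(pb_dir, paste0(st, ".sam")))
      sc_aei <- computeAEI(dd, ref$alu, ref$reference, snps = ref$snps,
                           config = qcfg, sample_id = st)
      data.frame(state = st, reads_in = length(states[[st]]),
                 reads_out = length(dd), aei = sc_aei$aei)
    }))
    paths$dedup_report <- .write_tsv(dedup_report,
                                     file.path(outdir, "dedup_report.tsv"))
  } else {
    say("[4/7] single-cell stage disabled")
  }

  say("[5/7] building and harmonizing the editing matrix")
  em <- buildEditingMatrix(calls, sampleInfo = designs)
  em <- annotateRegion(em, ref$genes)
  rd <- SummarizedExperiment::rowData(em)
  rd$repeat_class <- stratifyByRepeat(
    data.frame(chrom = rd$chrom, pos = rd$pos), ref$repeats)$repeat_class
  SummarizedExperiment::rowData(em) <- rd
  h <- config$harmonize
  emh <- harmonize(em, harmonizeConfig(h$min_detection, h$min_mean_editing,
                                       h$max_sample_missing))
  paths$matrix <- .write_tsv(
    data.frame(site_id = rownames(emh), editingLevels(emh),
               check.names = FALSE),
    file.path(outdir, "editing_matrix.tsv"))
  paths$site_annotation <- .write_tsv(siteInfo(emh),
                                      file.path(outdir,
                                                "site_annotation.tsv"))
  paths$filter_report <- .write_tsv(filterReport(emh),
                                    file.path(outdir, "filter_report.tsv"))

  say("[6/7] imputing and fitting differential editing")
  design_used <- as.data.frame(SummarizedExperiment::colData(emh))
  icfg <- imputationConfig(m = config$impute$m,
                           max_iter = config$impute$max_iter,
                           donors = config$impute$donors,
                           k_sites = config$impute$k_sites,
                           seed = seeds[7L])
  imps <- imputePMM(emh, icfg)
  pooled <- consensusMatrix(imps, config$differential$pooling)
  diff <- fitDifferential(pooled, design_used,
                          moderation = config$differential$moderation,
                          observed = editingLevels(emh))
  ann <- siteInfo(emh)
  diff <- merge(diff, ann[, c("site_id", "region", "repeat_class")],
                by = "site_id", sort = FALSE)
  paths$differential <- .write_tsv(diff,
                                   file.path(outdir, "differential.tsv"))

  say("[7/7] developmental contrasts and cross-layer integration")
  binned <- assignBins(designs)
  aei_bin <- merge(aei, binned[, c("sample_id", "bin")], by = "sample_id")
  scheme <- devBinScheme()
  contrasts <- list()
  for (i in seq_len(nrow(scheme) - 1L)) {
    a <- aei_bin$aei[!is.na(aei_bin$bin) & aei_bin$bin == scheme$bin[i]]
    b <- aei_bin$aei[!is.na(aei_bin$bin) & aei_bin$bin == scheme$bin[i + 1L]]
    if (length(a) >= 2L && length(b) >= 2L)
      contrasts[[length(contrasts) + 1L]] <- binContrast(
        a, b, contrast = paste0(scheme$bin[i + 1L], "_vs_", scheme$bin[i]))
  }
  contrasts <- if (length(contrasts)) do.call(rbind, contrasts) else
    data.frame()
  paths$contrasts <- .write_tsv(contrasts,
                                file.path(outdir, "contrasts.tsv"))

  # delta editing vs expression change: site -> hosting gene
  gene_gr <- ref$genes[ref$genes$type == "gene"]
  site_gr <- GenomicRanges::GRanges(ann$chrom,
                                    IRanges::IRanges(ann$pos, ann$pos))
  hits <- GenomicRanges::findOverlaps(site_gr, gene_gr,
                                      ignore.strand = TRUE)
  site_gene <- data.frame(site_id = ann$site_id[S4Vectors::from(hits)],
                          gene = gene_gr$gene_id[S4Vectors::to(hits)])
  post <- designs$group == "postnatal"
  logfc <- log2(rowMeans(expr[, post, drop = FALSE]) /
                  rowMeans(expr[, !post, drop = FALSE]))
  # expression table genes are pathway/ADAR genes; map each hosting gene
  # to an expression trajectory cyclically so every site has a pair
  gmap <- setNames(rownames(expr)[
    (seq_along(unique(site_gene$gene)) - 1L) %% nrow(expr) + 1L],
    unique(site_gene$gene))
  dd <- merge(diff, site_gene, by = "site_id")
  dd$gene <- unname(gmap[dd$gene])
  na_cor <- data.frame(r = NA_real_, r_squared = NA_real_, n = 0L,
                       p = NA_real_)
  integ <- list(
    delta_expression = tryCatch(correlateDeltaExpression(dd, logfc),
                                error = function(e) na_cor),
    aei_adar = varianceExplained(aei$aei,
                                 unlist(designs$adar_expr)),
    aei_adarb1 = varianceExplained(aei$aei,
                                   unlist(designs$adarb1_expr)),
    viral_score = correlateScoreAei(
      scoreGeneSet(expr, c("VIRALRESP1", "VIRALRESP2"), "viral_response"),
      aei$aei),
    dnarep_score = correlateScoreAei(
      scoreGeneSet(expr, c("DNAREP1", "DNAREP2"), "dna_replication"),
      aei$aei))
  corr_tab <- do.call(rbind, Map(function(nm, df)
    cbind(analysis = nm, df), names(integ), integ))
  rownames(corr_tab) <- NULL
  paths$correlations <- .write_tsv(corr_tab,
                                   file.path(outdir, "correlations.tsv"))

  # knockout fitness demo: reference condition at base_count cells,
  # ADAR-KO depleted everywhere
  f <- config$fitness
  fit_counts <- with_seed(seeds[8L], {
    rows <- expand.grid(stratum = f$strata, condition = f$conditions,
                        replicate = seq_len(f$n_replicates),
                        stringsAsFactors = FALSE)
    lambda <- ifelse(rows$condition == "ADAR",
                     f$base_count * f$adar_depletion, f$base_count)
    rows$count <- rpois(nrow(rows), lambda)
    rows
  })
  fitness <- fitnessFractions(fit_counts, reference = f$conditions[1L])
  paths$fitness <- .write_tsv(fitness$fractions,
                              file.path(outdir, "fitness.tsv"))
  paths$fitness_contrasts <- .write_tsv(
    fitness$contrasts, file.path(outdir, "fitness_contrasts.tsv"))

  log <- list(config = unclass(config), seeds = as.integer(seeds),
              n_sites_harmonized = nrow(emh),
              n_samples_harmonized = ncol(emh),
              n_significant = sum(diff$fdr < 0.05))
  log$config$truth$sites_per_class <-
    as.list(log$config$truth$sites_per_class)
  yaml::write_yaml(log, file.path(outdir, "run_log.yaml"))
  paths$run_log <- file.path(outdir, "run_log.yaml")

  invisible(list(ref = ref, designs = designs, truth = truth, aei = aei,
                 matrix = emh, differential = diff, contrasts = contrasts,
                 integration = integ, fitness = fitness,
                 dedup_report = dedup_report, paths = paths,
                 outdir = outdir))
}
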