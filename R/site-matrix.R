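#' Assemble per-sample site calls into an EditingMatrix
#'
#' Takes the union of sites across samples (ordered by chromosome and
#' position) and fills a sites-by-samples matrix with editing levels where
#' the call status is `CALLED`; every other status (low coverage, low
#' edited count, SNP-masked, not detected) becomes a missing entry. A site
#' appearing twice within one sample's calls is an integrity error.
#'
#' @param calls named list of data.frames from [callSites()], one per
#'   sample; names are sample ids.
#' @param sampleInfo optional per-sample design data.frame (matched by
#'   `sample_id`); stored as `colData`.
#' @return an [EditingMatrix-class].
#' @export
buildEditingMatrix <- function(calls, sampleInfo = NULL) {
  stopifnot(is.list(calls), length(names(calls)) == length(calls))
  for (sm in names(calls)) {
    if (anyDuplicated(calls[[sm]]$site_id))
      stop(sprintf("duplicate site within sample '%s'", sm), call. = FALSE)
  }
  all_sites <- unique(do.call(rbind, lapply(calls, function(df)
    df[, c("site_id", "chrom", "pos", "strand")])))
  if (nrow(all_sites) == 0L) {
    return(EditingMatrix(
      matrix(numeric(0), 0L, length(calls),
             dimnames = list(NULL, names(calls))),
      siteInfo = data.frame(site_id = character(0), chrom = character(0),
                            pos = integer(0), strand = character(0)),
      sampleInfo = sampleInfo))
  }
  all_sites <- all_sites[order(all_sites$chrom, all_sites$pos), , drop = FALSE]
  rownames(all_sites) <- NULL
  lv <- matrix(NA_real_, nrow(all_sites), length(calls),
               dimnames = list(all_sites$site_id, names(calls)))
  for (sm in names(calls)) {
    df <- calls[[sm]]
    called <- df$status == "CALLED"
    lv[match(df$site_id[called], all_sites$site_id), sm] <- df$level[called]
  }
  if (is.null(sampleInfo))
    sampleInfo <- data.frame(sample_id = names(calls))
  EditingMatrix(lv, siteInfo = all_sites, sampleInfo = sampleInfo)
}

#' Harmonization thresholds
#'
#' Filters applied by [harmonize()]: sites must be detected (called) in at
#' least `min_detection` of samples and average at least
#' `min_mean_editing` editing where observed; samples missing more than
#' `max_sample_missing` of sites are excluded first.
#'
#' @param min_detection minimum per-site detection rate.
#' @param min_mean_editing minimum per-site mean editing level.
#' @param max_sample_missing maximum per-sample missing fraction.
#' @return a list of class `"HarmonizeConfig"`.
#' @export
harmonizeConfig <- function(min_detection = 0.60, min_mean_editing = 0.05,
                            max_sample_missing = 0.20) {
  .assert_fraction(min_detection, "min_detection")
  .assert_fraction(min_mean_editing, "min_mean_editing")
  .assert_fraction(max_sample_missing, "max_sample_missing")
  structure(list(min_detection = min_detection,
                 min_mean_editing = min_mean_editing,
                 max_sample_missing = max_sample_missing),
            class = "HarmonizeConfig")
}

#' Harmonize an editing matrix
#'
#' Applies the quality filters in a fixed order: (1) drop samples whose
#' missing fraction exceeds `max_sample_missing`; (2) recompute site
#' statistics over the retained samples; (3) drop sites below the
#' detection-rate or mean-editing thresholds. Sample exclusion runs first
#' so that detection rates describe the samples that remain. Every dropped
#' item is recorded, with its reason and offending value, in the filter
#' report available via [filterReport()].
#'
#' @param em an [EditingMatrix-class].
#' @param config a [harmonizeConfig()].
#' @return the filtered `EditingMatrix`; errors if every sample is dropped.
#' @export
harmonize <- function(em, config = harmonizeConfig()) {
  stopifnot(is(em, "EditingMatrix"), inherits(config, "HarmonizeConfig"))
  report <- list()
  miss <- sampleMissingness(em)
  bad_samples <- names(miss)[miss > config$max_sample_missing]
  if (length(bad_samples))
    report[[length(report) + 1L]] <- data.frame(
      item = bad_samples, axis = "sample", reason = "missing_fraction",
      value = unname(miss[bad_samples]))
  keep_samples <- setdiff(colnames(em), bad_samples)
  if (!length(keep_samples))
    stop("harmonization removed every sample", call. = FALSE)
  em2 <- em[, keep_samples]

  det <- detectionRate(em2)
  mea <- meanEditing(em2)
  low_det <- det < config$min_detection
  low_mean <- !low_det & (is.nan(mea) | mea < config$min_mean_editing)
  if (any(low_det))
    report[[length(report) + 1L]] <- data.frame(
      item = rownames(em2)[low_det], axis = "site",
      reason = "detection_rate", value = unname(det[low_det]))
  if (any(low_mean))
    report[[length(report) + 1L]] <- data.frame(
      item = rownames(em2)[low_mean], axis = "site",
      reason = "mean_editing", value = unname(mea[low_mean]))
  em3 <- em2[!(low_det | low_mean), ]
  report <- if (length(report)) do.call(rbind, report) else
    data.frame(item = character(), axis = character(),
               reason = character(), value = numeric())
  rownames(report) <- NULL
  S4Vectors::metadata(em3)$filter_report <- report
  S4Vectors::metadata(em3)$harmonize_config <- config
  em3
}
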