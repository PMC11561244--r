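#' EditingMatrix: sites-by-samples editing levels
#'
#' An `EditingMatrix` is a [SummarizedExperiment::SummarizedExperiment]
#' carrying one assay, `"levels"`, the per-site editing fraction (edited /
#' (edited + unedited) reads in the site's strand frame) with `NA` marking
#' sites not called in a sample. `rowData` holds the site annotation
#' (`site_id`, `chrom`, `pos`, `strand`, and, when annotated, `repeat_class`
#' and `region`); `colData` holds the sample design (age, sex, group, ADAR and
#' ADARB1 expression, modality). Detection rates and per-sample missingness
#' are always derived from the current assay so they can never drift out of
#' step with the data.
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment]; no extra slots.
#' @seealso [buildEditingMatrix()], [harmonize()], [detectionRate()],
#'   [meanEditing()], [sampleMissingness()]
#' @export
setClass("EditingMatrix", contains = "SummarizedExperiment")

setValidity("EditingMatrix", function(object) {
  msg <- NULL
  if (!("levels" %in% SummarizedExperiment::assayNames(object)))
    msg <- c(msg, "assay 'levels' is required")
  else {
    lv <- SummarizedExperiment::assay(object, "levels")
    if (!is.numeric(lv))
      msg <- c(msg, "assay 'levels' must be numeric")
    else if (any(lv < 0 | lv > 1, na.rm = TRUE))
      msg <- c(msg, "editing levels must lie in [0, 1] where present")
  }
  rd <- SummarizedExperiment::rowData(object)
  for (col in c("site_id", "chrom", "pos"))
    if (!(col %in% colnames(rd)))
      msg <- c(msg, sprintf("rowData column '%s' is required", col))
  if ("site_id" %in% colnames(rd) && anyDuplicated(rd$site_id))
    msg <- c(msg, "duplicate site_id in rowData")
  if (is.null(msg)) TRUE else msg
})

#' Construct an EditingMatrix
#'
#' @param levels numeric matrix, sites x samples, editing fractions with `NA`
#'   for missing entries.
#' @param siteInfo data.frame with one row per site: `site_id`, `chrom`,
#'   `pos` (1-based), `strand`, plus any extra annotation columns.
#' @param sampleInfo data.frame with one row per sample (matched to the
#'   columns of `levels` by `sample_id` or by order).
#' @return an [EditingMatrix-class] object.
#' @export
EditingMatrix <- function(levels, siteInfo, sampleInfo = NULL) {
  levels <- as.matrix(levels)
  stopifnot(nrow(levels) == nrow(siteInfo))
  rownames(levels) <- siteInfo$site_id
  if (is.null(sampleInfo)) {
    sampleInfo <- S4Vectors::DataFrame(
      sample_id = colnames(levels) %||% paste0("S", seq_len(ncol(levels))))
  }
  sampleInfo <- S4Vectors::DataFrame(sampleInfo)
  if ("sample_id" %in% colnames(sampleInfo)) {
    if (!is.null(colnames(levels))) {
      idx <- match(colnames(levels), sampleInfo$sample_id)
      if (anyNA(idx)) stop("sampleInfo lacks entries for some samples")
      sampleInfo <- sampleInfo[idx, , drop = FALSE]
    }
    rownames(sampleInfo) <- sampleInfo$sample_id
    colnames(levels) <- sampleInfo$sample_id
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(levels = levels),
    rowData = S4Vectors::DataFrame(siteInfo),
    colData = sampleInfo)
  new("EditingMatrix", se)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
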