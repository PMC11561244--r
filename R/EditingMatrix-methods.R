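#' Accessors for EditingMatrix objects
#'
#' `editingLevels()` returns the sites x samples matrix of editing fractions
#' (`NA` = not called). `detectionRate()` gives, per site, the fraction of
#' samples in which the site was called; `meanEditing()` the mean level over
#' non-missing entries; `sampleMissingness()` the per-sample fraction of
#' missing sites. `siteInfo()` returns the site annotation, and
#' `filterReport()` the harmonization drop report (empty before
#' [harmonize()] has been run).
#'
#' All summaries are recomputed from the current assay, so subsetting an
#' `EditingMatrix` with `[` keeps them consistent automatically.
#'
#' @param x an [EditingMatrix-class].
#' @return see details per accessor.
#' @name EditingMatrix-accessors
NULL

#' @rdname EditingMatrix-accessors
#' @export
setMethod("editingLevels", "EditingMatrix", function(x) {
  SummarizedExperiment::assay(x, "levels")
})

#' @rdname EditingMatrix-accessors
#' @export
setMethod("detectionRate", "EditingMatrix", function(x) {
  lv <- editingLevels(x)
  if (ncol(lv) == 0L) return(setNames(numeric(nrow(lv)), rownames(lv)))
  rowMeans(!is.na(lv))
})

#' @rdname EditingMatrix-accessors
#' @export
setMethod("meanEditing", "EditingMatrix", function(x) {
  rowMeans(editingLevels(x), na.rm = TRUE)
})

#' @rdname EditingMatrix-accessors
#' @export
setMethod("sampleMissingness", "EditingMatrix", function(x) {
  lv <- editingLevels(x)
  if (nrow(lv) == 0L) return(setNames(numeric(ncol(lv)), colnames(lv)))
  colMeans(is.na(lv))
})

#' @rdname EditingMatrix-accessors
#' @export
setMethod("siteInfo", "EditingMatrix", function(x) {
  as.data.frame(SummarizedExperiment::rowData(x))
})

#' @rdname EditingMatrix-accessors
#' @export
setMethod("filterReport", "EditingMatrix", function(x) {
  rep <- S4Vectors::metadata(x)$filter_report
  if (is.null(rep)) {
    rep <- data.frame(item = character(), axis = character(),
                      reason = character(), value = numeric())
  }
  rep
})

setMethod("show", "EditingMatrix", function(object) {
  lv <- editingLevels(object)
  cat(sprintf("EditingMatrix: %d sites x %d samples\n", nrow(lv), ncol(lv)))
  if (length(lv)) {
    cat(sprintf("  missing: %.1f%% | mean editing (called): %.3f\n",
                100 * mean(is.na(lv)), mean(lv, na.rm = TRUE)))
  }
  rd <- SummarizedExperiment::rowData(object)
  extra <- setdiff(colnames(rd), c("site_id", "chrom", "pos", "strand"))
  if (length(extra))
    cat("  site annotation:", paste(extra, collapse = ", "), "\n")
  nrep <- nrow(filterReport(object))
  if (nrep) cat(sprintf("  harmonized (%d items dropped)\n", nrep))
})
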