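#' @rdname EditingMatrix-accessors
#' @export
setGeneric("editingLevels", function(x) standardGeneric("editingLevels"))

#' @rdname EditingMatrix-accessors
#' @export
setGeneric("detectionRate", function(x) standardGeneric("detectionRate"))

#' @rdname EditingMatrix-accessors
#' @export
setGeneric("meanEditing", function(x) standardGeneric("meanEditing"))

#' @rdname EditingMatrix-accessors
#' @export
setGeneric("sampleMissingness", function(x) standardGeneric("sampleMissingness"))

#' @rdname EditingMatrix-accessors
#' @export
setGeneric("siteInfo", function(x) standardGeneric("siteInfo"))

#' @rdname EditingMatrix-accessors
#' @export
setGeneric("filterReport", function(x) standardGeneric("filterReport"))
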