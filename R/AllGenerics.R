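#' @import methods
NULL

#' Accessor generics
#'
#' Small accessor generics used across the package's S4 classes. Each has a
#' method for the classes where the quantity is defined; see the class pages
#' for details.
#'
#' @param x an object of one of the package's S4 classes
#' @return the requested component (a numeric vector, matrix or scalar).
#' @name accessors
#' @aliases intensities timeAxis wavelengthAxis frequencyAxis magnitudes
#'   binResolution estimatedHz estimatedBpm provenance
NULL

#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname accessors
#' @export
setGeneric("timeAxis", function(x) standardGeneric("timeAxis"))

#' @rdname accessors
#' @export
setGeneric("wavelengthAxis", function(x) standardGeneric("wavelengthAxis"))

#' @rdname accessors
#' @export
setGeneric("frequencyAxis", function(x) standardGeneric("frequencyAxis"))

#' @rdname accessors
#' @export
setGeneric("magnitudes", function(x) standardGeneric("magnitudes"))

#' @rdname accessors
#' @export
setGeneric("binResolution", function(x) standardGeneric("binResolution"))

#' @rdname accessors
#' @export
setGeneric("estimatedHz", function(x) standardGeneric("estimatedHz"))

#' @rdname accessors
#' @export
setGeneric("estimatedBpm", function(x) standardGeneric("estimatedBpm"))

#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' Confusion-matrix accessors
#'
#' Extract the raw counts or the derived diagnostic fractions from a
#' \linkS4class{ConfusionMetrics} object. Ratios with a zero denominator are
#' `NA`, never silently 0.
#'
#' @param x a \linkS4class{ConfusionMetrics} object
#' @return `confusionCounts()` returns a named integer vector
#'   (`tp`, `fp`, `tn`, `fn`); the others return a single numeric in
#'   `[0, 1]` or `NA`.
#' @name confusion-accessors
#' @aliases confusionCounts sensitivity specificity positivePredictivity
#'   accuracy
NULL

#' @rdname confusion-accessors
#' @export
setGeneric("confusionCounts", function(x) standardGeneric("confusionCounts"))

#' @rdname confusion-accessors
#' @export
setGeneric("sensitivity", function(x) standardGeneric("sensitivity"))

#' @rdname confusion-accessors
#' @export
setGeneric("specificity", function(x) standardGeneric("specificity"))

#' @rdname confusion-accessors
#' @export
setGeneric("positivePredictivity",
           function(x) standardGeneric("positivePredictivity"))

#' @rdname confusion-accessors
#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))

#' Grid-report accessors
#'
#' Components of a \linkS4class{GridReport}: the per-recording results table,
#' the per-displacement uncertainty summary, the overall mean percent
#' uncertainty, and the normal/abnormal confusion metrics.
#'
#' @param x a \linkS4class{GridReport}
#' @name gridreport-accessors
#' @aliases gridResults displacementSummary overallUncertainty gridConfusion
NULL

#' @rdname gridreport-accessors
#' @export
setGeneric("gridResults", function(x) standardGeneric("gridResults"))

#' @rdname gridreport-accessors
#' @export
setGeneric("displacementSummary",
           function(x) standardGeneric("displacementSummary"))

#' @rdname gridreport-accessors
#' @export
setGeneric("overallUncertainty",
           function(x) standardGeneric("overallUncertainty"))

#' @rdname gridreport-accessors
#' @export
setGeneric("gridConfusion", function(x) standardGeneric("gridConfusion"))
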