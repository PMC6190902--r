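#' @rdname GenotypeExperiment-class
#' @param object,x a MantelQTL object
#' @param ... passed to methods
#' @export
setGeneric("dosages", function(x, ...) standardGeneric("dosages"))

#' @rdname GenotypeExperiment-class
#' @export
setGeneric("markerMap", function(x, ...) standardGeneric("markerMap"))

#' @rdname GenotypeExperiment-class
#' @export
setGeneric("markerIds", function(x, ...) standardGeneric("markerIds"))

#' @rdname GenotypeExperiment-class
#' @export
setGeneric("sampleIds", function(x, ...) standardGeneric("sampleIds"))

#' @rdname PhenotypeTable-class
#' @export
setGeneric("measureValues", function(x, ...) standardGeneric("measureValues"))

#' @rdname PhenotypeTable-class
#' @export
setGeneric("categoryMap", function(x, ...) standardGeneric("categoryMap"))

#' @rdname PhenotypeTable-class
#' @export
setGeneric("categories", function(x, ...) standardGeneric("categories"))

#' @rdname PhenotypeTable-class
#' @param category a category name
#' @export
setGeneric("categoryMeasures",
           function(x, category, ...) standardGeneric("categoryMeasures"))

#' @rdname SelectionCurve-class
#' @export
setGeneric("curveStat", function(x, ...) standardGeneric("curveStat"))

#' @rdname SelectionCurve-class
#' @export
setGeneric("curveMarkers", function(x, ...) standardGeneric("curveMarkers"))

#' @rdname SelectionCurve-class
#' @export
setGeneric("peakIndex", function(x, ...) standardGeneric("peakIndex"))

#' @rdname SelectionCurve-class
#' @export
setGeneric("peakValue", function(x, ...) standardGeneric("peakValue"))

#' @rdname SelectionCurve-class
#' @export
setGeneric("peakMarkers", function(x, ...) standardGeneric("peakMarkers"))

#' @rdname NullCurveEnsemble-class
#' @export
setGeneric("nullCurves", function(x, ...) standardGeneric("nullCurves"))

#' @rdname NullCurveEnsemble-class
#' @export
setGeneric("nullMean", function(x, ...) standardGeneric("nullMean"))

#' @rdname NullCurveEnsemble-class
#' @export
setGeneric("nullSD", function(x, ...) standardGeneric("nullSD"))

#' @rdname FounderPanel-class
#' @export
setGeneric("founderHaplotypes",
           function(x, ...) standardGeneric("founderHaplotypes"))

#' @rdname FounderPanel-class
#' @export
setGeneric("targetMaf", function(x, ...) standardGeneric("targetMaf"))
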