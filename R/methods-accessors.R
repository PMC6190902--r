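#' @describeIn GenotypeExperiment-class dosage matrix, samples x markers
#' @export
setMethod("dosages", "GenotypeExperiment", function(x, ...) {
    t(SummarizedExperiment::assay(x, "dosage"))
})

#' @describeIn GenotypeExperiment-class marker map as a data.frame
#'   (marker, chrom, bp, ref, alt)
#' @export
setMethod("markerMap", "GenotypeExperiment", function(x, ...) {
    rd <- rowData(x)
    data.frame(marker = rownames(x), chrom = rd$chrom, bp = rd$bp,
               ref = rd$ref, alt = rd$alt, row.names = NULL)
})

#' @describeIn GenotypeExperiment-class marker ids
#' @export
setMethod("markerIds", "GenotypeExperiment", function(x, ...) rownames(x))

#' @describeIn GenotypeExperiment-class sample ids
#' @export
setMethod("sampleIds", "GenotypeExperiment", function(x, ...) colnames(x))

#' @describeIn PhenotypeTable-class sample ids
#' @export
setMethod("sampleIds", "PhenotypeTable", function(x, ...) rownames(x@values))

#' @describeIn PhenotypeTable-class measure matrix, samples x measures
#' @export
setMethod("measureValues", "PhenotypeTable", function(x, ...) x@values)

#' @describeIn PhenotypeTable-class named vector measure -> category
#' @export
setMethod("categoryMap", "PhenotypeTable", function(x, ...) x@categoryMap)

#' @describeIn PhenotypeTable-class category names in map order
#' @export
setMethod("categories", "PhenotypeTable", function(x, ...) {
    unique(unname(x@categoryMap))
})

#' @describeIn PhenotypeTable-class measure names belonging to a category
#' @export
setMethod("categoryMeasures", "PhenotypeTable", function(x, category, ...) {
    out <- names(x@categoryMap)[x@categoryMap == category]
    if (!length(out)) stop("unknown category: ", category)
    out
})

#' @describeIn PhenotypeTable-class subset samples (i) and measures (j)
#' @param i,j,drop sample / measure indices (drop is ignored)
#' @export
setMethod("[", "PhenotypeTable", function(x, i, j, ..., drop = FALSE) {
    v <- x@values
    if (!missing(i)) v <- v[i, , drop = FALSE]
    if (!missing(j)) v <- v[, j, drop = FALSE]
    makePhenotypes(v, x@categoryMap)
})

setMethod("show", "PhenotypeTable", function(object) {
    v <- object@values
    cat("PhenotypeTable:", nrow(v), "samples x", ncol(v), "measures in",
        length(unique(object@categoryMap)), "categories\n")
    cat("categories:",
        paste(utils::head(unique(unname(object@categoryMap)), 8),
              collapse = ", "), "\n")
})

#' @describeIn FounderPanel-class founder x marker allele matrix
#' @export
setMethod("founderHaplotypes", "FounderPanel", function(x, ...) x@haplotypes)

#' @describeIn FounderPanel-class marker map data.frame
#' @export
setMethod("markerMap", "FounderPanel", function(x, ...) x@markerMap)

#' @describeIn FounderPanel-class per-marker target minor-allele frequency
#' @export
setMethod("targetMaf", "FounderPanel", function(x, ...) x@targetMaf)

#' @describeIn FounderPanel-class marker ids
#' @export
setMethod("markerIds", "FounderPanel", function(x, ...) x@markerMap$marker)

setMethod("show", "FounderPanel", function(object) {
    cat("FounderPanel:", nrow(object@haplotypes), "founders x",
        ncol(object@haplotypes), "markers on",
        length(unique(object@markerMap$chrom)), "chromosomes\n")
})

#' @describeIn SelectionCurve-class cumulative correlations c_k
#' @export
setMethod("curveStat", "SelectionCurve", function(x, ...) x@stat)

#' @describeIn SelectionCurve-class included markers in selection order
#' @export
setMethod("curveMarkers", "SelectionCurve", function(x, ...) x@markers)

#' @describeIn SelectionCurve-class selected set size k*
#' @export
setMethod("peakIndex", "SelectionCurve", function(x, ...) x@peakK)

#' @describeIn SelectionCurve-class cumulative correlation at k*
#' @export
setMethod("peakValue", "SelectionCurve", function(x, ...) {
    x@stat[x@peakK]
})

#' @describeIn SelectionCurve-class the selected marker set (first k*)
#' @export
setMethod("peakMarkers", "SelectionCurve", function(x, ...) {
    x@markers[seq_len(x@peakK)]
})

setMethod("length", "SelectionCurve", function(x) length(x@stat))

setMethod("show", "SelectionCurve", function(object) {
    cat("SelectionCurve:", length(object@stat), "set sizes, gate p <",
        object@pGate, "\n")
    cat(sprintf("peak: k* = %d, c = %.4f (plateau tol %.3g)\n",
                object@peakK, object@stat[object@peakK], object@plateauTol))
})

#' @describeIn NullCurveEnsemble-class matrix of null curves (R x K)
#' @export
setMethod("nullCurves", "NullCurveEnsemble", function(x, ...) x@curves)

#' @describeIn NullCurveEnsemble-class per-k null mean
#' @export
setMethod("nullMean", "NullCurveEnsemble", function(x, ...) x@mu)

#' @describeIn NullCurveEnsemble-class per-k null standard deviation
#' @export
setMethod("nullSD", "NullCurveEnsemble", function(x, ...) x@sigma)

setMethod("show", "NullCurveEnsemble", function(object) {
    cat("NullCurveEnsemble:", nrow(object@curves), "shuffles x",
        ncol(object@curves), "set sizes\n")
    cat(sprintf("max null curve value: %.4f\n", max(object@curves)))
})
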