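# Forward selection of marker sets: markers enter in decreasing order of
# single-marker association (the order is fixed by the initial scan, not
# re-scored after each inclusion) and the cumulative set-level Mantel
# correlation is tracked at each set size.

#' Markers passing the per-marker significance gate
#'
#' The first overfitting guard: only markers individually significant at
#' \code{p < pGate} (default 0.01) may enter the forward selection, in
#' scan rank order.
#'
#' @param scan a scan data.frame from \code{\link{singleMarkerScan}}.
#' @param pGate gate threshold (strict less-than).
#' @return character vector of eligible marker ids (may be empty).
#' @export
eligibleMarkers <- function(scan, pGate = 0.01) {
    .assertFraction(pGate, "pGate", lo = 0, hi = 1, lo.open = TRUE)
    stopifnot(is.data.frame(scan), nrow(scan) > 0)
    out <- scan$marker[scan$p < pGate]
    if (!length(out)) message("no markers pass the gate p < ", pGate)
    out
}

#' Cumulative Mantel correlation curve under forward selection
#'
#' For each set size k, correlates the Manhattan genotype distance over
#' the first k markers with the phenotype distance matrix. Manhattan
#' additivity over markers is exploited: the genotype pair-distance vector
#' is updated incrementally, which equals full recomputation at every k.
#'
#' @param g a \linkS4class{GenotypeExperiment}.
#' @param phenoD phenotype distance matrix over the same samples.
#' @param markers ordered marker ids (typically
#'   \code{\link{eligibleMarkers}} output).
#' @param maxK largest set size to evaluate
#'   (default \code{min(length(markers), 1000)}).
#' @param pGate recorded gate threshold (metadata only).
#' @param plateauTol plateau tolerance used for the stored peak
#'   (see \code{\link{selectPeak}}).
#' @param metric genotype distance metric; both Manhattan dosage and IBS
#'   mismatch distances are additive over markers, so the incremental
#'   update applies to either.
#' @return a \linkS4class{SelectionCurve}.
#' @export
cumulativeCurve <- function(g, phenoD, markers, maxK = NULL, pGate = 0.01,
                            plateauTol = 0.02,
                            metric = c("manhattan", "ibs")) {
    metric <- match.arg(metric)
    stopifnot(is(g, "GenotypeExperiment"), is.matrix(phenoD))
    if (!length(markers)) stop("'markers' must be nonempty")
    if (is.null(maxK)) maxK <- min(length(markers), 1000L)
    maxK <- min(.assertCount(maxK, "maxK"), length(markers))
    markers <- markers[seq_len(maxK)]
    ids <- sampleIds(g)
    if (!setequal(rownames(phenoD), ids)) {
        stop("genotype and phenotype distance cover different samples")
    }
    phenoD <- phenoD[ids, ids]
    idx <- .pairIndices(length(ids))
    d <- dosages(g)[, markers, drop = FALSE]
    if (anyNA(d)) stop("missing dosages; impute before selection")
    X <- if (metric == "ibs") {
        (d[idx$i, , drop = FALSE] != d[idx$j, , drop = FALSE]) + 0
    } else {
        abs(d[idx$i, , drop = FALSE] - d[idx$j, , drop = FALSE])
    }
    y <- .lowerTri(phenoD)
    stat <- .cumulativeCorSeq(X, y)
    peak <- .plateauEntry(stat, plateauTol)
    new("SelectionCurve", markers = markers, stat = stat, pGate = pGate,
        plateauTol = plateauTol, peakK = peak)
}

# cumulative-correlation sequence over columns of X against y, using the
# same cross-product arithmetic as the scan so c_1 matches the scan r
.cumulativeCorSeq <- function(X, y) {
    np <- length(y)
    sy <- sum(y)
    vy <- sum(y * y) - sy * sy / np
    if (vy <= 0) stop("constant phenotype distance vector")
    d <- numeric(np)
    out <- numeric(ncol(X))
    for (k in seq_len(ncol(X))) {
        d <- d + X[, k]
        sx <- sum(d)
        vx <- sum(d * d) - sx * sx / np
        out[k] <- if (vx <= 0) NA_real_ else
            (as.vector(crossprod(d, y)) - sx * sy / np) /
                (sqrt(vx) * sqrt(vy))
    }
    out
}

# earliest entry into the plateau
.plateauEntry <- function(stat, plateauTol) {
    cmax <- max(stat, na.rm = TRUE)
    thr <- (1 - plateauTol) * cmax
    # with a negative maximum the tolerance band still must contain cmax
    if (cmax < 0) thr <- cmax / (1 - plateauTol)
    as.integer(which(!is.na(stat) & stat >= thr)[1L])
}

#' Select the peak of a cumulative correlation curve
#'
#' The selected set size k* is the smallest k whose cumulative correlation
#' reaches \code{(1 - plateauTol)} of the curve maximum - the earliest
#' entry into the plateau. With \code{plateauTol = 0} this is the exact
#' argmax (first of ties).
#'
#' @param curve a \linkS4class{SelectionCurve}, or a bare numeric vector of
#'   cumulative correlations.
#' @param plateauTol plateau tolerance in [0, 1) (default 0.02).
#' @return for a \linkS4class{SelectionCurve}: the curve with its peak
#'   updated; for a numeric vector: a list with \code{k} and \code{value}.
#' @examples
#' selectPeak(c(0.10, 0.30, 0.25, 0.20), plateauTol = 0)$k  # 2
#' @export
selectPeak <- function(curve, plateauTol = 0.02) {
    .assertFraction(plateauTol, "plateauTol", lo = 0, hi = 1, hi.open = TRUE)
    if (is.numeric(curve)) {
        if (!length(curve)) stop("empty curve")
        k <- .plateauEntry(curve, plateauTol)
        return(list(k = k, value = curve[k]))
    }
    stopifnot(is(curve, "SelectionCurve"))
    curve@peakK <- .plateauEntry(curve@stat, plateauTol)
    curve@plateauTol <- plateauTol
    methods::validObject(curve)
    curve
}
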