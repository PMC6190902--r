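#' Scan and forward-select every phenotype category in one pass
#'
#' Runs \code{\link{singleMarkerScan}} followed by gate and
#' \code{\link{cumulativeCurve}} for each category, sharing the marker
#' pair-distance vectors (the expensive part of a scan) across
#' categories. The per-category "peak correlation" is the peak of the
#' forward-selection curve, falling back to the best single-marker
#' statistic when no marker passes the gate.
#'
#' @param g a \linkS4class{GenotypeExperiment} (MAF-filtered).
#' @param pheno a \linkS4class{PhenotypeTable} covering the same samples.
#' @param categories categories to analyse (default: all).
#' @param B scan permutations.
#' @param pGate per-marker gate threshold.
#' @param maxK largest set size retained.
#' @param plateauTol plateau tolerance.
#' @param standardize passed to \code{\link{phenotypeDistance}}.
#' @param seed master seed; categories draw child seeds.
#' @return named list per category: \code{scan} (data.frame), \code{curve}
#'   (\linkS4class{SelectionCurve} or NULL), \code{peak} (numeric peak
#'   correlation as defined above).
#' @export
scanCategories <- function(g, pheno, categories = NULL, B = 199,
                           pGate = 0.01, maxK = NULL, plateauTol = 0.02,
                           standardize = TRUE, seed = NULL) {
    stopifnot(is(g, "GenotypeExperiment"), is(pheno, "PhenotypeTable"))
    if (is.null(categories)) categories <- categories(pheno)
    B <- .assertCount(B, "B")
    ids <- sampleIds(g)
    n <- length(ids)
    idx <- .pairIndices(n)
    lookup <- .pairLookup(n)
    X <- .markerPairVectors(g, idx)
    xStats <- .colStats(X)
    if (is.null(maxK)) maxK <- min(ncol(X), 1000L)
    map <- markerMap(g)
    map <- map[match(colnames(X), map$marker), , drop = FALSE]
    seeds <- if (is.null(seed)) rep(list(NULL), length(categories)) else
        .childSeeds(seed, length(categories))
    out <- lapply(seq_along(categories), function(ci) {
        phenoD <- phenotypeDistance(pheno, categories[ci],
                                    standardize = standardize,
                                    samples = ids)
        y <- .lowerTri(phenoD)
        .setSeed(seeds[[ci]])
        res <- .scanAgainst(X, y, n, B, lookup = lookup, idx = idx,
                            xStats = xStats)
        scan <- data.frame(marker = map$marker, chrom = map$chrom,
                           bp = map$bp, r = res$r, p = res$p)
        ord <- order(-scan$r, scan$p, seq_len(nrow(scan)))
        scan <- scan[ord, , drop = FALSE]
        scan$rank <- seq_len(nrow(scan))
        rownames(scan) <- NULL
        elig <- scan$marker[scan$p < pGate]
        curve <- NULL
        peak <- max(scan$r)
        if (length(elig)) {
            elig <- elig[seq_len(min(length(elig), maxK))]
            stat <- .cumulativeCorSeq(X[, elig, drop = FALSE], y)
            curve <- new("SelectionCurve", markers = elig, stat = stat,
                         pGate = pGate, plateauTol = plateauTol,
                         peakK = .plateauEntry(stat, plateauTol))
            peak <- peakValue(curve)
        }
        list(scan = structure(scan, B = B, seed = seeds[[ci]],
                              alternative = "greater"),
             curve = curve, peak = peak)
    })
    names(out) <- categories
    out
}
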