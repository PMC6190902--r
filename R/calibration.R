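# The second overfitting guard: an empirical null for the ENTIRE selection
# procedure. Sample labels of the phenotype data are shuffled (breaking the
# genotype-phenotype link while leaving condition labels attached to the
# genotypes), and the whole procedure - re-scan, re-gate, re-select - is
# repeated per shuffle. Observed cumulative correlations are then expressed
# as Z-scores against the per-k null mean and standard deviation.

#' One-sided normal tail probability for a Z-score
#'
#' Converts a calibration Z-score to its upper-tail normal probability;
#' \code{zToP(3)} is 0.00135, \code{zToP(5)} is 2.9e-7.
#' @param z numeric Z-score(s).
#' @return upper-tail probability.
#' @export
zToP <- function(z) {
    stats::pnorm(z, lower.tail = FALSE)
}

# run scan -> gate -> cumulative curve for one phenotype pair vector y
# against prebuilt marker pair vectors X; returns the curve values (may be
# length zero when nothing passes the gate)
.gatedCurve <- function(X, y, n, B, pGate, maxK, lookup, idx,
                        xStats = NULL) {
    scan <- .scanAgainst(X, y, n, B, lookup = lookup, idx = idx,
                         xStats = xStats)
    ord <- order(-scan$r, scan$p, seq_along(scan$r))
    elig <- ord[scan$p[ord] < pGate]
    if (!length(elig)) return(numeric(0))
    elig <- elig[seq_len(min(length(elig), maxK))]
    .cumulativeCorSeq(X[, elig, drop = FALSE], y)
}

# right-pad curves by carrying the last value; zero-length -> flat zeros
.padCurve <- function(v, K) {
    if (!length(v)) return(numeric(K))
    c(v, rep(v[length(v)], K))[seq_len(K)]
}

#' Label-shuffled null ensemble for the selection procedure
#'
#' For each of \code{R} shuffles of the phenotype sample labels (the
#' identity permutation is excluded), repeats the entire observed
#' procedure with identical parameters: single-marker scan with \code{B}
#' permutations, significance gate at \code{pGate}, and cumulative
#' forward-selection curve. Shuffles with no gate-passing markers
#' contribute a flat zero curve; shorter curves are right-padded by
#' carrying their last value.
#'
#' @param g a \linkS4class{GenotypeExperiment} (MAF-filtered).
#' @param pheno a \linkS4class{PhenotypeTable} covering the same samples.
#' @param category phenotype category to analyse.
#' @param B scan permutations per shuffle.
#' @param R number of shuffles (>= 2).
#' @param pGate per-marker gate threshold.
#' @param maxK largest set size retained.
#' @param standardize passed to \code{\link{phenotypeDistance}}.
#' @param metric genotype distance metric.
#' @param seed master seed of the ensemble.
#' @return a \linkS4class{NullCurveEnsemble}.
#' @export
nullEnsemble <- function(g, pheno, category, B = 199, R = 25, pGate = 0.01,
                         maxK = NULL, standardize = TRUE,
                         metric = c("manhattan", "ibs"), seed = NULL) {
    R <- .assertCount(R, "R", min = 2L)
    B <- .assertCount(B, "B")
    ca <- calibratedAnalysis(g, pheno, category, B = B, R = R, pGate = pGate,
                             maxK = maxK, standardize = standardize,
                             metric = metric, seed = seed, observed = FALSE)
    ca$ensemble
}

#' Z-score curve of an observed selection curve against its null
#'
#' \eqn{Z_k = (c_k - \mu_k) / \sigma_k} per set size k. Where the null
#' standard deviation is zero the Z-score is undefined and returned as
#' \code{NA} with \code{defined = FALSE}. When observed and ensemble
#' lengths differ, the shorter is right-padded by carrying its last value.
#'
#' @param observed a \linkS4class{SelectionCurve} (or numeric curve).
#' @param ensemble a \linkS4class{NullCurveEnsemble} built with identical
#'   parameters.
#' @return data.frame with columns k, c, mu, sigma, z, defined.
#' @export
zCurve <- function(observed, ensemble) {
    stopifnot(is(ensemble, "NullCurveEnsemble"))
    cv <- if (is.numeric(observed)) observed else curveStat(observed)
    K <- max(length(cv), ncol(nullCurves(ensemble)))
    cv <- .padCurve(cv, K)
    mu <- .padCurve(nullMean(ensemble), K)
    sigma <- .padCurve(nullSD(ensemble), K)
    z <- ifelse(sigma > 0, (cv - mu) / sigma, NA_real_)
    data.frame(k = seq_len(K), c = cv, mu = mu, sigma = sigma, z = z,
               defined = sigma > 0)
}

#' Observed analysis plus its null calibration in one pass
#'
#' Runs the single-marker scan, gate, forward selection and the
#' label-shuffled null ensemble for one phenotype category, sharing the
#' (large) marker pair-distance vectors across the observed analysis and
#' all R null shuffles.
#'
#' @inheritParams nullEnsemble
#' @param plateauTol plateau tolerance for the stored peak.
#' @param metric genotype distance metric (\code{"manhattan"} or
#'   \code{"ibs"}).
#' @param observed if FALSE, skip the observed analysis (internal use).
#' @return list with elements \code{scan} (data.frame), \code{curve}
#'   (\linkS4class{SelectionCurve} or NULL when nothing passes the gate),
#'   \code{ensemble} (\linkS4class{NullCurveEnsemble}), and \code{z}
#'   (data.frame from \code{\link{zCurve}}).
#' @examples
#' st <- simulateStudy(nSamples = 60, nMarkers = 150, nCausal = 3,
#'                     heritability = 0.6, seed = 1)
#' g <- filterMarkersByMAF(st$genotypes)
#' res <- calibratedAnalysis(g, st$phenotypes, "context_avgmot",
#'                           B = 199, R = 5, seed = 2)
#' head(res$scan, 3)
#' if (!is.null(res$curve)) peakValue(res$curve)
#' @export
calibratedAnalysis <- function(g, pheno, category, B = 199, R = 25,
                               pGate = 0.01, maxK = NULL, plateauTol = 0.02,
                               standardize = TRUE,
                               metric = c("manhattan", "ibs"),
                               seed = NULL, observed = TRUE) {
    metric <- match.arg(metric)
    stopifnot(is(g, "GenotypeExperiment"), is(pheno, "PhenotypeTable"))
    ids <- sampleIds(g)
    phenoD <- phenotypeDistance(pheno, category, standardize = standardize,
                                samples = ids)
    n <- length(ids)
    idx <- .pairIndices(n)
    lookup <- .pairLookup(n)
    X <- .markerPairVectors(g, idx, metric)
    xStats <- .colStats(X)
    y <- .lowerTri(phenoD)
    if (is.null(maxK)) maxK <- min(ncol(X), 1000L)
    .setSeed(seed)

    out <- list(scan = NULL, curve = NULL, ensemble = NULL, z = NULL)
    if (observed) {
        res <- .scanAgainst(X, y, n, B, lookup = lookup, idx = idx,
                            xStats = xStats)
        map <- markerMap(g)
        map <- map[match(colnames(X), map$marker), , drop = FALSE]
        scan <- data.frame(marker = map$marker, chrom = map$chrom,
                           bp = map$bp, r = res$r, p = res$p)
        ord <- order(-scan$r, scan$p, seq_len(nrow(scan)))
        scan <- scan[ord, , drop = FALSE]
        scan$rank <- seq_len(nrow(scan))
        rownames(scan) <- NULL
        out$scan <- structure(scan, B = B, seed = seed,
                              alternative = "greater")
        elig <- eligibleMarkers(scan, pGate)
        if (length(elig)) {
            elig <- elig[seq_len(min(length(elig), maxK))]
            stat <- .cumulativeCorSeq(X[, elig, drop = FALSE], y)
            out$curve <- new("SelectionCurve", markers = elig, stat = stat,
                             pGate = pGate, plateauTol = plateauTol,
                             peakK = .plateauEntry(stat, plateauTol))
        }
    }
    curves <- matrix(0, R, maxK)
    for (s in seq_len(R)) {
        repeat {
            perm <- sample.int(n)
            if (!all(perm == seq_len(n))) break
        }
        ys <- y[lookup[perm[idx$i] + n * (perm[idx$j] - 1L)]]
        curves[s, ] <- .padCurve(
            .gatedCurve(X, ys, n, B, pGate, maxK, lookup, idx, xStats),
            maxK)
    }
    mu <- colMeans(curves)
    sigma <- apply(curves, 2L, stats::sd)
    out$ensemble <- new("NullCurveEnsemble", curves = curves, mu = mu,
                        sigma = sigma,
                        seed = if (is.null(seed)) NA_real_ else seed,
                        params = list(B = B, R = R, pGate = pGate,
                                      maxK = maxK,
                                      standardize = standardize))
    if (observed && !is.null(out$curve)) {
        out$z <- zCurve(out$curve, out$ensemble)
    }
    out
}
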