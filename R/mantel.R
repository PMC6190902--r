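# Mantel correlation between distance matrices, its permutation test, and
# the single-marker genome scan.
#
# Permutation strategy: a scan draws ONE pool of B sample-label
# permutations shared by every marker, so all B x M permuted statistics
# come from a single dense cross-product. Because the samples are
# exchangeable under the null, the B + 1 statistics of any one marker are
# exchangeable regardless of the shared pool, so each marker's add-one
# p-value is marginally exact, and the scan is independent of marker
# execution order by construction.

.checkDistPair <- function(d1, d2) {
    stopifnot(is.matrix(d1), is.matrix(d2),
              nrow(d1) == ncol(d1), nrow(d2) == ncol(d2))
    if (!identical(dim(d1), dim(d2))) {
        stop("distance matrices have different sizes")
    }
    if (nrow(d1) < 3L) stop("at least 3 samples are required")
    if (!is.null(rownames(d1)) && !is.null(rownames(d2)) &&
        !identical(rownames(d1), rownames(d2))) {
        stop("distance matrices have different sample ids or ordering")
    }
    invisible(NULL)
}

#' Mantel statistic of two distance matrices
#'
#' Pearson correlation over the N(N-1)/2 off-diagonal pairs of two
#' symmetric distance matrices with identical sample ordering. Symmetric
#' in its arguments and invariant to affine rescaling of either matrix's
#' off-diagonal entries.
#'
#' @param d1,d2 symmetric numeric matrices with matching sample ids.
#' @return the correlation r in [-1, 1].
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(12), 4); d <- as.matrix(dist(x))
#' mantelStatistic(d, 2 * d + 3 - diag(3, 4))  # affine: still 1
#' @export
mantelStatistic <- function(d1, d2) {
    .checkDistPair(d1, d2)
    v1 <- .lowerTri(d1)
    v2 <- .lowerTri(d2)
    if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
        stop("constant off-diagonal entries; Mantel statistic undefined")
    }
    stats::cor(v1, v2)
}

#' Add-one permutation p-value
#'
#' \code{(b + 1) / (B + 1)} with \code{b} exceedances among \code{B}
#' permutations; never zero, and with B = 1000 and no exceedances equals
#' 1/1001, i.e. just under 0.001.
#' @param b number of permuted statistics at least as extreme as observed.
#' @param B number of permutations.
#' @return the p-value.
#' @export
permPValue <- function(b, B) {
    stopifnot(all(b >= 0), all(b <= B), B >= 1)
    (b + 1) / (B + 1)
}

# Reindex a canonical pair vector under B random sample relabelings.
# Returns pairs x (B + extra) matrix whose first `extra` columns are left
# zero for the caller to fill; every permuted column is an
# entry-permutation of y. Linear indexing into the lookup matrix avoids
# per-permutation index-matrix allocations.
.permutedPairMatrix <- function(y, n, B, lookup = .pairLookup(n),
                                idx = .pairIndices(n), extra = 0L) {
    Y <- matrix(0, length(y), B + extra)
    for (b in seq_len(B)) {
        p <- sample.int(n)
        Y[, extra + b] <- y[lookup[p[idx$i] + n * (p[idx$j] - 1L)]]
    }
    Y
}

# Column sums and centred sums of squares of the marker pair vectors;
# computed once per analysis because X is shared across many scans.
.colStats <- function(X) {
    sx <- colSums(X)
    vx <- colSums(X * X) - sx * sx / nrow(X)
    list(sx = sx, vx = vx)
}

# Correlations of every column of X (pair vectors) with every column of Y.
# All Y columns are entry-permutations of one vector, so share mean/ssq.
.pairCorMatrix <- function(X, Y, xStats = NULL) {
    np <- nrow(X)
    if (is.null(xStats)) xStats <- .colStats(X)
    sx <- xStats$sx
    vx <- xStats$vx
    sy <- sum(Y[, 1L])
    vy <- sum(Y[, 1L]^2) - sy * sy / np
    if (vy <= 0) stop("constant phenotype distance vector")
    CP <- crossprod(X, Y)
    # both corrections recycle down columns: one entry per X column
    r <- (CP - sx * (sy / np)) / (sqrt(vx) * sqrt(vy))
    r[vx <= 0, ] <- NA_real_
    r
}

#' Mantel permutation test
#'
#' Permutes the sample labels of \code{d2} (joint row and column
#' permutation) \code{B} times and reports the add-one p-value
#' \code{(b + 1)/(B + 1)}, one-sided by default (large positive r =
#' genotype similarity predicts phenotype similarity).
#'
#' @param d1,d2 symmetric distance matrices with matching sample order.
#' @param B number of permutations (>= 1).
#' @param seed integer seed; the same seed reproduces b and p exactly.
#' @param alternative \code{"greater"} (default) or \code{"two.sided"}
#'   (exceedance counted on |r|).
#' @return an object of class \code{"htest"} with the statistic r, the
#'   permutation count B, exceedances b, and the p-value.
#' @export
mantelTest <- function(d1, d2, B = 999, seed = NULL,
                       alternative = c("greater", "two.sided")) {
    alternative <- match.arg(alternative)
    B <- .assertCount(B, "B")
    .checkDistPair(d1, d2)
    n <- nrow(d1)
    x <- .lowerTri(d1)
    y <- .lowerTri(d2)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        stop("constant off-diagonal entries; Mantel statistic undefined")
    }
    .setSeed(seed)
    rObs <- stats::cor(x, y)
    Y <- .permutedPairMatrix(y, n, B)
    rPerm <- as.vector(.pairCorMatrix(matrix(x, ncol = 1L), Y))
    # ties (e.g. a drawn identity permutation) count as exceedances; the
    # tolerance absorbs float noise between computation paths
    b <- if (alternative == "greater") sum(rPerm >= rObs - 1e-12) else
        sum(abs(rPerm) >= abs(rObs) - 1e-12)
    structure(list(
        statistic = c(r = rObs),
        parameter = c(B = B),
        p.value = permPValue(b, B),
        estimate = c(exceedances = b),
        alternative = alternative,
        method = "Mantel permutation test (add-one estimator)",
        data.name = "distance matrix pair",
        seed = seed),
        class = "htest")
}

# Build the pairs x markers single-marker distance vectors (Manhattan
# dosage differences, or IBS mismatch indicators), dropping zero-variance
# (monomorphic) markers with a message.
.markerPairVectors <- function(g, idx, metric = "manhattan") {
    d <- dosages(g)
    if (anyNA(d)) stop("missing dosages; impute before scanning")
    v <- apply(d, 2L, stats::var)
    mono <- v == 0
    if (all(mono)) stop("no polymorphic markers to scan")
    if (any(mono)) {
        message("skipping ", sum(mono), " monomorphic marker(s)")
        d <- d[, !mono, drop = FALSE]
    }
    X <- if (metric == "ibs") {
        (d[idx$i, , drop = FALSE] != d[idx$j, , drop = FALSE]) + 0
    } else {
        abs(d[idx$i, , drop = FALSE] - d[idx$j, , drop = FALSE])
    }
    # double storage up front: the scan feeds X to BLAS many times, and an
    # integer matrix would be re-coerced (and re-allocated) on every call
    storage.mode(X) <- "double"
    rownames(X) <- NULL
    X
}

#' Single-marker Mantel genome scan
#'
#' For every polymorphic marker, correlates the single-marker Manhattan
#' dosage distance matrix with the phenotype distance matrix and derives a
#' permutation p-value. One pool of \code{B} sample-label permutations is
#' shared across markers, making the scan a single dense cross-product;
#' each marker's add-one p-value remains marginally exact (see package
#' vignette). Results are ranked by r descending, then p ascending, then
#' marker map order.
#'
#' @param g a \linkS4class{GenotypeExperiment} (filter by MAF first).
#' @param phenoD phenotype distance matrix from
#'   \code{\link{phenotypeDistance}} covering the same samples.
#' @param B permutations per marker (default 999).
#' @param seed integer seed.
#' @param alternative as in \code{\link{mantelTest}}.
#' @param metric genotype distance metric, \code{"manhattan"} (default)
#'   or \code{"ibs"}.
#' @return data.frame with columns marker, chrom, bp, r, p, rank (rows in
#'   rank order); attributes \code{B}, \code{seed}, \code{alternative}.
#' @export
singleMarkerScan <- function(g, phenoD, B = 999, seed = NULL,
                             alternative = c("greater", "two.sided"),
                             metric = c("manhattan", "ibs")) {
    metric <- match.arg(metric)
    alternative <- match.arg(alternative)
    B <- .assertCount(B, "B")
    stopifnot(is(g, "GenotypeExperiment"), is.matrix(phenoD))
    ids <- sampleIds(g)
    if (!setequal(rownames(phenoD), ids)) {
        stop("genotype and phenotype distance cover different samples")
    }
    phenoD <- phenoD[ids, ids]
    n <- length(ids)
    if (n < 3L) stop("at least 3 samples are required")
    idx <- .pairIndices(n)
    X <- .markerPairVectors(g, idx, metric)
    y <- .lowerTri(phenoD)
    .setSeed(seed)
    res <- .scanAgainst(X, y, n, B, alternative, idx = idx)
    map <- markerMap(g)
    map <- map[match(colnames(X), map$marker), , drop = FALSE]
    out <- data.frame(marker = map$marker, chrom = map$chrom, bp = map$bp,
                      r = res$r, p = res$p, row.names = NULL)
    ord <- order(-out$r, out$p, match(out$marker, markerIds(g)))
    out <- out[ord, , drop = FALSE]
    out$rank <- seq_len(nrow(out))
    rownames(out) <- NULL
    structure(out, B = B, seed = seed, alternative = alternative)
}

# Scan core shared with the null-calibration module: X fixed pair vectors,
# y one phenotype pair vector; draws B permutations from the current RNG
# state. Returns observed r and add-one p per column of X.
.scanAgainst <- function(X, y, n, B, alternative = "greater",
                         lookup = .pairLookup(n), idx = .pairIndices(n),
                         xStats = NULL) {
    if (stats::sd(y) == 0) stop("constant phenotype distance vector")
    Y <- .permutedPairMatrix(y, n, B, lookup, idx, extra = 1L)
    Y[, 1L] <- y
    r <- .pairCorMatrix(X, Y, xStats)
    rObs <- r[, 1L]
    # ties count as exceedances (see mantelTest)
    if (alternative == "greater") {
        b <- rowSums(r[, -1L, drop = FALSE] >= rObs - 1e-12)
    } else {
        b <- rowSums(abs(r[, -1L, drop = FALSE]) >= abs(rObs) - 1e-12)
    }
    list(r = rObs, b = b, p = permPValue(b, B))
}
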