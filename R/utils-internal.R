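# Internal helpers shared by the distance engine, the scan and the
# calibration code. All pairwise quantities use one canonical ordering of
# the N(N-1)/2 unordered sample pairs: column-major lower triangle,
# matching as.vector(stats::dist(x)).

# i/j sample indices for the canonical pair ordering
.pairIndices <- function(n) {
    stopifnot(n >= 2L)
    j <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
    i <- sequence((n - 1L):1L) + j
    list(i = i, j = j, n = n)
}

# position of pair (i,j) in the canonical vector, as a full symmetric
# lookup matrix (diagonal unused); used to reindex a distance vector under
# a relabelling of the samples
.pairLookup <- function(n) {
    idx <- .pairIndices(n)
    m <- matrix(NA_integer_, n, n)
    pos <- seq_along(idx$i)
    m[cbind(idx$i, idx$j)] <- pos
    m[cbind(idx$j, idx$i)] <- pos
    m
}

# lower-triangle vector of a square symmetric matrix, canonical order
.lowerTri <- function(m) {
    m[lower.tri(m)]
}

# square symmetric matrix from a canonical pair vector
.squareFromPairs <- function(v, ids) {
    n <- length(ids)
    m <- matrix(0, n, n, dimnames = list(ids, ids))
    m[lower.tri(m)] <- v
    m <- m + t(m)
    m
}

# Pearson correlation of a fixed vector y with each column of X, using the
# cross-product identity so the same code path serves one column or
# thousands (columns are marker distance vectors, y a phenotype distance
# vector). Returns a vector of correlations; zero-variance columns give NA.
.corWithColumns <- function(X, y) {
    n <- length(y)
    sy <- sum(y)
    vy <- sum(y * y) - sy * sy / n
    if (vy <= 0) {
        stop("phenotype distance vector is constant; Mantel statistic undefined")
    }
    sx <- colSums(X)
    vx <- colSums(X * X) - sx * sx / n
    cp <- as.vector(crossprod(X, y)) - sx * sy / n
    r <- cp / sqrt(vx * vy)
    r[vx <= 0] <- NA_real_
    r
}

# deterministic child seeds below 2^31, derived from a master seed
.childSeeds <- function(seed, k) {
    stopifnot(is.numeric(seed), length(seed) == 1L)
    s <- as.double(seed %% 2147483647)
    out <- numeric(k)
    for (i in seq_len(k)) {
        s <- (s * 48271) %% 2147483647
        out[i] <- s
    }
    as.integer(out)
}

.setSeed <- function(seed) {
    if (!is.null(seed)) set.seed(as.integer(seed %% 2147483647))
    invisible(NULL)
}

# shared argument checks
.assertFraction <- function(x, name, lo = 0, hi = 1, lo.open = FALSE,
                            hi.open = FALSE) {
    ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
        (if (lo.open) x > lo else x >= lo) &&
        (if (hi.open) x < hi else x <= hi)
    if (!ok) {
        stop(sprintf("'%s' must be a single number in %s%g, %g%s",
                     name, if (lo.open) "(" else "[", lo, hi,
                     if (hi.open) ")" else "]"), call. = FALSE)
    }
    invisible(x)
}

.assertCount <- function(x, name, min = 1L) {
    ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
        x >= min && x == floor(x)
    if (!ok) {
        stop(sprintf("'%s' must be a single integer >= %d", name, min),
             call. = FALSE)
    }
    invisible(as.integer(x))
}
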