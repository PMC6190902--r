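# Small in-code fixtures shared across test files.

# hand-written genotype object: n samples x m markers with given dosages
toyGenotypes <- function(dosage, chrom = NULL, bp = NULL) {
    n <- nrow(dosage)
    m <- ncol(dosage)
    if (is.null(rownames(dosage))) {
        rownames(dosage) <- paste0("s", seq_len(n))
    }
    if (is.null(colnames(dosage))) {
        colnames(dosage) <- paste0("m", seq_len(m))
    }
    map <- data.frame(marker = colnames(dosage),
                      chrom = if (is.null(chrom)) rep("chr1", m) else chrom,
                      bp = if (is.null(bp)) seq_len(m) * 1000L else bp)
    makeGenotypes(dosage, map)
}

# random symmetric distance matrix with zero diagonal
randomDistMatrix <- function(n, ids = paste0("s", seq_len(n))) {
    x <- matrix(rnorm(n * 3), n)
    rownames(x) <- ids
    as.matrix(dist(x))
}

# brute-force Pearson over the off-diagonal pairs of two square matrices
bruteMantel <- function(d1, d2) {
    n <- nrow(d1)
    v1 <- c(); v2 <- c()
    for (i in seq_len(n)) {
        for (j in seq_len(n)) {
            if (i < j) {
                v1 <- c(v1, d1[i, j])
                v2 <- c(v2, d2[i, j])
            }
        }
    }
    cor(v1, v2)
}

# small simulated study used by several files (kept tiny for speed)
smallStudy <- function(seed = 11, n = 60, m = 120, ...) {
    simulateStudy(nSamples = n, nMarkers = m, nCausal = 3,
                  heritability = 0.5, seed = seed, ...)
}
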