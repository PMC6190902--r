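# Mantel statistic, permutation test, and the single-marker scan.

test_that("Mantel statistic: identity, affine invariance, symmetry", {
    set.seed(301)
    d <- randomDistMatrix(6)
    expect_equal(mantelStatistic(d, d), 1)
    dAff <- 2 * d + 3
    diag(dAff) <- 0
    expect_equal(mantelStatistic(d, dAff), 1)
    d2 <- randomDistMatrix(6)
    expect_equal(mantelStatistic(d, d2), mantelStatistic(d2, d))
})

test_that("Mantel statistic equals brute-force Pearson over pairs", {
    set.seed(302)
    for (n in c(4, 6, 8)) {
        d1 <- randomDistMatrix(n)
        d2 <- randomDistMatrix(n)
        expect_equal(mantelStatistic(d1, d2), bruteMantel(d1, d2),
                     tolerance = 1e-12)
    }
})

test_that("Mantel statistic agrees with vegan's implementation", {
    skip_if_not_installed("vegan")
    set.seed(303)
    d1 <- randomDistMatrix(10)
    d2 <- randomDistMatrix(10)
    ref <- vegan::mantel(as.dist(d1), as.dist(d2), permutations = 0)
    expect_equal(mantelStatistic(d1, d2), unname(ref$statistic),
                 tolerance = 1e-12)
})

test_that("degenerate (constant) distance matrices are an error", {
    d0 <- matrix(1, 4, 4) - diag(4)
    dimnames(d0) <- list(paste0("s", 1:4), paste0("s", 1:4))
    set.seed(304)
    d <- randomDistMatrix(4)
    expect_error(mantelStatistic(d0, d), "undefined")
    expect_error(mantelStatistic(d, d0), "undefined")
})

test_that("add-one estimator and determinism of the permutation test", {
    expect_equal(permPValue(0, 99), 0.01)
    expect_equal(permPValue(0, 1000), 1 / 1001)
    expect_error(permPValue(5, 3))

    set.seed(305)
    x <- matrix(rnorm(24), 8); rownames(x) <- paste0("s", 1:8)
    y <- x + matrix(rnorm(24, sd = 0.2), 8)
    d1 <- as.matrix(dist(x)); d2 <- as.matrix(dist(y))
    t1 <- mantelTest(d1, d2, B = 99, seed = 7)
    t2 <- mantelTest(d1, d2, B = 99, seed = 7)
    expect_identical(t1$p.value, t2$p.value)
    expect_identical(t1$estimate, t2$estimate)
    expect_equal(t1$p.value,
                 permPValue(unname(t1$estimate), 99))
    # a strong signal at B = 99 with no exceedances gives exactly 0.01
    expect_equal(mantelTest(d1, d1 + 0 * d2, B = 99, seed = 1)$p.value, 0.01)
})

test_that("Monte-Carlo permutation p matches exhaustive relabeling at N=4", {
    set.seed(306)
    d1 <- randomDistMatrix(4)
    d2 <- randomDistMatrix(4)
    rObs <- mantelStatistic(d1, d2)
    # exhaustive oracle: all 4! joint relabelings of d2
    perms <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
    perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ]
    rAll <- apply(perms, 1, function(p) {
        dp <- d2[p, p]
        dimnames(dp) <- dimnames(d2)
        mantelStatistic(d1, dp)
    })
    pExact <- mean(rAll >= rObs - 1e-12)
    mc <- mantelTest(d1, d2, B = 4999, seed = 8)
    expect_lt(abs(mc$p.value - pExact), 0.03)
})

test_that("permutation test has nominal type-I error under the null", {
    set.seed(307)
    hits <- 0L
    nrep <- 200
    for (i in seq_len(nrep)) {
        d1 <- randomDistMatrix(20)
        d2 <- randomDistMatrix(20)
        if (mantelTest(d1, d2, B = 99)$p.value <= 0.05) hits <- hits + 1L
    }
    # binomial 99.9% band around 0.05 for 200 replicates
    expect_gt(hits / nrep, 0.05 - 3.3 * sqrt(0.05 * 0.95 / nrep))
    expect_lt(hits / nrep, 0.05 + 3.3 * sqrt(0.05 * 0.95 / nrep))
})

test_that("scan finds a planted single-locus effect at the top rank", {
    top <- 0L
    for (i in 1:10) {
        st <- simulateStudy(nSamples = 120, nMarkers = 150, nCausal = 1,
                            heritability = 0.5, seed = 400 + i)
        g <- suppressMessages(filterMarkersByMAF(st$genotypes))
        pd <- phenotypeDistance(st$phenotypes, "context_avgmot")
        sc <- suppressMessages(singleMarkerScan(g, pd, B = 99,
                                                seed = 500 + i))
        cz <- st$truth$causal$sham
        map <- markerMap(g)
        topIdx <- match(sc$marker[1], map$marker)
        czIdx <- match(cz, map$marker)
        # top marker is the causal one or an immediate mosaic neighbour
        if (!is.na(czIdx) &&
            map$chrom[topIdx] == map$chrom[czIdx] &&
            abs(topIdx - czIdx) <= 20) {
            top <- top + 1L
        }
    }
    expect_gte(top, 8L)
})

test_that("monomorphic markers are skipped with a log message", {
    dos <- cbind(m1 = c(0, 1, 2, 1, 0, 2), m2 = rep(1, 6),
                 m3 = c(2, 0, 1, 1, 2, 0))
    g <- toyGenotypes(dos)
    set.seed(311)
    pd <- randomDistMatrix(6)
    expect_message(sc <- singleMarkerScan(g, pd, B = 49, seed = 1),
                   "1 monomorphic")
    expect_identical(sort(sc$marker), c("m1", "m3"))

    gAllMono <- toyGenotypes(cbind(m1 = rep(1, 6), m2 = rep(0, 6)))
    expect_error(suppressMessages(singleMarkerScan(gAllMono, pd, B = 9)),
                 "no polymorphic")
})

test_that("the IBS scan ranks by mismatch-count distances", {
    st <- smallStudy(seed = 315, n = 30, m = 20)
    g <- suppressMessages(filterMarkersByMAF(st$genotypes))
    pd <- phenotypeDistance(st$phenotypes, "context_avgmot")
    sc <- suppressMessages(singleMarkerScan(g, pd, B = 49, seed = 2,
                                            metric = "ibs"))
    for (m in sc$marker[c(1, nrow(sc))]) {
        expect_equal(sc$r[sc$marker == m],
                     mantelStatistic(genotypeDistance(g, m, metric = "ibs"),
                                     pd),
                     tolerance = 1e-12)
    }
})

test_that("scan is reproducible and ranked by the declared keys", {
    st <- smallStudy(seed = 320, n = 40, m = 60)
    g <- suppressMessages(filterMarkersByMAF(st$genotypes))
    pd <- phenotypeDistance(st$phenotypes, "cued_pctfrze")
    s1 <- singleMarkerScan(g, pd, B = 99, seed = 9)
    s2 <- singleMarkerScan(g, pd, B = 99, seed = 9)
    expect_identical(s1, s2)
    expect_identical(s1$rank, seq_len(nrow(s1)))
    expect_true(all(diff(s1$r) <= 1e-15))
    # scan r equals the directly computed Mantel statistic per marker
    for (m in s1$marker[c(1, 10, nrow(s1))]) {
        expect_equal(s1$r[s1$marker == m],
                     mantelStatistic(genotypeDistance(g, m), pd),
                     tolerance = 1e-12)
    }
})
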