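# The heterogeneous-stock simulator: founder panels, mosaic genomes,
# correlated condition-dependent phenotypes.

test_that("founder panel simulation is deterministic and respects ranges", {
    p1 <- simulateFounderPanel(8, 200, seed = 1)
    p2 <- simulateFounderPanel(8, 200, seed = 1)
    expect_identical(founderHaplotypes(p1), founderHaplotypes(p2))
    expect_identical(markerMap(p1), markerMap(p2))
    expect_identical(targetMaf(p1), targetMaf(p2))

    # achievable frequencies are k/8 with k in 1..7 (folded to <= 0.5)
    expect_true(all(targetMaf(p1) >= 1 / 8))
    expect_true(all(targetMaf(p1) <= 0.5))
    expect_true(all(targetMaf(p1) * 8 == round(targetMaf(p1) * 8)))

    # positions strictly increasing within each chromosome
    map <- markerMap(p1)
    expect_true(all(vapply(split(map$bp, map$chrom),
                           function(x) all(diff(x) > 0), logical(1))))

    expect_error(simulateFounderPanel(8, 100, mafLow = 0),
                 "mafLow")
    expect_error(simulateFounderPanel(8, 100, mafLow = 0.3, mafHigh = 0.2),
                 "mafHigh")
})

test_that("single-founder panel is monomorphic everywhere", {
    p <- simulateFounderPanel(1, 50, seed = 3)
    expect_true(all(founderHaplotypes(p) == 0))
    g <- simulateHSGenomes(p, 10, seed = 4)
    d <- genotypeDistance(g)
    expect_true(all(d == 0))
})

test_that("population MAF of mosaic genomes tracks the panel target", {
    p <- simulateFounderPanel(8, 2000, mafLow = 0.05, mafHigh = 0.5, seed = 5)
    g <- simulateHSGenomes(p, 500, seed = 6)
    maf <- markerMAF(g)
    dev <- abs(maf - targetMaf(p))
    # binomial sampling error at 1000 chromosomes: nearly all markers within
    # +/- 0.05 of the panel frequency, none grossly off
    expect_gt(mean(dev <= 0.05), 0.99)
    expect_lt(max(dev), 0.09)
})

test_that("per-marker sample MAF equals allele count over 2N exactly", {
    st <- smallStudy(seed = 21)
    d <- dosages(st$genotypes)
    expect_equal(unname(markerMAF(st$genotypes)),
                 unname(pmin(colSums(d), 2 * nrow(d) - colSums(d)) /
                            (2 * nrow(d))))
})

test_that("mosaic genomes are deterministic and block length controls linkage", {
    p <- simulateFounderPanel(8, 300, seed = 7)
    g1 <- simulateHSGenomes(p, 80, meanBlockMarkers = 10, seed = 8)
    g2 <- simulateHSGenomes(p, 80, meanBlockMarkers = 10, seed = 8)
    expect_identical(dosages(g1), dosages(g2))
    expect_true(all(dosages(g1) %in% 0:2))

    # adjacent-marker linkage (unsigned correlation) decays with shorter
    # blocks: founder mosaics only correlate markers while unbroken
    adjCor <- function(g) {
        d <- dosages(g)
        mean(abs(diag(cor(d[, -ncol(d)], d[, -1]))), na.rm = TRUE)
    }
    gShort <- simulateHSGenomes(p, 200, meanBlockMarkers = 1, seed = 9)
    gLong <- simulateHSGenomes(p, 200, meanBlockMarkers = 1e6, seed = 9)
    expect_gt(adjCor(gLong), adjCor(gShort))
})

test_that("phenotypes have the requested correlation structure", {
    st <- simulateStudy(nSamples = 400, nMarkers = 300, nCausal = 5,
                        heritability = 0.3, withinCor = 0.7, seed = 31)
    v <- measureValues(st$phenotypes)
    cm <- categoryMap(st$phenotypes)
    cc <- cor(v)
    within <- c(); between <- c()
    for (i in seq_len(ncol(v))) {
        for (j in seq_len(ncol(v))) {
            if (i < j) {
                if (cm[colnames(v)[i]] == cm[colnames(v)[j]]) {
                    within <- c(within, cc[i, j])
                } else {
                    between <- c(between, cc[i, j])
                }
            }
        }
    }
    # realised within-category correlations in the moderate-to-high band,
    # between-category clearly lower
    expect_gt(mean(within), 0.5)
    expect_lt(mean(within), 0.9)
    expect_true(all(between < 0.6))
    expect_lt(mean(between), mean(within))
})

test_that("zero heritability gives a null genotype-phenotype link", {
    st <- simulateStudy(nSamples = 200, nMarkers = 100, nCausal = 5,
                        heritability = 0, seed = 41)
    g <- st$genotypes
    pd <- phenotypeDistance(st$phenotypes, "context_avgmot")
    gd <- genotypeDistance(g)
    expect_lt(abs(mantelStatistic(gd, pd)), 0.05)
})

test_that("full heritability with one causal marker is affine in dosage", {
    p <- simulateFounderPanel(8, 10, seed = 51)
    g <- simulateHSGenomes(p, 50, seed = 52)
    mk <- markerIds(g)[which(markerMAF(g) > 0.2)[1]]
    arch <- hsArchitecture(
        effects = list(all = data.frame(marker = mk, effect = 2)),
        heritability = 1,
        categories = "context_avgmot", measuresPerCategory = 1)
    conds <- data.frame(sample = sampleIds(g), condition = "all")
    sim <- simulatePhenotypes(g, arch, conds, seed = 53)
    x <- measureValues(sim$phenotypes)[, 1]
    dos <- dosages(g)[, mk]
    fit <- lm(x ~ dos)
    expect_equal(unname(residuals(fit)), rep(0, 50), tolerance = 1e-10)
})

test_that("phenotype simulation validates its inputs", {
    st <- smallStudy(seed = 61)
    conds <- st$conditions
    conds$condition[1] <- "unknown_arm"
    expect_error(simulatePhenotypes(st$genotypes, st$architecture, conds),
                 "unknown_arm")
    arch <- hsArchitecture(
        effects = list(sham = data.frame(marker = "nope", effect = 1),
                       irradiated = data.frame(marker = "nope", effect = 1)))
    expect_error(simulatePhenotypes(st$genotypes, arch, st$conditions),
                 "absent")
})

test_that("study simulation is reproducible and overlap knob is honoured", {
    s1 <- simulateStudy(nSamples = 40, nMarkers = 100, nCausal = 4,
                        architectureOverlap = 0.5, seed = 71)
    s2 <- simulateStudy(nSamples = 40, nMarkers = 100, nCausal = 4,
                        architectureOverlap = 0.5, seed = 71)
    expect_identical(dosages(s1$genotypes), dosages(s2$genotypes))
    expect_identical(measureValues(s1$phenotypes),
                     measureValues(s2$phenotypes))
    shared <- intersect(s1$truth$causal$sham, s1$truth$causal$irradiated)
    expect_length(shared, 2L)
    s3 <- simulateStudy(nSamples = 40, nMarkers = 100, nCausal = 4,
                        architectureOverlap = 0, seed = 71)
    expect_length(intersect(s3$truth$causal$sham,
                            s3$truth$causal$irradiated), 0L)
    s4 <- simulateStudy(nSamples = 40, nMarkers = 100, nCausal = 4,
                        architectureOverlap = 1, seed = 71)
    expect_identical(sort(s4$truth$causal$sham),
                     sort(s4$truth$causal$irradiated))
})
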