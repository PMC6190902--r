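# Marker-set overlap: 2x2 tables, Fisher exact test, stratified comparison.

test_that("overlap tables cross-tabulate membership exactly", {
    u <- paste0("m", 1:100)
    t1 <- overlapTable(u[1:10], u[1:10], u)
    expect_equal(as.vector(t1), c(10, 0, 0, 90))
    t2 <- overlapTable(u[1:40], u[41:100], u)   # disjoint, covering
    expect_equal(t2[1, 1], 0)
    expect_equal(t2[2, 2], 0)
    # hand-enumerated toy
    t3 <- overlapTable(c("m1", "m2", "m3"), c("m2", "m3", "m4"), u[1:6])
    expect_equal(as.vector(t3), c(2, 1, 1, 2))
    expect_error(overlapTable("zz", "m1", u), "outside the universe")
})

test_that("odds ratio, correction and symmetry behave as defined", {
    fo <- fisherOverlap(matrix(c(10, 5, 5, 80), 2))
    expect_equal(fo$oddsRatio, 32)   # (10*80)/(5*5), no zero cells
    expect_gt(fo$conf.int[1], 1)
    expect_lt(fo$conf.int[1], fo$oddsRatio)
    expect_gt(fo$conf.int[2], fo$oddsRatio)
    # swapping the two sets (b <-> c) leaves OR and p unchanged
    fo3 <- fisherOverlap(t(matrix(c(10, 5, 5, 80), 2)))
    expect_equal(fo3$oddsRatio, fo$oddsRatio)
    expect_equal(fo3$p.value, fo$p.value)
    # Haldane-Anscombe correction engages on zero cells
    foz <- fisherOverlap(matrix(c(0, 5, 5, 90), 2))
    expect_equal(foz$oddsRatio, (0.5 * 90.5) / (5.5 * 5.5))
    # empty set -> flagged, OR undefined
    fde <- fisherOverlap(matrix(c(0, 0, 10, 90), 2))
    expect_true(fde$flagged)
    expect_true(is.na(fde$oddsRatio))
})

test_that("Fisher p matches exhaustive hypergeometric enumeration", {
    # oracle: for fixed margins, enumerate all tables, sum probabilities
    # not exceeding the observed table's
    exhaustiveP <- function(a, b, c_, d) {
        K <- a + b; n2 <- a + c_; N <- a + b + c_ + d
        probs <- vapply(max(0, K + n2 - N):min(K, n2), function(x) {
            choose(K, x) * choose(N - K, n2 - x) / choose(N, n2)
        }, numeric(1))
        pObs <- choose(K, a) * choose(N - K, n2 - a) / choose(N, n2)
        sum(probs[probs <= pObs * (1 + 1e-7)])
    }
    set.seed(801)
    for (rep in 1:20) {
        N <- sample(8:30, 1)
        a <- sample(0:4, 1); b <- sample(0:4, 1); c_ <- sample(0:4, 1)
        d <- N - a - b - c_
        if (d < 0 || (a + b) == 0 || (a + c_) == 0) next
        fo <- fisherOverlap(matrix(c(a, b, c_, d), 2, byrow = FALSE))
        expect_equal(fo$p.value, exhaustiveP(a, b, c_, d),
                     tolerance = 1e-7)
    }
    # identical 10-of-100 sets: overwhelming overlap
    fid <- fisherOverlap(overlapTable(paste0("m", 1:10), paste0("m", 1:10),
                                      paste0("m", 1:100)))
    expect_lt(fid$p.value, 1e-10)
    expect_gt(fid$conf.int[1], 1)
})

test_that("random equal-sized sets give mean log-OR near zero", {
    set.seed(802)
    u <- paste0("m", 1:60)
    lors <- replicate(500, {
        a <- sample(u, 15); b <- sample(u, 15)
        log(fisherOverlap(overlapTable(a, b, u))$oddsRatio)
    })
    expect_lt(abs(mean(lors)), 3 * sd(lors) / sqrt(length(lors)) + 0.05)
})

test_that("stratified comparison enforces the sample-size floor", {
    st <- smallStudy(seed = 811, n = 40, m = 50)
    expect_error(
        compareConditions(st$genotypes, st$phenotypes, st$conditions,
                          split = "condition", categories = "context_avgmot",
                          B = 9, minStratum = 30),
        "floor")
})

test_that("shared architectures overlap; shifted ones do not", {
    orShared <- c(); orDisjoint <- c()
    for (i in 1:4) {
        stS <- simulateStudy(nSamples = 240, nMarkers = 200, nCausal = 5,
                             heritability = 0.6, architectureOverlap = 1,
                             seed = 820 + i)
        res <- suppressMessages(compareConditions(
            stS$genotypes, stS$phenotypes, stS$conditions,
            split = "condition", categories = "context_avgmot",
            B = 199, seed = 830 + i))
        orShared <- c(orShared, res$ciLow)
        stD <- simulateStudy(nSamples = 240, nMarkers = 200, nCausal = 5,
                             heritability = 0.6, architectureOverlap = 0,
                             seed = 820 + i)
        resD <- suppressMessages(compareConditions(
            stD$genotypes, stD$phenotypes, stD$conditions,
            split = "condition", categories = "context_avgmot",
            B = 199, seed = 830 + i))
        orDisjoint <- c(orDisjoint,
                        ifelse(is.na(resD$oddsRatio), 0, resD$ciLow))
    }
    expect_gte(sum(orShared > 1, na.rm = TRUE), 3L)
    expect_gte(sum(orDisjoint <= 1), 3L)
})

test_that("architecture overlap knob moves the observed odds ratio", {
    set.seed(841)
    grid <- c(0, 0.5, 1)
    med <- vapply(grid, function(ov) {
        ors <- vapply(1:3, function(i) {
            st <- simulateStudy(nSamples = 140, nMarkers = 150, nCausal = 4,
                                heritability = 0.6,
                                architectureOverlap = ov, seed = 850 + i)
            res <- suppressMessages(compareConditions(
                st$genotypes, st$phenotypes, st$conditions,
                split = "condition", categories = "context_avgmot",
                B = 199, seed = 860 + i))
            or <- res$oddsRatio
            if (is.na(or)) 0 else or
        }, numeric(1))
        median(ors)
    }, numeric(1))
    expect_gt(cor(grid, med, method = "spearman"), 0)
})
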