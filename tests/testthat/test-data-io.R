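# Readers, writers and the MAF filter.

test_that("genotype files round-trip losslessly", {
    st <- smallStudy(seed = 101, n = 12, m = 8)
    gp <- withr::local_tempfile(fileext = ".tsv")
    mp <- withr::local_tempfile(fileext = ".tsv")
    writeGenotypes(st$genotypes, gp, mp)
    g2 <- readGenotypes(gp, mp)
    expect_identical(dosages(g2), dosages(st$genotypes))
    expect_identical(markerMap(g2), markerMap(st$genotypes))
})

test_that("a hand-written genotype file parses to exact values", {
    gp <- withr::local_tempfile(fileext = ".tsv")
    mp <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("sample\tmA\tmB\tmC",
                 "s1\t0\t1\t2",
                 "s2\t2\t1\t0"), gp)
    writeLines(c("marker\tchrom\tbp\tref\talt",
                 "mA\tchr1\t100\tA\tB",
                 "mB\tchr1\t200\tA\tB",
                 "mC\tchr2\t100\tA\tB"), mp)
    g <- readGenotypes(gp, mp)
    expect_identical(dim(dosages(g)), c(2L, 3L))
    expect_identical(unname(dosages(g)["s2", ]), c(2, 1, 0))
})

test_that("invalid dosages are rejected naming marker and sample", {
    gp <- withr::local_tempfile(fileext = ".tsv")
    mp <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("sample\tmA\tmB", "s1\t0\t3", "s2\t1\t1"), gp)
    writeLines(c("marker\tchrom\tbp", "mA\tchr1\t100", "mB\tchr1\t200"), mp)
    expect_error(readGenotypes(gp, mp), "s1.*mB|mB.*s1")
})

test_that("missing dosages follow the configured policy", {
    gp <- withr::local_tempfile(fileext = ".tsv")
    mp <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("sample\tmA\tmB", "s1\t0\tNA", "s2\t2\t1", "s3\t2\t1"), gp)
    writeLines(c("marker\tchrom\tbp", "mA\tchr1\t100", "mB\tchr1\t200"), mp)
    expect_error(readGenotypes(gp, mp), "missing")
    expect_message(g <- readGenotypes(gp, mp, missing = "impute"),
                   "mean-imputed 1")
    expect_equal(dosages(g)["s1", "mB"], 1)
})

test_that("markers in the matrix but not the map are rejected", {
    gp <- withr::local_tempfile(fileext = ".tsv")
    mp <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("sample\tmA\tmB", "s1\t0\t1", "s2\t1\t1"), gp)
    writeLines(c("marker\tchrom\tbp", "mA\tchr1\t100"), mp)
    expect_error(readGenotypes(gp, mp), "absent from map")
})

test_that("MAF filter is strict at the threshold", {
    # 10 samples; marker at exactly MAF 0.05 (1 alt allele in 20) must go
    dos <- cbind(m1 = c(1, rep(0, 9)),     # MAF exactly 0.05
                 m2 = c(1, 1, rep(0, 8)),  # MAF 0.10
                 m3 = rep(1, 10))          # all heterozygous, MAF 0.5
    g <- toyGenotypes(dos)
    expect_message(f <- filterMarkersByMAF(g, 0.05), "1 of 3")
    expect_identical(markerIds(f), c("m2", "m3"))
})

test_that("surviving marker count matches brute-force allele counting", {
    set.seed(77)
    dos <- matrix(sample(0:2, 10 * 10, replace = TRUE,
                         prob = c(.7, .2, .1)), 10)
    colnames(dos) <- paste0("m", 1:10)
    g <- toyGenotypes(dos)
    # brute force: count alleles per marker by explicit loop
    keep <- logical(10)
    for (m in seq_len(10)) {
        alt <- 0
        for (s in seq_len(10)) alt <- alt + dos[s, m]
        p <- alt / 20
        keep[m] <- min(p, 1 - p) > 0.1
    }
    f <- suppressMessages(filterMarkersByMAF(g, 0.1))
    expect_identical(length(markerIds(f)), sum(keep))
    expect_identical(markerIds(f), colnames(dos)[keep])
})

test_that("phenotype and condition files round-trip", {
    st <- smallStudy(seed = 103, n = 10, m = 6)
    pp <- withr::local_tempfile(fileext = ".csv")
    cp <- withr::local_tempfile(fileext = ".csv")
    writePhenotypes(st$phenotypes, pp, cp)
    p2 <- readPhenotypes(pp, cp)
    expect_equal(measureValues(p2), measureValues(st$phenotypes),
                 tolerance = 1e-12)
    expect_identical(categoryMap(p2), categoryMap(st$phenotypes))

    xp <- withr::local_tempfile(fileext = ".csv")
    writeConditions(st$conditions, xp)
    expect_identical(readConditions(xp), st$conditions)
})

test_that("unmapped measures are a format error", {
    pp <- withr::local_tempfile(fileext = ".csv")
    cp <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("sample,meas1,meas2", "s1,0.5,1.2", "s2,0.7,0.9"), pp)
    writeLines(c("measure,category", "meas1,catA"), cp)
    expect_error(readPhenotypes(pp, cp), "meas2")
})

test_that("gene annotation rejects start > end and round-trips", {
    ap <- withr::local_tempfile(fileext = ".tsv")
    ann <- data.frame(gene = c("g1", "g2"), chrom = "chr1",
                      start = c(100L, 500L), end = c(300L, 900L))
    writeGeneAnnotation(ann, ap)
    expect_identical(readGeneAnnotation(ap), ann)

    writeLines(c("chrom\tstart\tend\tgene",
                 "chr1\t100\t300\tg1",
                 "chr1\t900\t500\tg2"), ap)
    expect_error(readGeneAnnotation(ap), "start > end")
})

test_that("GMT parsing enforces the three-field minimum", {
    gp <- withr::local_tempfile(fileext = ".gmt")
    writeLines(c("setA\tdesc\tg1\tg2", "setB\tdesc\tg3"), gp)
    sets <- readGmt(gp)
    expect_identical(sets$setA, c("g1", "g2"))
    expect_identical(sets$setB, "g3")

    writeGmt(sets, gp)
    expect_identical(readGmt(gp)$setA, c("g1", "g2"))

    writeLines(c("setA\tdesc\tg1", "lonelyname"), gp)
    expect_error(readGmt(gp), "line 2")
})

test_that("ground truth manifest round-trips through YAML", {
    st <- smallStudy(seed = 104, n = 10, m = 6)
    tp <- withr::local_tempfile(fileext = ".yaml")
    writeGroundTruth(st$truth, tp)
    tr <- readGroundTruth(tp)
    expect_identical(sort(unlist(tr$causal$sham)),
                     sort(st$truth$causal$sham))
})

test_that("sample alignment is by id with a dropped-sample report", {
    st <- smallStudy(seed = 106, n = 12, m = 6)
    ids <- sampleIds(st$genotypes)
    phenoSub <- st$phenotypes[ids[1:10], ]
    expect_message(al <- alignSamples(st$genotypes, phenoSub,
                                      st$conditions),
                   "genotypes 2")
    expect_identical(sampleIds(al$genotypes), ids[1:10])
    expect_identical(sampleIds(al$phenotypes), ids[1:10])
    expect_identical(al$conditions$sample, ids[1:10])
    expect_error(alignSamples(st$genotypes, st$phenotypes[ids[1], ]),
                 "fewer than 2")
})

test_that("a written study is parseable by every reader", {
    st <- smallStudy(seed = 105, n = 10, m = 6)
    dir <- withr::local_tempdir()
    paths <- writeStudy(st, dir)
    g <- readGenotypes(paths["genotypes"], paths["map"])
    p <- readPhenotypes(paths["phenotypes"], paths["categories"])
    cc <- readConditions(paths["conditions"])
    expect_identical(sampleIds(g), sampleIds(p))
    expect_identical(cc$sample, sampleIds(g))
})
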