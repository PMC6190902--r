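#' Simulate a founder haplotype panel
#'
#' Builds a panel of inbred founder haplotypes (binary allele codes) from
#' which heterogeneous-stock-like mosaic genomes can be drawn. For each
#' marker a target minor-allele frequency is drawn uniformly in
#' \code{[mafLow, mafHigh]} and realised by assigning the minor allele to
#' \code{k} founders, \code{k = round(target * nFounders)} clamped to
#' \code{[1, nFounders - 1]}; under equal founder mixing the population
#' frequency is then \code{k / nFounders}, so achievable frequencies are
#' quantised in steps of \code{1 / nFounders}. The achieved frequency is
#' stored as the panel's \code{targetMaf}. With a single founder every
#' marker is monomorphic.
#'
#' @param nFounders number of founder strains (8 for an HS mouse panel).
#' @param nMarkers total number of markers.
#' @param chromLayout named integer vector giving markers per chromosome;
#'   default splits markers evenly over \code{min(10, nMarkers)}
#'   chromosomes. Positions are drawn with mean spacing ~100 kb and are
#'   strictly increasing within each chromosome.
#' @param mafLow,mafHigh bounds of the target minor-allele frequency,
#'   \code{0 < mafLow <= mafHigh <= 0.5}.
#' @param seed integer seed; identical seeds give identical panels.
#' @return A \linkS4class{FounderPanel}.
#' @examples
#' p <- simulateFounderPanel(8, 100, seed = 1)
#' range(targetMaf(p))
#' @export
simulateFounderPanel <- function(nFounders = 8, nMarkers = 1000,
                                 chromLayout = NULL, mafLow = 0.05,
                                 mafHigh = 0.5, seed = NULL) {
    nFounders <- .assertCount(nFounders, "nFounders")
    nMarkers <- .assertCount(nMarkers, "nMarkers")
    .assertFraction(mafLow, "mafLow", lo = 0, hi = 0.5, lo.open = TRUE)
    .assertFraction(mafHigh, "mafHigh", lo = mafLow, hi = 0.5)
    .setSeed(seed)
    if (is.null(chromLayout)) {
        nChrom <- min(10L, nMarkers)
        base <- nMarkers %/% nChrom
        chromLayout <- rep.int(base, nChrom)
        chromLayout[seq_len(nMarkers %% nChrom)] <-
            chromLayout[seq_len(nMarkers %% nChrom)] + 1L
        names(chromLayout) <- paste0("chr", seq_len(nChrom))
    }
    stopifnot(sum(chromLayout) == nMarkers, all(chromLayout >= 1))
    chrom <- rep(names(chromLayout), chromLayout)
    bp <- unlist(lapply(chromLayout, function(m) {
        cumsum(as.integer(round(stats::runif(m, 5e4, 1.5e5))))
    }), use.names = FALSE)
    map <- data.frame(marker = sprintf("m%05d", seq_len(nMarkers)),
                      chrom = chrom, bp = bp,
                      ref = "A", alt = "B")
    if (nFounders == 1L) {
        hap <- matrix(0L, 1L, nMarkers)
        maf <- rep(0, nMarkers)
    } else {
        target <- stats::runif(nMarkers, mafLow, mafHigh)
        k <- pmin(pmax(as.integer(round(target * nFounders)), 1L),
                  nFounders - 1L)
        hap <- matrix(0L, nFounders, nMarkers)
        for (m in seq_len(nMarkers)) {
            hap[sample.int(nFounders, k[m]), m] <- 1L
        }
        maf <- pmin(k, nFounders - k) / nFounders
    }
    rownames(hap) <- paste0("f", seq_len(nFounders))
    colnames(hap) <- map$marker
    new("FounderPanel", haplotypes = hap, markerMap = map, targetMaf = maf)
}

#' Simulate heterogeneous-stock mosaic genomes
#'
#' Each sample carries two haplotypes per chromosome, each a mosaic of
#' founder segments: the founder of origin follows a Markov chain along
#' the ordered markers, switching with probability
#' \code{1 / meanBlockMarkers} per step to a uniformly drawn founder, so
#' segment lengths are approximately geometric with the given mean. Dosage
#' at a marker is the sum of the two haplotype alleles (0, 1 or 2); no
#' missing values are produced.
#'
#' @param panel a \linkS4class{FounderPanel}.
#' @param nSamples number of diploid samples.
#' @param meanBlockMarkers mean mosaic segment length, in markers (>= 1).
#' @param seed integer seed.
#' @return A \linkS4class{GenotypeExperiment}.
#' @examples
#' p <- simulateFounderPanel(8, 50, seed = 1)
#' g <- simulateHSGenomes(p, 20, seed = 2)
#' dim(dosages(g))
#' @export
simulateHSGenomes <- function(panel, nSamples, meanBlockMarkers = 20,
                              seed = NULL) {
    stopifnot(is(panel, "FounderPanel"))
    nSamples <- .assertCount(nSamples, "nSamples")
    if (!is.numeric(meanBlockMarkers) || meanBlockMarkers < 1) {
        stop("'meanBlockMarkers' must be >= 1")
    }
    hap <- founderHaplotypes(panel)
    map <- markerMap(panel)
    if (ncol(hap) == 0L) stop("empty founder panel")
    .setSeed(seed)
    nF <- nrow(hap)
    nH <- 2L * nSamples
    pSwitch <- 1 / meanBlockMarkers
    dosage <- matrix(0L, nSamples, nrow(map))
    for (ch in unique(map$chrom)) {
        idx <- which(map$chrom == ch)
        m <- length(idx)
        state <- sample.int(nF, nH, replace = TRUE)
        alle <- matrix(0L, nH, m)
        alle[, 1L] <- hap[cbind(state, idx[1L])]
        if (m > 1L) {
            for (k in 2L:m) {
                sw <- stats::runif(nH) < pSwitch
                if (any(sw)) {
                    state[sw] <- sample.int(nF, sum(sw), replace = TRUE)
                }
                alle[, k] <- hap[cbind(state, idx[k])]
            }
        }
        dosage[, idx] <- alle[seq_len(nSamples), , drop = FALSE] +
            alle[nSamples + seq_len(nSamples), , drop = FALSE]
    }
    dimnames(dosage) <- list(sprintf("s%04d", seq_len(nSamples)), map$marker)
    g <- makeGenotypes(dosage, map)
    metadata(g)$meanBlockMarkers <- meanBlockMarkers
    metadata(g)$seed <- seed
    g
}

#' Describe a condition-dependent phenotype architecture
#'
#' Bundles the genetic architecture used by \code{\link{simulatePhenotypes}}:
#' which markers carry additive effects under each environmental condition,
#' how much of the phenotypic variance is genetic, how measures group into
#' correlated composite categories, and per-cohort location/scale shifts.
#'
#' @param effects named list, one entry per condition label, each a
#'   data.frame with columns \code{marker} and \code{effect} (may have zero
#'   rows for a condition with no genetic signal).
#' @param heritability fraction of phenotypic variance that is genetic;
#'   a scalar, or a named vector with one entry per category.
#' @param withinCor target realised Pearson correlation between measures of
#'   the same category (scalar or per-category). Internally the latent
#'   category factor's share is solved so that the realised within-category
#'   correlation is approximately \code{withinCor} and the between-category
#'   correlation is approximately the (geometric mean) heritability.
#' @param categories character vector of category names; default the six
#'   composite fear-conditioning categories.
#' @param measuresPerCategory measures simulated per category (default 4).
#' @param cohortShift data.frame with columns \code{cohort}, \code{offset},
#'   \code{varMult}: additive mean offset and variance multiplier applied
#'   last, per cohort. Default: no shift.
#' @return A list of class \code{"hsArchitecture"}.
#' @examples
#' arch <- hsArchitecture(
#'     effects = list(sham = data.frame(marker = "m00001", effect = 1)),
#'     heritability = 0.4)
#' @export
hsArchitecture <- function(effects,
                           heritability = 0.3,
                           withinCor = 0.7,
                           categories = c("context_pctfrze", "context_avgmot",
                                          "cued_pctfrze", "train_pctfrze",
                                          "shock_avgmot", "train_avgmo"),
                           measuresPerCategory = 4,
                           cohortShift = NULL) {
    stopifnot(is.list(effects), length(names(effects)) == length(effects))
    for (e in effects) {
        stopifnot(is.data.frame(e), all(c("marker", "effect") %in% colnames(e)))
    }
    if (is.null(names(heritability))) {
        heritability <- stats::setNames(rep_len(heritability,
                                                length(categories)),
                                        categories)
    }
    vapply(heritability, .assertFraction, numeric(1), name = "heritability")
    if (is.null(names(withinCor))) {
        withinCor <- stats::setNames(rep_len(withinCor, length(categories)),
                                     categories)
    }
    if (is.null(cohortShift)) {
        cohortShift <- data.frame(cohort = "cohort1", offset = 0, varMult = 1)
    }
    stopifnot(all(c("cohort", "offset", "varMult") %in% colnames(cohortShift)),
              all(cohortShift$varMult > 0))
    measuresPerCategory <- .assertCount(measuresPerCategory,
                                        "measuresPerCategory")
    structure(list(effects = effects,
                   heritability = heritability[categories],
                   withinCor = withinCor[categories],
                   categories = categories,
                   measuresPerCategory = measuresPerCategory,
                   cohortShift = cohortShift),
              class = "hsArchitecture")
}

#' Simulate condition-dependent correlated phenotypes
#'
#' For each sample, a condition-specific genetic score (the dosage-weighted
#' sum over that condition's effect markers, standardised within condition)
#' is mixed with a shared latent category factor and independent noise:
#' \deqn{x = \sqrt{h^2}\, z + \sqrt{1-h^2}\,(\sqrt{\rho}\, F + \sqrt{1-\rho}\,\epsilon)}
#' so measures have unit variance, within-category correlation
#' approximately \code{withinCor}, and genetic variance fraction
#' \code{heritability}. Cohort mean offsets and variance multipliers are
#' applied last (they do not change correlations after standardisation).
#'
#' @param genotypes a \linkS4class{GenotypeExperiment}.
#' @param spec an \code{\link{hsArchitecture}}.
#' @param conditions data.frame with columns \code{sample},
#'   \code{condition} and optionally \code{cohort}, covering every sample.
#' @param seed integer seed.
#' @return A list with elements \code{phenotypes}
#'   (\linkS4class{PhenotypeTable}) and \code{truth} (ground-truth list:
#'   causal markers per condition, realised per-measure heritability,
#'   condition and cohort labels).
#' @export
simulatePhenotypes <- function(genotypes, spec, conditions, seed = NULL) {
    stopifnot(is(genotypes, "GenotypeExperiment"),
              inherits(spec, "hsArchitecture"),
              is.data.frame(conditions),
              all(c("sample", "condition") %in% colnames(conditions)))
    ids <- sampleIds(genotypes)
    if (!setequal(conditions$sample, ids) ||
        anyDuplicated(conditions$sample)) {
        stop("every genotyped sample needs exactly one condition label")
    }
    conditions <- conditions[match(ids, conditions$sample), , drop = FALSE]
    if (!"cohort" %in% colnames(conditions)) {
        conditions$cohort <- spec$cohortShift$cohort[1L]
    }
    unknown <- setdiff(unique(conditions$condition), names(spec$effects))
    if (length(unknown)) {
        stop("condition label(s) without an architecture entry: ",
             paste(unknown, collapse = ", "))
    }
    badMarkers <- setdiff(
        unlist(lapply(spec$effects, function(e) e$marker), use.names = FALSE),
        markerIds(genotypes))
    if (length(badMarkers)) {
        stop("effect markers absent from genotypes: ",
             paste(utils::head(badMarkers, 5), collapse = ", "))
    }
    .setSeed(seed)
    dos <- dosages(genotypes)
    n <- length(ids)
    z <- numeric(n)
    for (cond in names(spec$effects)) {
        sel <- conditions$condition == cond
        if (!any(sel)) next
        eff <- spec$effects[[cond]]
        if (nrow(eff)) {
            raw <- as.vector(dos[sel, eff$marker, drop = FALSE] %*% eff$effect)
            s <- stats::sd(raw)
            z[sel] <- if (s > 0) (raw - mean(raw)) / s else 0
        }
    }
    cats <- spec$categories
    nm <- spec$measuresPerCategory
    measures <- as.vector(t(outer(cats, seq_len(nm), function(a, b) {
        paste0(a, "_m", b)
    })))
    catMap <- stats::setNames(rep(cats, each = nm), measures)
    x <- matrix(NA_real_, n, length(measures),
                dimnames = list(ids, measures))
    realized <- stats::setNames(numeric(length(measures)), measures)
    for (k in cats) {
        h2 <- spec$heritability[[k]]
        rho <- if (h2 >= 1) 0 else
            min(max((spec$withinCor[[k]] - h2) / (1 - h2), 0), 1)
        f <- stats::rnorm(n)
        for (j in seq_len(nm)) {
            e <- stats::rnorm(n)
            col <- paste0(k, "_m", j)
            val <- sqrt(h2) * z +
                sqrt(1 - h2) * (sqrt(rho) * f + sqrt(1 - rho) * e)
            x[, col] <- val
            vt <- stats::var(val)
            realized[col] <- if (vt > 0) h2 * stats::var(z) / vt else 0
        }
    }
    for (i in seq_len(nrow(spec$cohortShift))) {
        co <- spec$cohortShift$cohort[i]
        sel <- conditions$cohort == co
        if (!any(sel)) next
        x[sel, ] <- spec$cohortShift$offset[i] +
            sqrt(spec$cohortShift$varMult[i]) * x[sel, , drop = FALSE]
    }
    truth <- list(
        causal = lapply(spec$effects, function(e) e$marker),
        realizedHeritability = realized,
        conditions = stats::setNames(conditions$condition, ids),
        cohorts = stats::setNames(conditions$cohort, ids),
        categoryMap = catMap,
        seed = seed)
    list(phenotypes = makePhenotypes(x, catMap), truth = truth)
}

# Draw k causal markers defining DISTINCT, detectable loci: common
# variants (panel minor-allele frequency >= 0.25) separated by at least one
# mean mosaic block, so the planted architecture really has k loci rather
# than fewer (same-block draws) or undetectable ones (rare alleles).
.spacedCausalPool <- function(panel, k, meanBlockMarkers) {
    map <- markerMap(panel)
    common <- which(targetMaf(panel) >= 0.25)
    if (length(common) < k) common <- order(-targetMaf(panel))[seq_len(
        min(length(targetMaf(panel)), max(k, 1L)))]
    cand <- sample(common)
    chosen <- integer(0)
    for (i in cand) {
        # map rows are in (chrom, position) order, so row-index distance on
        # the same chromosome counts intervening markers
        ok <- !length(chosen) ||
            all(map$chrom[chosen] != map$chrom[i] |
                abs(chosen - i) > meanBlockMarkers)
        if (ok) chosen <- c(chosen, i)
        if (length(chosen) == k) break
    }
    if (length(chosen) < k) {
        chosen <- c(chosen, setdiff(cand, chosen)[seq_len(k - length(chosen))])
    }
    map$marker[chosen]
}

#' Simulate a complete heterogeneous-stock study
#'
#' One-call generator producing genotypes, phenotypes, condition/cohort
#' labels and the ground truth for a two-condition study. The fraction of
#' causal markers shared between the two conditions' architectures is a
#' knob (\code{architectureOverlap}): 1 plants identical loci in both
#' conditions, 0 fully condition-specific loci.
#'
#' @param nSamples,nMarkers study dimensions.
#' @param nFounders founder strains (default 8).
#' @param meanBlockMarkers mean mosaic segment length in markers.
#' @param conditionNames two condition labels (e.g. sham vs irradiated).
#' @param nCausal causal markers per condition.
#' @param architectureOverlap fraction in [0, 1] of causal markers shared
#'   between the two conditions.
#' @param heritability,withinCor passed to \code{\link{hsArchitecture}}.
#' @param cohortNames cohort labels; samples are split evenly.
#' @param cohortShift as in \code{\link{hsArchitecture}}; default gives the
#'   second cohort a +0.5 mean offset and 1.5x variance, no shift for the
#'   first.
#' @param effectSize additive effect per causal marker (default 1).
#' @param seed master seed; all stages derive child seeds from it.
#' @return list: \code{genotypes}, \code{phenotypes}, \code{conditions}
#'   (data.frame sample/condition/cohort), \code{truth}, \code{panel}.
#' @examples
#' st <- simulateStudy(nSamples = 60, nMarkers = 200, seed = 1)
#' st$truth$causal$sham
#' @export
simulateStudy <- function(nSamples = 200, nMarkers = 1000, nFounders = 8,
                          meanBlockMarkers = 20,
                          conditionNames = c("sham", "irradiated"),
                          nCausal = 10, architectureOverlap = 1,
                          heritability = 0.3, withinCor = 0.7,
                          cohortNames = "cohort1", cohortShift = NULL,
                          effectSize = 1, seed = NULL) {
    stopifnot(length(conditionNames) == 2L)
    .assertFraction(architectureOverlap, "architectureOverlap")
    seeds <- if (is.null(seed)) rep(list(NULL), 4L) else .childSeeds(seed, 4L)
    panel <- simulateFounderPanel(nFounders, nMarkers, seed = seeds[[1L]])
    g <- simulateHSGenomes(panel, nSamples, meanBlockMarkers,
                           seed = seeds[[2L]])
    .setSeed(seeds[[3L]])
    ids <- sampleIds(g)
    conditions <- data.frame(
        sample = ids,
        condition = sample(rep_len(conditionNames, nSamples)),
        cohort = sample(rep_len(cohortNames, nSamples)))
    nShared <- round(architectureOverlap * nCausal)
    pool <- .spacedCausalPool(panel, 2L * nCausal, meanBlockMarkers)
    causalA <- pool[seq_len(nCausal)]
    causalB <- c(causalA[seq_len(nShared)],
                 pool[nCausal + seq_len(nCausal - nShared)])
    effects <- stats::setNames(list(
        data.frame(marker = causalA, effect = effectSize),
        data.frame(marker = causalB, effect = effectSize)),
        conditionNames)
    if (is.null(cohortShift)) {
        co <- unique(cohortNames)
        cohortShift <- data.frame(
            cohort = co,
            offset = ifelse(seq_along(co) == 1L, 0, 0.5),
            varMult = ifelse(seq_along(co) == 1L, 1, 1.5))
    }
    arch <- hsArchitecture(effects, heritability = heritability,
                           withinCor = withinCor, cohortShift = cohortShift)
    sim <- simulatePhenotypes(g, arch, conditions, seed = seeds[[4L]])
    list(genotypes = g, phenotypes = sim$phenotypes,
         conditions = conditions, truth = sim$truth, panel = panel,
         architecture = arch)
}
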