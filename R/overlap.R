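# Overlap of significant marker sets detected under different conditions
# (cohorts, or sham vs irradiated). Membership is cross-tabulated over a
# shared marker universe and tested with the Fisher exact test; the
# directional claim (concordant vs shifted architectures) is carried by
# the odds ratio and its confidence interval.

#' Cross-tabulate two marker sets over a universe
#'
#' @param setA,setB character vectors of marker ids, subsets of
#'   \code{universe}.
#' @param universe character vector, the shared marker universe (markers
#'   surviving the MAF filter in the joint data).
#' @return 2x2 integer matrix: rows in/out of A, columns in/out of B;
#'   \code{a} = in both, \code{d} = in neither.
#' @examples
#' overlapTable(c("m1", "m2"), c("m2", "m3"), paste0("m", 1:10))
#' @export
overlapTable <- function(setA, setB, universe) {
    if (anyDuplicated(universe)) stop("universe ids must be unique")
    outA <- setdiff(setA, universe)
    outB <- setdiff(setB, universe)
    if (length(outA) || length(outB)) {
        stop("set member(s) outside the universe: ",
             paste(utils::head(c(outA, outB), 5), collapse = ", "))
    }
    inA <- universe %in% setA
    inB <- universe %in% setB
    m <- matrix(c(sum(inA & inB), sum(inA & !inB),
                  sum(!inA & inB), sum(!inA & !inB)),
                2L, 2L,
                dimnames = list(A = c("in", "out"), B = c("in", "out")))
    m
}

#' Fisher exact test of marker-set overlap
#'
#' Exact two-sided p-value from the hypergeometric distribution
#' (\code{\link[stats]{fisher.test}}), the cross-product odds ratio
#' \eqn{(ad)/(bc)} with the Haldane-Anscombe +0.5 correction applied to
#' all cells when any cell is zero, and the Woolf log-OR 95\% confidence
#' interval. An empty margin (one of the sets is empty) gives a flagged
#' result with an undefined odds ratio.
#'
#' @param table 2x2 matrix from \code{\link{overlapTable}}.
#' @return list of class \code{"fisherOverlap"}: \code{table},
#'   \code{oddsRatio}, \code{conf.int}, \code{p.value}, \code{universe}
#'   (size), \code{flagged}.
#' @examples
#' fisherOverlap(matrix(c(10, 5, 5, 80), 2))$oddsRatio  # 32
#' @export
fisherOverlap <- function(table) {
    stopifnot(is.matrix(table), identical(dim(table), c(2L, 2L)),
              all(table >= 0), all(table == floor(table)))
    a <- table[1L, 1L]; b <- table[1L, 2L]
    c_ <- table[2L, 1L]; d <- table[2L, 2L]
    flagged <- (a + b) == 0 || (a + c_) == 0
    if (flagged) {
        return(structure(list(table = table, oddsRatio = NA_real_,
                              conf.int = c(NA_real_, NA_real_),
                              p.value = NA_real_, universe = sum(table),
                              flagged = TRUE),
                         class = "fisherOverlap"))
    }
    p <- stats::fisher.test(table, alternative = "two.sided")$p.value
    cells <- c(a, b, c_, d)
    if (any(cells == 0)) cells <- cells + 0.5
    or <- (cells[1L] * cells[4L]) / (cells[2L] * cells[3L])
    se <- sqrt(sum(1 / cells))
    ci <- exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se)
    structure(list(table = table, oddsRatio = or, conf.int = ci,
                   p.value = p, universe = sum(table), flagged = FALSE),
              class = "fisherOverlap")
}

#' @export
print.fisherOverlap <- function(x, ...) {
    cat("Fisher overlap test over a universe of", x$universe, "markers\n")
    print(x$table)
    if (x$flagged) {
        cat("degenerate margin: odds ratio undefined\n")
    } else {
        cat(sprintf("odds ratio %.3g (95%% CI %.3g-%.3g), p = %.3g\n",
                    x$oddsRatio, x$conf.int[1L], x$conf.int[2L], x$p.value))
    }
    invisible(x)
}

#' Compare marker sets detected under two environmental strata
#'
#' Splits the samples by a stratum label (cohort, or sham vs irradiated),
#' runs the full scan - gate - forward-selection pipeline independently in
#' each stratum for each phenotype category, and tests the overlap of the
#' two detected marker sets with the Fisher exact test over the shared
#' post-MAF marker universe.
#'
#' @param g a \linkS4class{GenotypeExperiment} covering all samples.
#' @param pheno a \linkS4class{PhenotypeTable}.
#' @param strata named character/factor vector (sample id -> stratum) with
#'   exactly two levels, or a data.frame with columns \code{sample} and the
#'   column named by \code{split}.
#' @param split column name when \code{strata} is a data.frame.
#' @param categories categories to analyse (default: all).
#' @param B,pGate,maxK,plateauTol,standardize,metric pipeline parameters.
#' @param mafThreshold MAF filter applied to the joint data; the surviving
#'   markers are the shared universe.
#' @param setDefinition \code{"peak"} (forward-selected peak set, default)
#'   or \code{"gate"} (all gate-passing markers).
#' @param minStratum smallest acceptable stratum size (default 30).
#' @param seed master seed; per-stratum scans draw child seeds.
#' @return data.frame with one row per category: the 2x2 counts, odds
#'   ratio, CI, p-value and set sizes; the detected sets are in
#'   \code{attr(, "sets")}.
#' @examples
#' st <- simulateStudy(nSamples = 120, nMarkers = 120, nCausal = 4,
#'                     heritability = 0.6, architectureOverlap = 1,
#'                     seed = 3)
#' compareConditions(st$genotypes, st$phenotypes, st$conditions,
#'                   split = "condition", categories = "context_avgmot",
#'                   B = 199, minStratum = 20, seed = 4)
#' @export
compareConditions <- function(g, pheno, strata, split = "condition",
                              categories = NULL, B = 199, pGate = 0.01,
                              maxK = NULL, plateauTol = 0.02,
                              standardize = TRUE,
                              metric = c("manhattan", "ibs"),
                              mafThreshold = 0.05,
                              setDefinition = c("peak", "gate"),
                              minStratum = 30, seed = NULL) {
    setDefinition <- match.arg(setDefinition)
    metric <- match.arg(metric)
    if (is.data.frame(strata)) {
        stopifnot(all(c("sample", split) %in% colnames(strata)))
        strata <- stats::setNames(as.character(strata[[split]]),
                                  strata$sample)
    }
    ids <- sampleIds(g)
    if (!all(ids %in% names(strata))) {
        stop("every genotyped sample needs a stratum label")
    }
    strata <- strata[ids]
    lev <- sort(unique(strata))
    if (length(lev) != 2L) stop("exactly two strata are required")
    sizes <- table(strata)
    if (any(sizes < minStratum)) {
        stop("stratum below the size floor of ", minStratum, ": ",
             paste(names(sizes)[sizes < minStratum], collapse = ", "),
             " (n = ", paste(sizes[sizes < minStratum], collapse = ", "),
             ")")
    }
    g <- filterMarkersByMAF(g, mafThreshold)
    universe <- markerIds(g)
    if (is.null(categories)) categories <- categories(pheno)
    seeds <- if (is.null(seed)) NULL else
        matrix(.childSeeds(seed, 2L * length(categories)), nrow = 2L)
    sets <- list()
    rows <- lapply(seq_along(categories), function(ci) {
        cat_ <- categories[ci]
        perStratum <- lapply(seq_along(lev), function(li) {
            sub <- g[, strata == lev[li]]
            phenoD <- phenotypeDistance(pheno, cat_,
                                        standardize = standardize,
                                        samples = sampleIds(sub))
            sc <- singleMarkerScan(sub, phenoD, B = B,
                                   seed = if (is.null(seeds)) NULL else
                                       seeds[li, ci],
                                   metric = metric)
            elig <- eligibleMarkers(sc, pGate)
            if (!length(elig)) return(character(0))
            if (setDefinition == "gate") return(elig)
            cur <- cumulativeCurve(sub, phenoD, elig, maxK = maxK,
                                   pGate = pGate, plateauTol = plateauTol,
                                   metric = metric)
            peakMarkers(cur)
        })
        names(perStratum) <- lev
        sets[[cat_]] <<- perStratum
        fo <- fisherOverlap(overlapTable(perStratum[[1L]], perStratum[[2L]],
                                         universe))
        data.frame(category = cat_,
                   a = fo$table[1L, 1L], b = fo$table[1L, 2L],
                   c = fo$table[2L, 1L], d = fo$table[2L, 2L],
                   oddsRatio = fo$oddsRatio,
                   ciLow = fo$conf.int[1L], ciHigh = fo$conf.int[2L],
                   p = fo$p.value,
                   sizeA = length(perStratum[[1L]]),
                   sizeB = length(perStratum[[2L]]))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    structure(out, sets = sets, strata = lev, universeSize = length(universe))
}
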