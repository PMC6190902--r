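# End-to-end orchestration: filter, per-stratum per-category scan /
# selection / calibration, cross-stratum overlap, gene windows and
# enrichment, with one master seed and a config that is echoed into every
# output header.

#' Assemble and validate a pipeline configuration
#'
#' Houses the analysis constants: the MAF filter (markers retained above
#' 5\% by default), the per-marker gate (p < 0.01), the scan permutation
#' count, the number of label shuffles for the empirical null, the plateau
#' tolerance, and the gene window (1 Mb).
#'
#' @param mafThreshold MAF filter threshold in [0, 0.5).
#' @param pGate per-marker permutation p-value gate in (0, 1).
#' @param B scan permutations (>= 1).
#' @param R null-ensemble shuffles (>= 2).
#' @param plateauTol plateau tolerance in [0, 1).
#' @param windowBp gene window half-width in bp.
#' @param metric genotype distance metric (\code{"manhattan"} or
#'   \code{"ibs"}).
#' @param standardize standardise phenotype measures before the Manhattan
#'   distance.
#' @param split stratum column in the conditions table used for the
#'   cross-stratum comparison (default \code{"condition"}).
#' @param setDefinition marker-set definition entering the overlap test:
#'   \code{"peak"} or \code{"gate"}.
#' @param minStratum smallest acceptable stratum size.
#' @param seed master seed.
#' @return validated list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(mafThreshold = 0.05, pGate = 0.01, B = 999,
                           R = 25, plateauTol = 0.02, windowBp = 1e6,
                           metric = c("manhattan", "ibs"),
                           standardize = TRUE, split = "condition",
                           setDefinition = c("peak", "gate"),
                           minStratum = 30, seed = 1) {
    metric <- match.arg(metric)
    setDefinition <- match.arg(setDefinition)
    .assertFraction(mafThreshold, "mafThreshold", lo = 0, hi = 0.5,
                    hi.open = TRUE)
    .assertFraction(pGate, "pGate", lo = 0, hi = 1, lo.open = TRUE)
    B <- .assertCount(B, "B")
    R <- .assertCount(R, "R", min = 2L)
    .assertFraction(plateauTol, "plateauTol", lo = 0, hi = 1,
                    hi.open = TRUE)
    if (!is.numeric(windowBp) || windowBp <= 0) {
        stop("'windowBp' must be positive")
    }
    structure(list(mafThreshold = mafThreshold, pGate = pGate, B = B,
                   R = R, plateauTol = plateauTol, windowBp = windowBp,
                   metric = metric, standardize = standardize,
                   split = split, setDefinition = setDefinition,
                   minStratum = minStratum, seed = seed),
              class = "PipelineConfig")
}

# order-insensitive FNV-1a style hash of the serialised config, for
# provenance headers
.configHash <- function(config) {
    bytes <- as.integer(serialize(config[order(names(unclass(config)))],
                                  NULL, version = 2L))
    h <- 2166136261
    for (b in bytes) {
        h <- bitwXor(as.integer(h %% 2^31), b) * 16777619
        h <- h %% 2^31
    }
    sprintf("%08x", as.integer(h))
}

#' Run the full distance-based multi-locus association analysis
#'
#' Three steps per stratum and phenotype category, mirroring the method's
#' structure: (1) a single-marker Mantel scan with permutation p-values;
#' (2) forward selection of the cumulative-correlation curve over
#' gate-passing markers; (3) the label-shuffled empirical null converting
#' the curve to Z-scores. Across the two strata, peak marker sets are
#' compared with Fisher exact overlap tests; markers detected in both
#' strata seed gene windows and gene-set enrichment when an annotation and
#' collections are supplied.
#'
#' @param g a \linkS4class{GenotypeExperiment}.
#' @param pheno a \linkS4class{PhenotypeTable}.
#' @param conditions data.frame with columns \code{sample} and the stratum
#'   column named by \code{config$split}.
#' @param config a \code{\link{pipelineConfig}}.
#' @param annotation optional gene annotation data.frame
#'   (\code{\link{readGeneAnnotation}}).
#' @param collections optional named list of GMT collections, each a named
#'   list of gene sets; enrichment is run (and BH-adjusted) per collection.
#' @param categories categories to analyse (default: all).
#' @param outDir optional directory; when given, scan/curve/Z tables and
#'   overlap reports are written as TSV with a provenance header (config
#'   hash and seed) plus a YAML manifest.
#' @return list: \code{strata} (per stratum, per category: scan, curve,
#'   ensemble, z), \code{overlap} (data.frame from
#'   \code{\link{compareConditions}}), \code{commonMarkers},
#'   \code{genes}, \code{enrichment} (per collection), \code{config},
#'   \code{configHash}.
#' @export
runFullAnalysis <- function(g, pheno, conditions, config = pipelineConfig(),
                            annotation = NULL, collections = NULL,
                            categories = NULL, outDir = NULL) {
    stopifnot(inherits(config, "PipelineConfig"),
              is.data.frame(conditions),
              all(c("sample", config$split) %in% colnames(conditions)))
    strata <- stats::setNames(as.character(conditions[[config$split]]),
                              conditions$sample)
    ids <- sampleIds(g)
    if (!all(ids %in% names(strata))) {
        stop("every genotyped sample needs a '", config$split, "' label")
    }
    strata <- strata[ids]
    lev <- sort(unique(strata))
    if (length(lev) != 2L) stop("exactly two strata are required")
    sizes <- table(strata)
    if (any(sizes < config$minStratum)) {
        stop("stratum below the size floor of ", config$minStratum)
    }
    if (is.null(categories)) categories <- categories(pheno)
    message("samples: ", length(ids), "; strata: ",
            paste(sprintf("%s(n=%d)", lev, sizes[lev]), collapse = ", "))
    g <- filterMarkersByMAF(g, config$mafThreshold)
    universe <- markerIds(g)
    message("markers in universe after MAF filter: ", length(universe))

    seeds <- matrix(.childSeeds(config$seed, 2L * length(categories)),
                    nrow = 2L)
    perStratum <- lapply(seq_along(lev), function(li) {
        sub <- g[, strata == lev[li]]
        res <- lapply(seq_along(categories), function(ci) {
            calibratedAnalysis(sub, pheno, categories[ci], B = config$B,
                               R = config$R, pGate = config$pGate,
                               plateauTol = config$plateauTol,
                               standardize = config$standardize,
                               metric = config$metric,
                               seed = seeds[li, ci])
        })
        names(res) <- categories
        res
    })
    names(perStratum) <- lev

    peaks <- lapply(perStratum, function(st) {
        lapply(st, function(x) {
            if (config$setDefinition == "gate") {
                if (is.null(x$curve)) character(0) else curveMarkers(x$curve)
            } else {
                if (is.null(x$curve)) character(0) else peakMarkers(x$curve)
            }
        })
    })
    overlap <- do.call(rbind, lapply(categories, function(cat_) {
        fo <- fisherOverlap(overlapTable(peaks[[1L]][[cat_]],
                                         peaks[[2L]][[cat_]], universe))
        data.frame(category = cat_, a = fo$table[1L, 1L],
                   b = fo$table[1L, 2L], c = fo$table[2L, 1L],
                   d = fo$table[2L, 2L], oddsRatio = fo$oddsRatio,
                   ciLow = fo$conf.int[1L], ciHigh = fo$conf.int[2L],
                   p = fo$p.value)
    }))

    common <- lapply(categories, function(cat_) {
        intersectConditionMarkers(peaks[[1L]][[cat_]], peaks[[2L]][[cat_]])
    })
    names(common) <- categories

    genes <- NULL
    enr <- NULL
    if (!is.null(annotation)) {
        map <- markerMap(g)
        genes <- lapply(common, function(mk) {
            if (!length(mk)) return(character(0))
            genesNearMarkers(mk, map, annotation, config$windowBp)
        })
        if (!is.null(collections)) {
            chromsTested <- unique(map$chrom)
            uniGenes <- annotation$gene[annotation$chrom %in% chromsTested]
            enr <- lapply(names(collections), function(cn) {
                res <- lapply(categories, function(cat_) {
                    if (!length(genes[[cat_]])) return(NULL)
                    enrich(genes[[cat_]], collections[[cn]], uniGenes)
                })
                names(res) <- categories
                res
            })
            names(enr) <- names(collections)
        }
    }

    out <- list(strata = perStratum, overlap = overlap,
                commonMarkers = common, genes = genes, enrichment = enr,
                config = config, configHash = .configHash(config))
    if (!is.null(outDir)) .writeReportBundle(out, lev, categories, outDir)
    out
}

# TSV writer with a provenance header line
.writeTsv <- function(df, path, hash, seed) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# config_hash=%s seed=%s", hash, seed), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
}

.writeReportBundle <- function(res, lev, categories, outDir) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    hash <- res$configHash
    seed <- res$config$seed
    for (st in lev) {
        for (cat_ in categories) {
            x <- res$strata[[st]][[cat_]]
            base <- file.path(outDir, paste0(st, "_", cat_))
            .writeTsv(x$scan, paste0(base, "_scan.tsv"), hash, seed)
            if (!is.null(x$curve)) {
                .writeTsv(data.frame(k = seq_along(curveStat(x$curve)),
                                     marker = curveMarkers(x$curve),
                                     c = curveStat(x$curve)),
                          paste0(base, "_curve.tsv"), hash, seed)
            }
            if (!is.null(x$z)) {
                .writeTsv(x$z, paste0(base, "_z.tsv"), hash, seed)
            }
        }
    }
    .writeTsv(res$overlap, file.path(outDir, "overlap.tsv"), hash, seed)
    peaks <- lapply(res$strata, function(st) {
        lapply(st, function(x) {
            if (is.null(x$curve)) {
                list(k = 0L, c = NA_real_, markers = character(0))
            } else {
                list(k = peakIndex(x$curve), c = peakValue(x$curve),
                     markers = peakMarkers(x$curve))
            }
        })
    })
    manifest <- list(config = unclass(res$config), configHash = hash,
                     strata = lev, categories = categories,
                     peaks = peaks)
    yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
    invisible(outDir)
}
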