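#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

#' GenotypeExperiment: SNP dosages with a marker map
#'
#' A \linkS4class{SummarizedExperiment} holding a single \code{"dosage"}
#' assay with markers as rows and samples as columns. Dosage is the count
#' of the minor allele in a diploid genotype, so values are 0, 1 or 2
#' (mean-imputed values in \eqn{[0, 2]} are tolerated after an explicit
#' imputation step; \code{NA} only transiently, before imputation).
#' Row metadata carries the marker map: chromosome label, 1-based basepair
#' position, and reference/alternate allele characters.
#'
#' @seealso \code{\link{makeGenotypes}}, \code{\link{readGenotypes}},
#'   \code{\link{filterMarkersByMAF}}
#' @export
setClass("GenotypeExperiment", contains = "SummarizedExperiment")

setValidity("GenotypeExperiment", function(object) {
    msg <- character()
    if (!"dosage" %in% SummarizedExperiment::assayNames(object)) {
        msg <- c(msg, "assay 'dosage' is required")
    } else {
        d <- SummarizedExperiment::assay(object, "dosage")
        if (!is.numeric(d)) {
            msg <- c(msg, "dosages must be numeric")
        } else {
            v <- d[!is.na(d)]
            if (length(v) && (min(v) < 0 || max(v) > 2)) {
                msg <- c(msg, "dosages must lie in [0, 2]")
            }
        }
    }
    rd <- rowData(object)
    need <- c("chrom", "bp")
    if (!all(need %in% colnames(rd))) {
        msg <- c(msg, "rowData must contain 'chrom' and 'bp'")
    } else if (nrow(rd) && (!is.numeric(rd$bp) || any(rd$bp < 1))) {
        msg <- c(msg, "'bp' positions must be positive integers (1-based)")
    }
    if (anyDuplicated(rownames(object))) {
        msg <- c(msg, "marker ids must be unique")
    }
    if (anyDuplicated(colnames(object))) {
        msg <- c(msg, "sample ids must be unique")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a GenotypeExperiment from a dosage matrix and marker map
#'
#' @param dosage numeric matrix, samples in rows and markers in columns
#'   (the orientation of a genotype file), values in \{0, 1, 2\} or
#'   \code{NA}; row and column names are required and become sample and
#'   marker ids.
#' @param markerMap data.frame with columns \code{marker}, \code{chrom},
#'   \code{bp} and optionally \code{ref}, \code{alt}; must cover every
#'   marker in \code{dosage}.
#' @return A \linkS4class{GenotypeExperiment}.
#' @examples
#' d <- matrix(c(0, 1, 2, 1), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("m1", "m2")))
#' map <- data.frame(marker = c("m1", "m2"), chrom = "chr1", bp = c(100, 200))
#' g <- makeGenotypes(d, map)
#' @export
makeGenotypes <- function(dosage, markerMap) {
    if (is.null(rownames(dosage)) || is.null(colnames(dosage))) {
        stop("'dosage' needs sample row names and marker column names")
    }
    if (!all(c("marker", "chrom", "bp") %in% colnames(markerMap))) {
        stop("'markerMap' needs columns marker, chrom, bp")
    }
    missing <- setdiff(colnames(dosage), markerMap$marker)
    if (length(missing)) {
        stop("markers absent from the map: ",
             paste(utils::head(missing, 5), collapse = ", "))
    }
    map <- markerMap[match(colnames(dosage), markerMap$marker), , drop = FALSE]
    if (!"ref" %in% colnames(map)) map$ref <- "A"
    if (!"alt" %in% colnames(map)) map$alt <- "B"
    rd <- DataFrame(chrom = as.character(map$chrom),
                    bp = as.integer(map$bp),
                    ref = as.character(map$ref),
                    alt = as.character(map$alt),
                    row.names = colnames(dosage))
    # uniform double storage so objects compare equal across write/read
    storage.mode(dosage) <- "double"
    se <- SummarizedExperiment(assays = list(dosage = t(dosage)), rowData = rd)
    new("GenotypeExperiment", se)
}

#' PhenotypeTable: behavioral measures with a category map
#'
#' Numeric behavioral/cognitive measures per sample, together with a map
#' assigning every measure to exactly one composite category (six
#' categories by default, mirroring grouped fear-conditioning measures such
#' as percent freezing during the contextual memory test). Categories are
#' the unit at which phenotype distance matrices are built.
#'
#' @slot values numeric matrix, samples in rows, measures in columns.
#' @slot categoryMap named character vector, measure -> category.
#' @seealso \code{\link{makePhenotypes}}, \code{\link{phenotypeDistance}}
#' @export
setClass("PhenotypeTable",
         representation(values = "matrix", categoryMap = "character"))

setValidity("PhenotypeTable", function(object) {
    msg <- character()
    v <- object@values
    if (is.null(rownames(v)) || is.null(colnames(v))) {
        msg <- c(msg, "values need sample row names and measure column names")
    }
    if (anyDuplicated(rownames(v))) msg <- c(msg, "sample ids must be unique")
    if (!is.numeric(v)) msg <- c(msg, "measure values must be numeric")
    cm <- object@categoryMap
    unmapped <- setdiff(colnames(v), names(cm))
    if (length(unmapped)) {
        msg <- c(msg, paste0("measures without a category: ",
                             paste(utils::head(unmapped, 5), collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
})

#' Construct a PhenotypeTable
#'
#' @param values numeric matrix (samples x measures) with dimnames.
#' @param categoryMap named character vector mapping each measure name to
#'   its category.
#' @return A \linkS4class{PhenotypeTable}.
#' @export
makePhenotypes <- function(values, categoryMap) {
    new("PhenotypeTable", values = values,
        categoryMap = categoryMap[colnames(values)])
}

#' FounderPanel: founder haplotypes for a heterogeneous-stock simulator
#'
#' Binary allele codes for each founder strain at each marker, plus the
#' marker map and the per-marker population minor-allele frequency implied
#' by equal founder mixing (the achievable frequencies are multiples of
#' 1/n_founders).
#'
#' @slot haplotypes integer matrix in \{0,1\}, founders x markers.
#' @slot markerMap data.frame: marker, chrom, bp (1-based, strictly
#'   increasing within chromosome).
#' @slot targetMaf numeric vector, per-marker target minor-allele frequency.
#' @seealso \code{\link{simulateFounderPanel}}, \code{\link{simulateHSGenomes}}
#' @export
setClass("FounderPanel",
         representation(haplotypes = "matrix", markerMap = "data.frame",
                        targetMaf = "numeric"))

setValidity("FounderPanel", function(object) {
    msg <- character()
    h <- object@haplotypes
    if (!all(h %in% c(0L, 1L))) msg <- c(msg, "allele codes must be 0/1")
    map <- object@markerMap
    if (ncol(h) != nrow(map)) {
        msg <- c(msg, "marker map must cover every haplotype column")
    }
    if (length(object@targetMaf) != ncol(h)) {
        msg <- c(msg, "targetMaf must have one entry per marker")
    }
    if (nrow(map)) {
        if (anyDuplicated(map$marker)) msg <- c(msg, "marker ids must be unique")
        bad <- vapply(split(map$bp, map$chrom),
                      function(p) any(diff(p) <= 0), logical(1))
        if (any(bad)) {
            msg <- c(msg,
                     "positions must be strictly increasing within chromosome")
        }
    }
    if (length(msg)) msg else TRUE
})

#' SelectionCurve: cumulative Mantel correlation under forward selection
#'
#' Markers are added in decreasing order of single-marker association and
#' the set-level Mantel correlation is recorded at each set size k. The
#' peak is the earliest entry into the plateau: the smallest k whose
#' cumulative correlation reaches (1 - plateauTol) of the curve maximum.
#'
#' @slot markers character, the included markers in selection order.
#' @slot stat numeric, cumulative Mantel correlation c_k at each k.
#' @slot pGate numeric, the per-marker permutation p-value gate used.
#' @slot plateauTol numeric, plateau tolerance used for the stored peak.
#' @slot peakK integer, selected set size k*.
#' @seealso \code{\link{cumulativeCurve}}, \code{\link{selectPeak}}
#' @export
setClass("SelectionCurve",
         representation(markers = "character", stat = "numeric",
                        pGate = "numeric", plateauTol = "numeric",
                        peakK = "integer"))

setValidity("SelectionCurve", function(object) {
    msg <- character()
    if (length(object@markers) != length(object@stat)) {
        msg <- c(msg, "one cumulative statistic per included marker required")
    }
    if (length(object@stat) &&
        (object@peakK < 1L || object@peakK > length(object@stat))) {
        msg <- c(msg, "peakK must index into the curve")
    }
    if (length(msg)) msg else TRUE
})

#' NullCurveEnsemble: label-shuffled empirical null for selection curves
#'
#' Each row is the cumulative-correlation curve obtained after shuffling
#' the genotype-phenotype sample link and re-running the entire procedure
#' (re-scan, re-gate, re-select). Curves shorter than the ensemble width
#' are right-padded by carrying their last value; shuffles with no
#' gate-passing markers contribute a flat zero curve.
#'
#' @slot curves numeric matrix, R shuffles x K set sizes.
#' @slot mu numeric, per-k null mean.
#' @slot sigma numeric, per-k null standard deviation (R - 1 divisor).
#' @slot seed numeric, master seed of the ensemble.
#' @slot params list, pipeline parameters the ensemble was built under.
#' @seealso \code{\link{nullEnsemble}}, \code{\link{zCurve}}
#' @export
setClass("NullCurveEnsemble",
         representation(curves = "matrix", mu = "numeric", sigma = "numeric",
                        seed = "numeric", params = "list"))

setValidity("NullCurveEnsemble", function(object) {
    msg <- character()
    if (nrow(object@curves) < 2L) {
        msg <- c(msg, "at least 2 shuffles are required for a null sd")
    }
    if (length(object@mu) != ncol(object@curves) ||
        length(object@sigma) != ncol(object@curves)) {
        msg <- c(msg, "mu and sigma must have one entry per set size")
    }
    if (length(msg)) msg else TRUE
})
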