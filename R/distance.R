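# Pairwise sample distance matrices. Both constructors return dense
# symmetric matrices with sample ids as dimnames and a zero diagonal;
# "source" and subset/category metadata travel in attributes. Dense N x N
# storage is deliberate: N at desk scale is at most a few thousand.

#' Genotype distance matrix over a marker subset
#'
#' Manhattan dosage distance \eqn{d(i,j) = \sum_m |g_i(m) - g_j(m)|}
#' (default) or identity-by-state mismatch count
#' \eqn{d(i,j) = \sum_m [g_i(m) \neq g_j(m)]}. Every marker receives equal
#' weight; dosages are not standardised. Manhattan distances are additive
#' over disjoint marker subsets, which the forward-selection code exploits.
#'
#' @param g a \linkS4class{GenotypeExperiment} without missing dosages.
#' @param markers marker ids to include (default: all).
#' @param metric \code{"manhattan"} or \code{"ibs"} (mismatch count).
#' @return symmetric numeric matrix with sample-id dimnames; attributes
#'   \code{source = "genotype"}, \code{markers}, \code{metric}.
#' @examples
#' d <- matrix(c(0, 2, 2, 0), 2, 2,
#'             dimnames = list(c("a", "b"), c("m1", "m2")))
#' map <- data.frame(marker = c("m1", "m2"), chrom = "chr1", bp = c(1, 2))
#' g <- makeGenotypes(d, map)
#' genotypeDistance(g)["a", "b"]   # 4
#' @export
genotypeDistance <- function(g, markers = markerIds(g),
                             metric = c("manhattan", "ibs")) {
    metric <- match.arg(metric)
    stopifnot(is(g, "GenotypeExperiment"))
    if (!length(markers)) stop("'markers' must be nonempty")
    unknown <- setdiff(markers, markerIds(g))
    if (length(unknown)) {
        stop("unknown marker id(s): ",
             paste(utils::head(unknown, 5), collapse = ", "))
    }
    d <- dosages(g)[, markers, drop = FALSE]
    if (anyNA(d)) stop("missing dosages; impute before computing distances")
    if (metric == "manhattan") {
        m <- as.matrix(stats::dist(d, method = "manhattan"))
    } else {
        idx <- .pairIndices(nrow(d))
        v <- rowSums(d[idx$i, , drop = FALSE] != d[idx$j, , drop = FALSE])
        m <- .squareFromPairs(v, rownames(d))
    }
    structure(m, source = "genotype", markers = markers, metric = metric)
}

#' Phenotype distance matrix for a composite category
#'
#' Manhattan distance over the vector of measures belonging to one
#' category. By default each measure is centred and scaled to unit
#' variance first, so measures on different scales contribute equally;
#' set \code{standardize = FALSE} for categories whose measures share a
#' unit. Zero-variance measures cannot be standardised and are dropped
#' with a warning.
#'
#' @param p a \linkS4class{PhenotypeTable}.
#' @param category a category name from \code{categories(p)}.
#' @param standardize centre/scale each measure first (default TRUE).
#' @param samples optional sample ids to restrict (and order) the matrix.
#' @return symmetric numeric matrix with sample-id dimnames; attributes
#'   \code{source = "phenotype"}, \code{category}.
#' @export
phenotypeDistance <- function(p, category, standardize = TRUE,
                              samples = NULL) {
    stopifnot(is(p, "PhenotypeTable"))
    meas <- categoryMeasures(p, category)
    v <- measureValues(p)[, meas, drop = FALSE]
    if (!is.null(samples)) {
        missing <- setdiff(samples, rownames(v))
        if (length(missing)) {
            stop("sample id(s) absent from phenotypes: ",
                 paste(utils::head(missing, 5), collapse = ", "))
        }
        v <- v[samples, , drop = FALSE]
    }
    if (anyNA(v)) stop("missing phenotype values in category ", category)
    if (standardize) {
        sds <- apply(v, 2L, stats::sd)
        if (any(sds == 0)) {
            warning("dropping zero-variance measure(s): ",
                    paste(colnames(v)[sds == 0], collapse = ", "))
            v <- v[, sds > 0, drop = FALSE]
            sds <- sds[sds > 0]
            if (!ncol(v)) stop("no measures left in category ", category)
        }
        v <- scale(v)
    }
    m <- as.matrix(stats::dist(v, method = "manhattan"))
    structure(m, source = "phenotype", category = category)
}

#' Write / read a distance matrix as TSV
#'
#' Square TSV with sample ids as both the header row and the first
#' column.
#' @param d symmetric distance matrix with sample-id dimnames.
#' @param path file path.
#' @export
writeDistanceMatrix <- function(d, path) {
    out <- data.frame(sample = rownames(d), d, check.names = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeDistanceMatrix
#' @export
readDistanceMatrix <- function(path) {
    tab <- utils::read.delim(path, check.names = FALSE)
    m <- as.matrix(tab[, -1L, drop = FALSE])
    rownames(m) <- tab$sample
    if (!identical(rownames(m), colnames(m))) {
        stop("row and column sample ids disagree: ", path)
    }
    m
}
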