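# Gene collection near reproducibly significant markers, and gene-set
# overrepresentation. Marker windows and gene bodies are 1-based inclusive
# intervals; interval arithmetic goes through IRanges/GenomicRanges.

#' Intersect marker sets detected under two conditions
#'
#' @param setA,setB character vectors of marker ids.
#' @return their exact intersection.
#' @export
intersectConditionMarkers <- function(setA, setB) {
    intersect(setA, setB)
}

#' Genes within a window of any marker
#'
#' A gene is collected iff it lies on the same chromosome as a marker and
#' its body \code{[start, end]} intersects the closed window
#' \code{[pos - windowBp, pos + windowBp]} (boundary-touching genes are
#' included). The default window of 1 Mb reflects the mapping resolution
#' of a heterogeneous-stock population.
#'
#' @param markers character vector of marker ids.
#' @param map marker map data.frame (marker, chrom, bp), e.g.
#'   \code{markerMap(g)}.
#' @param ann gene annotation data.frame (gene, chrom, start, end) from
#'   \code{\link{readGeneAnnotation}}.
#' @param windowBp window half-width in basepairs (default 1e6).
#' @param mode \code{"body"} (any gene-body overlap, default) or
#'   \code{"tss"} (distance measured to the gene start only).
#' @return character vector of gene ids (sorted, unique).
#' @export
genesNearMarkers <- function(markers, map, ann, windowBp = 1e6,
                             mode = c("body", "tss")) {
    mode <- match.arg(mode)
    if (!is.numeric(windowBp) || windowBp <= 0) {
        stop("'windowBp' must be positive")
    }
    missing <- setdiff(markers, map$marker)
    if (length(missing)) {
        stop("marker(s) absent from the map: ",
             paste(utils::head(missing, 5), collapse = ", "))
    }
    if (!length(markers)) return(character(0))
    mm <- map[match(markers, map$marker), , drop = FALSE]
    win <- GenomicRanges::GRanges(
        mm$chrom,
        IRanges::IRanges(start = pmax(1, mm$bp - windowBp),
                         end = mm$bp + windowBp))
    # "tss" collapses each gene to its start before the overlap test
    genes <- GenomicRanges::GRanges(
        ann$chrom,
        IRanges::IRanges(start = ann$start,
                         end = if (mode == "body") ann$end else ann$start))
    hits <- GenomicRanges::findOverlaps(genes, win)
    sort(unique(ann$gene[S4Vectors::queryHits(hits)]))
}

#' Hypergeometric gene-set overrepresentation
#'
#' One-sided hypergeometric upper-tail p-value per gene set (the classic
#' overrepresentation test), with Benjamini-Hochberg adjustment across the
#' collection. Sets are intersected with the universe before testing; the
#' query must be a subset of the universe.
#'
#' @param query character vector of gene ids (e.g. from
#'   \code{\link{genesNearMarkers}}), nonempty.
#' @param collection named list of gene sets (\code{\link{readGmt}}).
#' @param universe character vector of background gene ids. A sensible
#'   default is all annotated genes on chromosomes carrying at least one
#'   tested marker.
#' @return data.frame ordered by p: set, overlap, setSize, querySize,
#'   universeSize, p, q.
#' @export
enrich <- function(query, collection, universe) {
    if (!length(query)) stop("empty query gene set; nothing to test")
    query <- unique(query)
    universe <- unique(universe)
    if (!all(query %in% universe)) {
        stop("query contains gene(s) outside the universe")
    }
    if (!length(collection)) stop("empty gene-set collection")
    N <- length(universe)
    q <- length(query)
    rows <- lapply(names(collection), function(nm) {
        set <- intersect(collection[[nm]], universe)
        ov <- length(intersect(set, query))
        K <- length(set)
        p <- if (K == 0L) 1 else
            stats::phyper(ov - 1L, K, N - K, q, lower.tail = FALSE)
        data.frame(set = nm, overlap = ov, setSize = K, querySize = q,
                   universeSize = N, p = p)
    })
    out <- do.call(rbind, rows)
    out$q <- stats::p.adjust(out$p, method = "BH")
    out <- out[order(out$p, out$set), , drop = FALSE]
    rownames(out) <- NULL
    out
}
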