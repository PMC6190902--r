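# On-disk formats. Coordinates are 1-based inclusive throughout (marker bp
# and gene intervals); the gene annotation writer states this in a header
# comment. Readers validate and reject rather than silently coerce.

#' Read / write a genotype dosage matrix with its marker map
#'
#' The genotype file is TSV with a \code{sample} id column followed by one
#' column per marker holding dosages 0/1/2 (\code{NA} allowed only when
#' \code{missing = "impute"}). The marker map is TSV with columns
#' \code{marker}, \code{chrom}, \code{bp}, \code{ref}, \code{alt}.
#'
#' @param path genotype TSV path.
#' @param mapPath marker map TSV path.
#' @param missing policy for missing dosages: \code{"error"} (default)
#'   rejects the file, \code{"impute"} replaces each missing value with the
#'   marker's mean dosage (count reported via a message).
#' @return A \linkS4class{GenotypeExperiment}.
#' @export
readGenotypes <- function(path, mapPath, missing = c("error", "impute")) {
    missing <- match.arg(missing)
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    if (colnames(tab)[1L] != "sample") {
        stop("genotype file must start with a 'sample' column: ", path)
    }
    ids <- as.character(tab$sample)
    d <- as.matrix(tab[, -1L, drop = FALSE])
    storage.mode(d) <- "double"
    rownames(d) <- ids
    bad <- which(!(is.na(d) | d %in% c(0, 1, 2)), arr.ind = TRUE)
    if (nrow(bad)) {
        stop(sprintf("invalid dosage %s at sample '%s', marker '%s'",
                     format(d[bad[1L, , drop = FALSE]]),
                     ids[bad[1L, 1L]], colnames(d)[bad[1L, 2L]]))
    }
    nMissing <- sum(is.na(d))
    if (nMissing) {
        if (missing == "error") {
            stop(nMissing, " missing dosage value(s); re-read with ",
                 "missing = \"impute\" to mean-impute them")
        }
        mu <- colMeans(d, na.rm = TRUE)
        idx <- which(is.na(d), arr.ind = TRUE)
        d[idx] <- mu[idx[, 2L]]
        message("mean-imputed ", nMissing, " missing dosage value(s)")
    }
    map <- utils::read.delim(mapPath, stringsAsFactors = FALSE)
    absent <- setdiff(colnames(d), map$marker)
    if (length(absent)) {
        stop("marker(s) in matrix absent from map: ",
             paste(utils::head(absent, 5), collapse = ", "))
    }
    makeGenotypes(d, map)
}

#' @rdname readGenotypes
#' @param g a \linkS4class{GenotypeExperiment} to write.
#' @export
writeGenotypes <- function(g, path, mapPath) {
    d <- dosages(g)
    out <- data.frame(sample = rownames(d), d, check.names = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(markerMap(g), mapPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read / write a phenotype table with its measure-category map
#'
#' The phenotype file is CSV with a \code{sample} column followed by one
#' numeric column per measure; the category map is CSV with columns
#' \code{measure}, \code{category}. Every measure must be mapped.
#'
#' @param path phenotype CSV path.
#' @param categoryMapPath category map CSV path.
#' @return A \linkS4class{PhenotypeTable}.
#' @export
readPhenotypes <- function(path, categoryMapPath) {
    tab <- utils::read.csv(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
    if (colnames(tab)[1L] != "sample") {
        stop("phenotype file must start with a 'sample' column: ", path)
    }
    v <- as.matrix(tab[, -1L, drop = FALSE])
    storage.mode(v) <- "double"
    rownames(v) <- as.character(tab$sample)
    cm <- utils::read.csv(categoryMapPath, stringsAsFactors = FALSE)
    stopifnot(all(c("measure", "category") %in% colnames(cm)))
    unmapped <- setdiff(colnames(v), cm$measure)
    if (length(unmapped)) {
        stop("measure(s) without a category: ",
             paste(utils::head(unmapped, 5), collapse = ", "))
    }
    makePhenotypes(v, stats::setNames(cm$category, cm$measure))
}

#' @rdname readPhenotypes
#' @param p a \linkS4class{PhenotypeTable} to write.
#' @export
writePhenotypes <- function(p, path, categoryMapPath) {
    v <- measureValues(p)
    out <- data.frame(sample = rownames(v), v, check.names = FALSE)
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    cm <- categoryMap(p)
    utils::write.csv(data.frame(measure = names(cm), category = unname(cm)),
                     categoryMapPath, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read / write per-sample condition labels
#'
#' CSV with columns \code{sample}, \code{condition} and optionally
#' \code{cohort}.
#' @param path conditions CSV path.
#' @return data.frame of condition labels.
#' @export
readConditions <- function(path) {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("sample", "condition") %in% colnames(tab))) {
        stop("conditions file needs columns 'sample' and 'condition'")
    }
    tab
}

#' @rdname readConditions
#' @param conditions data.frame to write.
#' @export
writeConditions <- function(conditions, path) {
    utils::write.csv(conditions, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read / write a BED-like gene annotation
#'
#' Tab-delimited with columns \code{chrom}, \code{start}, \code{end},
#' \code{gene}; coordinates 1-based inclusive (stated in a header comment
#' on write). Rows with \code{start > end} or duplicated gene ids are
#' rejected.
#'
#' @param path annotation path.
#' @return data.frame with columns gene, chrom, start, end.
#' @export
readGeneAnnotation <- function(path) {
    tab <- utils::read.delim(path, comment.char = "#",
                             stringsAsFactors = FALSE)
    need <- c("chrom", "start", "end", "gene")
    if (!all(need %in% colnames(tab))) {
        stop("gene annotation needs columns chrom, start, end, gene")
    }
    bad <- which(tab$start > tab$end)
    if (length(bad)) {
        stop("gene interval with start > end at line ", bad[1L] + 1L,
             " ('", tab$gene[bad[1L]], "')")
    }
    if (anyDuplicated(tab$gene)) stop("duplicated gene ids in annotation")
    tab[, c("gene", "chrom", "start", "end")]
}

#' @rdname readGeneAnnotation
#' @param ann annotation data.frame to write.
#' @export
writeGeneAnnotation <- function(ann, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("# coordinates are 1-based inclusive", con)
    utils::write.table(ann[, c("chrom", "start", "end", "gene")], con,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read / write gene-set collections in GMT format
#'
#' Standard GMT: one set per line, \code{name TAB description TAB
#' member...}. Lines with fewer than three fields (no members) are
#' rejected with their line number.
#'
#' @param path GMT path.
#' @return named list of character vectors of gene ids; descriptions kept
#'   in the \code{"description"} attribute.
#' @export
readGmt <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    short <- which(vapply(fields, length, integer(1)) < 3L)
    if (length(short)) {
        stop("malformed GMT line ", short[1L],
             ": need name, description and at least one member")
    }
    sets <- lapply(fields, function(f) f[-(1:2)])
    names(sets) <- vapply(fields, `[[`, character(1), 1L)
    attr(sets, "description") <- vapply(fields, `[[`, character(1), 2L)
    sets
}

#' @rdname readGmt
#' @param sets named list of character vectors to write.
#' @export
writeGmt <- function(sets, path) {
    desc <- attr(sets, "description")
    if (is.null(desc)) desc <- rep("na", length(sets))
    lines <- vapply(seq_along(sets), function(i) {
        paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t")
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Read / write a ground-truth manifest (YAML)
#' @param truth ground-truth list from \code{\link{simulatePhenotypes}}.
#' @param path YAML path.
#' @export
writeGroundTruth <- function(truth, path) {
    yaml::write_yaml(truth, path)
    invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
    yaml::read_yaml(path)
}

#' Per-marker minor-allele frequency from dosages
#'
#' MAF = min(p, 1 - p) with p = (sum of dosages) / (2N); exact allele
#' counting, no missing values allowed.
#' @param g a \linkS4class{GenotypeExperiment}.
#' @return named numeric vector of MAFs.
#' @export
markerMAF <- function(g) {
    d <- SummarizedExperiment::assay(g, "dosage")
    if (anyNA(d)) stop("missing dosages; impute or filter first")
    p <- rowSums(d) / (2 * ncol(d))
    stats::setNames(pmin(p, 1 - p), rownames(g))
}

#' Filter markers by minor-allele frequency
#'
#' Retains markers whose MAF is strictly greater than the threshold
#' (a marker at exactly the threshold is excluded). The default 0.05
#' reflects the usual requirement of sufficient genetic diversity for
#' association scans.
#'
#' @param g a \linkS4class{GenotypeExperiment}.
#' @param threshold MAF threshold in [0, 0.5).
#' @return the filtered \linkS4class{GenotypeExperiment}; a message reports
#'   the number of markers removed.
#' @export
filterMarkersByMAF <- function(g, threshold = 0.05) {
    .assertFraction(threshold, "threshold", lo = 0, hi = 0.5, hi.open = TRUE)
    maf <- markerMAF(g)
    keep <- maf > threshold
    message(sum(!keep), " of ", length(keep),
            " markers removed at MAF threshold ", threshold)
    g[keep, ]
}

#' Align genotype, phenotype and condition tables by sample id
#'
#' Inner-joins the three inputs on sample id (never on row order) and
#' reports how many samples each input loses. At least two shared samples
#' are required for any downstream analysis.
#'
#' @param g a \linkS4class{GenotypeExperiment}.
#' @param pheno a \linkS4class{PhenotypeTable}.
#' @param conditions data.frame with a \code{sample} column, or NULL.
#' @return list with the three inputs restricted to the shared samples,
#'   in a common order.
#' @export
alignSamples <- function(g, pheno, conditions = NULL) {
    shared <- intersect(sampleIds(g), sampleIds(pheno))
    if (!is.null(conditions)) {
        shared <- intersect(shared, conditions$sample)
    }
    if (length(shared) < 2L) {
        stop("fewer than 2 samples shared across inputs")
    }
    drop <- c(genotypes = length(sampleIds(g)) - length(shared),
              phenotypes = length(sampleIds(pheno)) - length(shared),
              conditions = if (is.null(conditions)) 0L else
                  nrow(conditions) - length(shared))
    if (any(drop > 0)) {
        message("inner join on sample id dropped: ",
                paste(sprintf("%s %d", names(drop), drop), collapse = ", "))
    }
    list(genotypes = g[, shared],
         phenotypes = pheno[shared, ],
         conditions = if (is.null(conditions)) NULL else
             conditions[match(shared, conditions$sample), , drop = FALSE])
}

#' Write a simulated study to disk
#'
#' Writes genotypes + marker map (TSV), phenotypes + category map (CSV),
#' condition labels (CSV) and the ground-truth manifest (YAML) under a
#' directory, with fixed file names readable by the corresponding readers.
#' @param study list from \code{\link{simulateStudy}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of paths written.
#' @export
writeStudy <- function(study, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(genotypes = file.path(dir, "genotypes.tsv"),
               map = file.path(dir, "marker_map.tsv"),
               phenotypes = file.path(dir, "phenotypes.csv"),
               categories = file.path(dir, "category_map.csv"),
               conditions = file.path(dir, "conditions.csv"),
               truth = file.path(dir, "ground_truth.yaml"))
    writeGenotypes(study$genotypes, paths["genotypes"], paths["map"])
    writePhenotypes(study$phenotypes, paths["phenotypes"],
                    paths["categories"])
    writeConditions(study$conditions, paths["conditions"])
    writeGroundTruth(study$truth, paths["truth"])
    invisible(paths)
}
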