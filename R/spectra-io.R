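#' Construct a SpectrumSet
#'
#' Builds a [SpectrumSet-class] from an absorbance matrix in the analyst's
#' natural orientation (samples in rows, spectral points in columns). The
#' wavenumber grid may be supplied ascending or descending; it is stored
#' strictly descending (4000 down to 600 cm-1 by convention) and the columns
#' are reordered to match.
#'
#' @param absorbance numeric matrix, samples x spectral points.
#' @param wavenumbers numeric, one wavenumber (cm-1) per column of
#'   `absorbance`, strictly monotone.
#' @param sampleIds character, unique sample identifiers; defaults to
#'   `rownames(absorbance)`.
#' @param sampleData `DataFrame` or `data.frame` of per-sample metadata
#'   (site, variety, year, ...), one row per sample.
#'
#' @return A [SpectrumSet-class].
#' @examples
#' s <- SpectrumSet(matrix(runif(20), 2, 10), seq(600, 636, by = 4),
#'                  sampleIds = c("a", "b"))
#' wavenumbers(s)[1:3]
#' @export
SpectrumSet <- function(absorbance, wavenumbers,
                        sampleIds = rownames(absorbance),
                        sampleData = NULL) {
    absorbance <- as.matrix(absorbance)
    if (!is.numeric(absorbance))
        stop("'absorbance' must be a numeric matrix")
    wavenumbers <- as.numeric(wavenumbers)
    if (length(wavenumbers) != ncol(absorbance))
        stop("one wavenumber per absorbance column is required")
    d <- diff(wavenumbers)
    if (any(d == 0) || (any(d > 0) && any(d < 0)))
        stop("wavenumber grid must be strictly monotone")
    if (all(d > 0)) {                       # ascending input: store descending
        wavenumbers <- rev(wavenumbers)
        absorbance <- absorbance[, rev(seq_len(ncol(absorbance))), drop = FALSE]
    }
    if (is.null(sampleIds))
        sampleIds <- sprintf("sample_%03d", seq_len(nrow(absorbance)))
    sampleIds <- as.character(sampleIds)
    if (anyDuplicated(sampleIds))
        stop(sprintf("duplicated sample identifiers: %s",
                     paste(unique(sampleIds[duplicated(sampleIds)]),
                           collapse = ", ")))
    if (is.null(sampleData))
        sampleData <- DataFrame(row.names = sampleIds)
    else {
        sampleData <- as(sampleData, "DataFrame")
        rownames(sampleData) <- sampleIds
    }
    se <- SummarizedExperiment(
        assays = list(absorbance = t(unname(absorbance))),
        rowData = DataFrame(wavenumber = wavenumbers),
        colData = sampleData)
    colnames(se) <- sampleIds
    new("SpectrumSet", se)
}

#' Wavenumber grid of a SpectrumSet or PLSModel
#'
#' @param x a [SpectrumSet-class] or [PLSModel-class].
#' @return numeric vector of wavenumbers in cm-1, strictly descending.
#' @export
#' @name wavenumbers
setMethod("wavenumbers", "SpectrumSet", function(x) rowData(x)$wavenumber)

#' @rdname wavenumbers
setMethod("wavenumbers", "PLSModel", function(x) x@wavenumbers)

#' Absorbance matrix in samples-by-wavenumbers orientation
#'
#' @param x a [SpectrumSet-class].
#' @return numeric matrix, samples x spectral points, with sample ids as row
#'   names and formatted wavenumbers as column names.
#' @export
#' @name spectralMatrix
setMethod("spectralMatrix", "SpectrumSet", function(x) {
    m <- t(assay(x, "absorbance"))
    dimnames(m) <- list(colnames(x), format(rowData(x)$wavenumber,
                                            trim = TRUE, scientific = FALSE))
    m
})

#' Sample identifiers
#'
#' @param x a [SpectrumSet-class].
#' @return character vector of unique sample ids.
#' @export
#' @name sampleIds
setMethod("sampleIds", "SpectrumSet", function(x) colnames(x))

setMethod("show", "SpectrumSet", function(object) {
    wn <- wavenumbers(object)
    cat(sprintf("SpectrumSet: %d samples, %d spectral points\n",
                ncol(object), nrow(object)))
    cat(sprintf("  wavenumbers: %g .. %g cm-1 (descending)\n",
                wn[1], wn[length(wn)]))
    if (ncol(colData(object)))
        cat("  sample metadata:", paste(colnames(colData(object)),
                                        collapse = ", "), "\n")
    pp <- metadata(object)$preprocessing
    if (!is.null(pp) && length(pp))
        cat("  preprocessing:", paste(pp, collapse = " -> "), "\n")
    invisible(NULL)
})

## replace the absorbance matrix (samples x points), keeping grid/metadata
.setSpectralMatrix <- function(x, m) {
    stopifnot(nrow(m) == ncol(x), ncol(m) == nrow(x))
    assay(x, "absorbance", withDimnames = FALSE) <- t(unname(m))
    validObject(x)
    x
}

#' Read a wide-format spectral matrix from CSV
#'
#' The expected dialect is one header row `sample_id,<wn1>,<wn2>,...` whose
#' remaining header fields are wavenumbers in cm-1, then one row per sample.
#' The grid may be written ascending or descending; it is stored descending.
#'
#' @param path path to a CSV file (UTF-8, "." decimal separator).
#' @return A [SpectrumSet-class].
#' @seealso [writeSpectra()]
#' @export
readSpectra <- function(path) {
    df <- read.csv(path, check.names = FALSE, colClasses = "character")
    if (ncol(df) < 3L)
        stop("spectral CSV needs a sample_id column and at least 2 wavenumbers")
    wn <- suppressWarnings(as.numeric(colnames(df)[-1]))
    if (anyNA(wn))
        stop("header fields after sample_id must all be numeric wavenumbers")
    ids <- df[[1]]
    vals <- suppressWarnings(
        vapply(df[-1], as.numeric, numeric(nrow(df))))
    vals <- matrix(vals, nrow = nrow(df))
    if (anyNA(vals)) {
        bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
        stop(sprintf("non-numeric absorbance at row '%s', wavenumber %s",
                     ids[bad[1]], colnames(df)[-1][bad[2]]))
    }
    SpectrumSet(vals, wn, sampleIds = ids)
}

#' Write a SpectrumSet as a wide-format CSV
#'
#' Writes the dialect read by [readSpectra()] at full double precision
#' (~15 significant digits), grid in the stored descending order.
#'
#' @param x a [SpectrumSet-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSpectra <- function(x, path) {
    stopifnot(is(x, "SpectrumSet"))
    m <- t(assay(x, "absorbance"))
    df <- data.frame(sample_id = colnames(x), m, check.names = FALSE)
    colnames(df) <- c("sample_id",
                      format(wavenumbers(x), trim = TRUE, scientific = FALSE,
                             digits = 15))
    write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

## ---- response tables -------------------------------------------------------

.validateResponses <- function(df, replicates = NULL) {
    for (v in c("glucose", "xylose", "total")) {
        if (any(df[[v]] < 0))
            stop(sprintf("negative %s release for sample(s) %s", v,
                         paste(df$sample_id[df[[v]] < 0], collapse = ", ")))
        if (any(df[[v]] > 1))
            stop(sprintf("%s release above 1 g/g dm is not physical", v))
    }
    if (any(abs(df$total - (df$glucose + df$xylose)) > 1e-9))
        stop("total release must equal glucose + xylose")
    if (anyDuplicated(df$sample_id))
        stop(sprintf("duplicated sample identifiers: %s",
                     paste(unique(df$sample_id[duplicated(df$sample_id)]),
                           collapse = ", ")))
    if (!is.null(replicates)) {
        m <- unique(vapply(replicates, ncol, 0L))
        if (length(m) != 1L || m < 2L)
            stop("replicate tables need a constant number m >= 2 of replicates")
    }
    df
}

#' Read a sugar-release response table
#'
#' Expects columns `sample_id,glucose,xylose[,total][,replicate]` with
#' releases in g per g dry matter. When `total` is absent it is filled as
#' glucose + xylose; when present but inconsistent beyond 1e-6 it is
#' recomputed with a warning. When a `replicate` column is present, rows are
#' sample x laboratory replicate: the returned table holds per-sample
#' replicate means and the replicate-level values are attached for
#' laboratory-error (SDL) estimation, retrievable with
#' [responseReplicates()].
#'
#' @param path path to a CSV file.
#' @return A `data.frame` with columns `sample_id`, `glucose`, `xylose`,
#'   `total`, optionally carrying a `"replicates"` attribute (a named list
#'   of samples x replicates matrices).
#' @export
readResponses <- function(path) {
    df <- read.csv(path, check.names = FALSE)
    need <- c("sample_id", "glucose", "xylose")
    if (!all(need %in% colnames(df)))
        stop("response CSV needs columns sample_id, glucose, xylose")
    for (v in intersect(c("glucose", "xylose", "total"), colnames(df)))
        if (!is.numeric(df[[v]]))
            stop(sprintf("column '%s' must be numeric", v))
    hasTotal <- "total" %in% colnames(df)
    if (!hasTotal) df$total <- df$glucose + df$xylose
    else if (any(abs(df$total - (df$glucose + df$xylose)) > 1e-6)) {
        warning("'total' disagrees with glucose + xylose; recomputing")
        df$total <- df$glucose + df$xylose
    } else df$total <- df$glucose + df$xylose   # enforce exact identity
    if ("replicate" %in% colnames(df)) {
        ids <- unique(df$sample_id)
        m <- table(df$sample_id)
        if (length(unique(as.integer(m))) != 1L)
            stop("all samples must have the same number of replicates")
        reps <- lapply(c(glucose = "glucose", xylose = "xylose",
                         total = "total"), function(v) {
            t(vapply(ids, function(i) df[[v]][df$sample_id == i],
                     numeric(as.integer(m[1]))))
        })
        for (i in seq_along(reps)) rownames(reps[[i]]) <- ids
        main <- data.frame(
            sample_id = ids,
            glucose = rowMeans(reps$glucose),
            xylose = rowMeans(reps$xylose),
            row.names = NULL)
        main$total <- main$glucose + main$xylose
        main <- .validateResponses(main, reps)
        attr(main, "replicates") <- reps
        return(main)
    }
    .validateResponses(df[, c("sample_id", "glucose", "xylose", "total")])
}

#' Replicate-level response values
#'
#' @param x a response table as returned by [readResponses()] or
#'   [generateDataset()].
#' @return Named list of samples x replicates matrices (glucose, xylose,
#'   total), or `NULL` when no replicates are attached.
#' @export
responseReplicates <- function(x) attr(x, "replicates")

#' Interpolate a SpectrumSet onto a new wavenumber grid
#'
#' Linear interpolation per sample. The target grid must lie within the
#' source grid's range (no extrapolation) and is stored descending.
#'
#' @param x a [SpectrumSet-class].
#' @param targetGrid numeric, strictly monotone wavenumbers in cm-1.
#' @return A [SpectrumSet-class] on the new grid.
#' @export
regridSpectra <- function(x, targetGrid) {
    stopifnot(is(x, "SpectrumSet"))
    targetGrid <- as.numeric(targetGrid)
    d <- diff(targetGrid)
    if (length(targetGrid) < 2L || any(d == 0) || (any(d > 0) && any(d < 0)))
        stop("target grid must be strictly monotone with >= 2 points")
    if (all(d > 0)) targetGrid <- rev(targetGrid)
    src <- wavenumbers(x)
    if (max(targetGrid) > max(src) || min(targetGrid) < min(src))
        stop("target grid would require extrapolation; it must lie within ",
             sprintf("[%g, %g] cm-1", min(src), max(src)))
    m <- spectralMatrix(x)
    out <- t(apply(m, 1L, function(row)
        approx(x = src, y = row, xout = targetGrid)$y))
    SpectrumSet(out, targetGrid, sampleIds = colnames(x),
                sampleData = colData(x))
}
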