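#' SpectrumSet: absorbance spectra on a shared wavenumber grid
#'
#' An S4 container for a set of absorbance spectra measured on one common,
#' strictly descending wavenumber grid (conventional infrared plotting order,
#' high to low wavenumber). It extends
#' \link[SummarizedExperiment]{SummarizedExperiment}: rows are spectral
#' points (with the wavenumber in \code{rowData(x)$wavenumber}, cm-1),
#' columns are samples, and the single assay \code{"absorbance"} holds the
#' photoacoustic absorbance (dimensionless). Per-sample metadata (site,
#' variety, year, ...) lives in \code{colData}.
#'
#' Validity requires: a numeric, strictly descending wavenumber grid with at
#' least two points; all absorbance values finite; unique, non-empty sample
#' identifiers.
#'
#' @seealso [SpectrumSet()] for construction, [readSpectra()],
#'   [spectralMatrix()], [wavenumbers()]
#' @aliases SpectrumSet-class
#' @exportClass SpectrumSet
setClass("SpectrumSet", contains = "SummarizedExperiment")

setValidity("SpectrumSet", function(object) {
    msg <- character()
    if (!("absorbance" %in% assayNames(object)))
        msg <- c(msg, "assay 'absorbance' is required")
    wn <- rowData(object)$wavenumber
    if (is.null(wn) || !is.numeric(wn))
        msg <- c(msg, "rowData(x)$wavenumber must be numeric")
    else {
        if (length(wn) < 2L)
            msg <- c(msg, "at least 2 spectral points are required")
        if (anyNA(wn) || any(!is.finite(wn)))
            msg <- c(msg, "wavenumbers must be finite")
        else if (length(wn) >= 2L && any(diff(wn) >= 0))
            msg <- c(msg, "wavenumber grid must be strictly descending")
    }
    ids <- colnames(object)
    if (is.null(ids) || anyNA(ids) || any(!nzchar(ids)))
        msg <- c(msg, "sample identifiers (colnames) must be non-empty strings")
    else if (anyDuplicated(ids))
        msg <- c(msg, sprintf("duplicated sample identifiers: %s",
                              paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    if ("absorbance" %in% assayNames(object) &&
        any(!is.finite(assay(object, "absorbance"))))
        msg <- c(msg, "absorbance values must all be finite")
    if (length(msg)) msg else TRUE
})

#' PLSModel: a fitted PLS1 calibration
#'
#' Holds one univariate partial least squares regression fitted by NIPALS:
#' the weight matrix W and loading matrix P (fitted variables x factors),
#' response loadings q, the centering vectors, per-factor training score
#' variances (for Hotelling T2), and the regression-coefficient vector in
#' (preprocessed) absorbance space. Coefficients are stored on the full
#' wavenumber grid with zeros at variables excluded by variable selection,
#' so \code{yhat = yMean + (x - xMean) \%*\% coefficients} always holds.
#'
#' @slot nFactors integer, the number of latent factors F.
#' @slot weights,loadings matrices (n selected variables x F).
#' @slot yLoadings numeric length F.
#' @slot coefficients numeric, full-grid regression coefficients (zeros at
#'   unselected variables).
#' @slot xMean,yMean centering information from the training set.
#' @slot scoreVar numeric length F, variance of the training scores.
#' @slot nTrain integer, training-set size.
#' @slot selected logical mask over the full grid.
#' @slot wavenumbers numeric, the full training grid (descending, cm-1).
#' @slot responseName character, e.g. "total", "glucose" or "xylose".
#' @slot preprocessing character record of the preprocessing applied.
#'
#' @aliases PLSModel-class
#' @exportClass PLSModel
setClass("PLSModel", representation(
    nFactors      = "integer",
    weights       = "matrix",
    loadings      = "matrix",
    yLoadings     = "numeric",
    coefficients  = "numeric",
    xMean         = "numeric",
    yMean         = "numeric",
    scoreVar      = "numeric",
    nTrain        = "integer",
    selected      = "logical",
    wavenumbers   = "numeric",
    responseName  = "character",
    preprocessing = "character"
))

setValidity("PLSModel", function(object) {
    msg <- character()
    F <- object@nFactors
    p <- length(object@wavenumbers)
    if (length(F) != 1L || F < 1L) msg <- c(msg, "nFactors must be a single integer >= 1")
    if (ncol(object@weights) != F || ncol(object@loadings) != F ||
        length(object@yLoadings) != F || length(object@scoreVar) != F)
        msg <- c(msg, "weights/loadings/yLoadings/scoreVar must have F columns/entries")
    if (length(object@selected) != p || length(object@coefficients) != p ||
        length(object@xMean) != p)
        msg <- c(msg, "selected, coefficients and xMean must span the full grid")
    if (nrow(object@weights) != sum(object@selected))
        msg <- c(msg, "weights must have one row per selected variable")
    if (any(object@coefficients[!object@selected] != 0))
        msg <- c(msg, "coefficients must be zero at unselected variables")
    if (length(msg)) msg else TRUE
})

#' CVResult: segmented cross-validation of a PLS1 calibration
#'
#' Stores, for factor counts 1..maxFactors: the cross-validated RMSE and R2,
#' the out-of-segment predictions (samples x factor counts), the segment
#' assignment, and each segment submodel's full coefficient path (needed by
#' Martens' uncertainty test). Every sample is predicted exactly once, by
#' the submodel that did not see it.
#'
#' @slot rmsecv,r2cv numeric vectors over factor counts 1..maxFactors.
#' @slot predictions matrix (n samples x maxFactors) of out-of-segment
#'   predictions.
#' @slot segments integer vector, segment id per sample.
#' @slot segCoefficients list of matrices (n variables x maxFactors), the
#'   coefficient path of each segment's submodel.
#' @slot maxFactors,seed integers.
#'
#' @aliases CVResult-class
#' @exportClass CVResult
setClass("CVResult", representation(
    rmsecv          = "numeric",
    r2cv            = "numeric",
    predictions     = "matrix",
    segments        = "integer",
    segCoefficients = "list",
    maxFactors      = "integer",
    seed            = "integer"
))

setValidity("CVResult", function(object) {
    msg <- character()
    mF <- object@maxFactors
    if (length(object@rmsecv) != mF || length(object@r2cv) != mF)
        msg <- c(msg, "rmsecv and r2cv must have one entry per factor count")
    if (ncol(object@predictions) != mF)
        msg <- c(msg, "predictions must have maxFactors columns")
    if (nrow(object@predictions) != length(object@segments))
        msg <- c(msg, "one segment id per sample is required")
    M <- length(unique(object@segments))
    if (length(object@segCoefficients) != M)
        msg <- c(msg, "one coefficient path per segment is required")
    if (length(msg)) msg else TRUE
})
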