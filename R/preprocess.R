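## Savitzky-Golay machinery.
##
## For each output point a polynomial of degree `polyorder` is fitted by least
## squares to the surrounding `window` points and evaluated (or its derivative
## evaluated) at that point. At the boundaries the window is anchored at the
## edge and the fitted polynomial is evaluated off-center ("polynomial
## extension"), so the output has the same length as the input and no grid
## points are trimmed.

.sgCheck <- function(window, polyorder, derivOrder = 0L) {
    if (window %% 2L != 1L || window < 3L)
        stop("'window' must be an odd integer >= 3")
    if (polyorder < 0L || polyorder >= window)
        stop("'polyorder' must satisfy 0 <= polyorder < window")
    if (derivOrder < 0L || derivOrder > polyorder)
        stop("'derivOrder' must satisfy 0 <= derivOrder <= polyorder")
    invisible(NULL)
}

## coefficient rows: value (or derivative) of the window LS polynomial at
## offset e from the window center, as a linear functional of the window.
.sgCoef <- function(window, polyorder, derivOrder = 0L) {
    half <- (window - 1L) %/% 2L
    z <- seq.int(-half, half)
    V <- outer(z, 0:polyorder, `^`)
    A <- solve(crossprod(V), t(V))          # poly coefs <- window values
    evalRow <- function(e) {
        k <- 0:polyorder
        w <- numeric(polyorder + 1L)
        kk <- k[k >= derivOrder]
        w[k >= derivOrder] <- factorial(kk) / factorial(kk - derivOrder) *
            e^(kk - derivOrder)
        drop(w %*% A)
    }
    list(center = evalRow(0),
         edges = lapply(seq.int(-half, half), evalRow),  # index = e + half + 1
         half = half)
}

## apply the filter to a samples x points matrix laid out on an ascending,
## uniformly indexed axis; `delta` is the grid spacing used to scale
## derivatives into per-unit-wavenumber units.
.sgApply <- function(m, window, polyorder, derivOrder = 0L, delta = 1) {
    p <- ncol(m)
    if (window > p)
        stop("'window' exceeds the number of spectral points")
    cf <- .sgCoef(window, polyorder, derivOrder)
    half <- cf$half
    out <- matrix(0, nrow(m), p)
    interior <- (half + 1L):(p - half)
    for (j in seq_len(window)) {
        off <- j - half - 1L
        out[, interior] <- out[, interior] +
            cf$center[j] * m[, interior + off, drop = FALSE]
    }
    firstW <- m[, seq_len(window), drop = FALSE]
    lastW <- m[, (p - window + 1L):p, drop = FALSE]
    for (i in seq_len(half)) {
        out[, i] <- firstW %*% cf$edges[[i]]
        out[, p - half + i] <- lastW %*% cf$edges[[half + 1L + i]]
    }
    out / delta^derivOrder
}

## run f on the absorbance matrix in ascending-wavenumber orientation and
## restore the descending storage order
.onAscending <- function(x, f) {
    m <- spectralMatrix(x)
    rev_ <- rev(seq_len(ncol(m)))
    out <- f(m[, rev_, drop = FALSE])[, , drop = FALSE]
    .setSpectralMatrix(x, out[, rev_, drop = FALSE])
}

.recordStep <- function(x, label) {
    metadata(x)$preprocessing <- c(metadata(x)$preprocessing, label)
    x
}

#' Savitzky-Golay smoothing
#'
#' Replaces each spectrum by the value of a local least-squares polynomial
#' fit in a sliding window. The default (window 7, polynomial order 0) is a
#' seven-point moving average, the smoothing conventionally applied to
#' photoacoustic spectra at acquisition. Output length equals input length:
#' at the edges the window is anchored at the boundary and the fitted
#' polynomial evaluated off-center.
#'
#' @param x a [SpectrumSet-class].
#' @param window odd integer window width (points), `<=` the number of
#'   spectral points.
#' @param polyorder polynomial degree, `< window`.
#' @return A smoothed [SpectrumSet-class].
#' @export
#' @name sgSmooth
setMethod("sgSmooth", "SpectrumSet", function(x, window = 7L, polyorder = 0L) {
    .sgCheck(window, polyorder)
    out <- .onAscending(x, function(m) .sgApply(m, window, polyorder))
    .recordStep(out, sprintf("sg_smooth(window=%d,polyorder=%d)",
                             window, polyorder))
})

#' Savitzky-Golay derivative
#'
#' Differentiates each spectrum with respect to wavenumber via local
#' polynomial fits (default: second-order polynomial, seven points). The
#' derivative is taken on the ascending-wavenumber axis, so the sign is
#' physical (d absorbance / d wavenumber), then returned on the stored
#' descending grid. Requires a uniform grid; regrid first otherwise.
#' Units of the result: absorbance per cm-1 (per cm-1 squared for the
#' second derivative).
#'
#' @param x a [SpectrumSet-class].
#' @param window odd integer window width (points).
#' @param polyorder polynomial degree, `>= derivOrder`.
#' @param derivOrder 1 or 2.
#' @return A differentiated [SpectrumSet-class].
#' @export
#' @name sgDerivative
setMethod("sgDerivative", "SpectrumSet",
          function(x, window = 7L, polyorder = 2L, derivOrder = 1L) {
    .sgCheck(window, polyorder, derivOrder)
    if (!derivOrder %in% c(1L, 2L))
        stop("'derivOrder' must be 1 or 2")
    wn <- wavenumbers(x)
    d <- diff(wn)
    if (max(abs(d - d[1])) > 1e-6 * abs(d[1]))
        stop("derivatives need a uniform wavenumber grid; ",
             "use regridSpectra() first")
    delta <- abs(d[1])
    out <- .onAscending(x, function(m)
        .sgApply(m, window, polyorder, derivOrder, delta))
    .recordStep(out, sprintf(
        "sg_derivative(window=%d,polyorder=%d,derivOrder=%d)",
        window, polyorder, derivOrder))
})

#' Mean normalisation
#'
#' Divides each spectrum by its own mean absorbance, a multiplicative
#' scatter-style correction: every returned spectrum has mean exactly 1.
#' Spectra with (near-)zero mean are an error.
#'
#' @param x a [SpectrumSet-class].
#' @return A normalised [SpectrumSet-class].
#' @export
#' @name normalizeMean
setMethod("normalizeMean", "SpectrumSet", function(x) {
    m <- spectralMatrix(x)
    mu <- rowMeans(m)
    scale0 <- rowMeans(abs(m))
    if (any(scale0 == 0) || any(abs(mu) < 1e-12 * scale0))
        stop("cannot mean-normalise spectra with zero mean absorbance")
    out <- .setSpectralMatrix(x, m / mu)
    .recordStep(out, "normalize_mean")
})

#' Standard normal variate (SNV) transform
#'
#' Centers each spectrum to mean 0 and scales it to unit standard deviation
#' (n - 1 denominator); the classical scatter correction. Constant spectra
#' are an error.
#'
#' @param x a [SpectrumSet-class].
#' @return A transformed [SpectrumSet-class].
#' @export
#' @name snv
setMethod("snv", "SpectrumSet", function(x) {
    m <- spectralMatrix(x)
    mu <- rowMeans(m)
    s <- apply(m, 1L, sd)
    if (any(s == 0))
        stop("cannot SNV-transform a constant spectrum")
    out <- .setSpectralMatrix(x, (m - mu) / s)
    .recordStep(out, "snv")
})

#' The four standard preprocessing variants
#'
#' Returns the named step lists for the four pipelines compared in the
#' calibration study design: smoothing + mean normalisation
#' (`smooth_norm`), Savitzky-Golay first derivative (`sg1`), second
#' derivative (`sg2`), and smoothing + SNV (`smooth_snv`).
#'
#' @return Named list of preprocessing specifications for
#'   [applyPipeline()].
#' @examples
#' names(preprocessVariants())
#' @export
preprocessVariants <- function() {
    list(
        smooth_norm = list(
            list(step = "sg_smooth", window = 7L, polyorder = 0L),
            list(step = "normalize_mean")),
        sg1 = list(
            list(step = "sg_derivative", window = 7L, polyorder = 2L,
                 derivOrder = 1L)),
        sg2 = list(
            list(step = "sg_derivative", window = 7L, polyorder = 2L,
                 derivOrder = 2L)),
        smooth_snv = list(
            list(step = "sg_smooth", window = 7L, polyorder = 0L),
            list(step = "snv")))
}

#' Apply a preprocessing pipeline
#'
#' Applies an ordered list of preprocessing steps to a [SpectrumSet-class].
#' Each step is a list with a `step` element in `"sg_smooth"`,
#' `"sg_derivative"`, `"normalize_mean"`, `"snv"` plus that operator's
#' parameters; alternatively pass the name of one of the standard variants
#' (see [preprocessVariants()]). The applied steps are recorded in
#' `metadata(x)$preprocessing`.
#'
#' @param x a [SpectrumSet-class].
#' @param spec a non-empty list of steps, or a variant name.
#' @return The preprocessed [SpectrumSet-class].
#' @examples
#' s <- SpectrumSet(matrix(rexp(300) + 1, 3, 100), seq(600, 996, 4))
#' out <- applyPipeline(s, "smooth_norm")
#' metadata(out)$preprocessing
#' @export
applyPipeline <- function(x, spec) {
    if (is.character(spec) && length(spec) == 1L) {
        variants <- preprocessVariants()
        if (!spec %in% names(variants))
            stop("unknown preprocessing variant '", spec, "'; choose one of ",
                 paste(names(variants), collapse = ", "))
        spec <- variants[[spec]]
    }
    if (!is.list(spec) || length(spec) == 0L)
        stop("'spec' must be a non-empty list of preprocessing steps")
    for (st in spec) {
        if (is.null(st$step))
            stop("each step needs a 'step' name")
        x <- switch(st$step,
            sg_smooth = sgSmooth(x,
                window = st$window %||% 7L,
                polyorder = st$polyorder %||% 0L),
            sg_derivative = sgDerivative(x,
                window = st$window %||% 7L,
                polyorder = st$polyorder %||% 2L,
                derivOrder = st$derivOrder %||% 1L),
            normalize_mean = normalizeMean(x),
            snv = snv(x),
            stop("unknown preprocessing step '", st$step, "'"))
    }
    x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
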