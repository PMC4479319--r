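## NIPALS PLS1 core on a centered design. For a single response the NIPALS
## weight step is non-iterative: w = X'y (normalised), t = Xw, p = X't/t't,
## q = y't/t't, then X is deflated by t p'. Coefficients for any factor
## count F are b_F = W_F (P_F' W_F)^-1 q_F.
.plsNipals <- function(Xc, yc, ncomp) {
    n <- nrow(Xc); p <- ncol(Xc)
    if (ncomp < 1L) stop("'nFactors' must be >= 1")
    if (n <= ncomp) stop("need more samples than factors")
    W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
    q <- numeric(ncomp); Tm <- matrix(0, n, ncomp)
    Xd <- Xc
    w0 <- sqrt(sum(crossprod(Xc, yc)^2))
    if (w0 == 0) stop("response is uncorrelated with every variable")
    for (f in seq_len(ncomp)) {
        w <- crossprod(Xd, yc)
        nw <- sqrt(sum(w^2))
        if (nw < 1e-10 * w0)
            stop("factor count exceeds the effective rank of the predictors")
        w <- w / nw
        t <- Xd %*% w
        tt <- sum(t^2)
        if (tt < 1e-30)
            stop("factor count exceeds the effective rank of the predictors")
        pv <- crossprod(Xd, t) / tt
        q[f] <- sum(yc * t) / tt
        Xd <- Xd - tcrossprod(t, pv)
        W[, f] <- w; P[, f] <- pv; Tm[, f] <- t
    }
    list(W = W, P = P, q = q, T = Tm)
}

## coefficient path: p x ncomp matrix, column F = coefficients using factors 1..F
.plsCoefPath <- function(fit) {
    ncomp <- length(fit$q)
    PW <- crossprod(fit$P, fit$W)
    b <- matrix(0, nrow(fit$W), ncomp)
    for (f in seq_len(ncomp))
        b[, f] <- fit$W[, seq_len(f), drop = FALSE] %*%
            solve(PW[seq_len(f), seq_len(f), drop = FALSE],
                  fit$q[seq_len(f)])
    b
}

.asDesign <- function(x) {
    if (is(x, "SpectrumSet"))
        list(X = unname(spectralMatrix(x)), wn = wavenumbers(x),
             pp = metadata(x)$preprocessing %||% character())
    else if (is.matrix(x) && is.numeric(x)) {
        wn <- suppressWarnings(as.numeric(colnames(x)))
        if (is.null(colnames(x)) || anyNA(wn)) wn <- as.numeric(seq_len(ncol(x)))
        list(X = unname(x), wn = wn, pp = character())
    } else stop("'x' must be a SpectrumSet or a numeric matrix")
}

#' Fit a univariate PLS calibration (NIPALS PLS1)
#'
#' Fits a partial least squares regression with a single response by the
#' NIPALS algorithm with X-deflation. Centering of predictors and response
#' is done internally and stored in the model, so predictions are
#' `yMean + (x - xMean) %*% coefficients`.
#'
#' @param x a [SpectrumSet-class] or numeric matrix (samples x variables) of
#'   (preprocessed) absorbances; no non-finite values.
#' @param y numeric response, one value per sample (g/g dry matter for
#'   sugar-release work); must not be constant.
#' @param nFactors number of latent factors F (`>= 1`, less than the
#'   effective rank of the centered design).
#' @param responseName optional label ("total", "glucose", "xylose", ...).
#' @return A [PLSModel-class].
#' @examples
#' X <- matrix(rnorm(200), 20, 10)
#' y <- X[, 3] + rnorm(20, sd = 0.1)
#' m <- fitPLS1(X, y, nFactors = 2)
#' cor(predict(m, X), y)
#' @export
fitPLS1 <- function(x, y, nFactors, responseName = "") {
    d <- .asDesign(x)
    X <- d$X
    y <- as.numeric(y)
    if (length(y) != nrow(X)) stop("length(y) must equal the sample count")
    if (any(!is.finite(X)) || any(!is.finite(y)))
        stop("non-finite values in predictors or response")
    if (var(y) == 0) stop("response has zero variance")
    nFactors <- as.integer(nFactors)
    xm <- colMeans(X); ym <- mean(y)
    fit <- .plsNipals(sweep(X, 2L, xm), y - ym, nFactors)
    b <- .plsCoefPath(fit)[, nFactors]
    new("PLSModel",
        nFactors = nFactors, weights = fit$W, loadings = fit$P,
        yLoadings = fit$q, coefficients = b, xMean = xm, yMean = ym,
        scoreVar = apply(fit$T, 2L, var), nTrain = nrow(X),
        selected = rep(TRUE, ncol(X)), wavenumbers = d$wn,
        responseName = as.character(responseName), preprocessing = d$pp)
}

## refit on a variable subset, embedding results back onto the full grid
.fitSelected <- function(X, y, nFactors, selected, wn, responseName = "",
                         preprocessing = character()) {
    Xs <- X[, selected, drop = FALSE]
    xm <- colMeans(X); ym <- mean(y)
    fit <- .plsNipals(sweep(Xs, 2L, xm[selected]), y - ym, nFactors)
    bFull <- numeric(ncol(X))
    bFull[selected] <- .plsCoefPath(fit)[, nFactors]
    new("PLSModel",
        nFactors = as.integer(nFactors), weights = fit$W, loadings = fit$P,
        yLoadings = fit$q, coefficients = bFull, xMean = xm, yMean = ym,
        scoreVar = apply(fit$T, 2L, var), nTrain = nrow(X),
        selected = selected, wavenumbers = wn,
        responseName = as.character(responseName),
        preprocessing = preprocessing)
}

#' Predict from a PLSModel
#'
#' @param object a [PLSModel-class].
#' @param newdata a [SpectrumSet-class] on the training grid (and with the
#'   same preprocessing applied) or a numeric matrix with the training
#'   number of variables.
#' @return Numeric vector of predicted responses.
#' @export
setMethod("predict", "PLSModel", function(object, newdata) {
    if (is(newdata, "SpectrumSet")) {
        if (!isTRUE(all.equal(wavenumbers(newdata), object@wavenumbers)))
            stop("wavenumber grid of 'newdata' does not match the model")
        X <- unname(spectralMatrix(newdata))
    } else X <- as.matrix(newdata)
    if (ncol(X) != length(object@xMean))
        stop("'newdata' must have the model's number of variables")
    drop(object@yMean +
         sweep(X, 2L, object@xMean) %*% object@coefficients)
})

#' @describeIn fitPLS1 regression coefficients on the full grid (zeros at
#'   unselected variables).
#' @param object a [PLSModel-class].
#' @param ... unused.
#' @export
setMethod("coef", "PLSModel", function(object, ...) {
    setNames(object@coefficients,
             format(object@wavenumbers, trim = TRUE, scientific = FALSE))
})

#' Number of latent factors of a fitted model
#' @param x a [PLSModel-class].
#' @return integer.
#' @export
#' @name nFactors
setMethod("nFactors", "PLSModel", function(x) x@nFactors)

#' Variable-selection mask of a fitted model
#' @param x a [PLSModel-class].
#' @return logical vector over the full wavenumber grid.
#' @export
#' @name selectedVariables
setMethod("selectedVariables", "PLSModel", function(x) x@selected)

setMethod("show", "PLSModel", function(object) {
    cat(sprintf("PLSModel (%s): %d factor(s), %d/%d variables selected, n = %d\n",
                if (nzchar(object@responseName)) object@responseName else "?",
                object@nFactors, sum(object@selected),
                length(object@selected), object@nTrain))
    if (length(object@preprocessing))
        cat("  preprocessing:", paste(object@preprocessing, collapse = " -> "),
            "\n")
    invisible(NULL)
})

## seeded RNG scope: run f() under set.seed(seed) without disturbing the
## caller's RNG stream
.withSeed <- function(seed, f) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    f()
}

#' Segmented (leave-one-segment-out) cross-validation
#'
#' Shuffles the samples with a fixed seed, splits them into `nSegments`
#' contiguous blocks of as-equal-as-possible size (the classical "10
#' segments" design), and for each held-out segment fits PLS1 on the
#' remainder and predicts the segment for every factor count 1..`maxFactors`.
#' With `nSegments = n` this is leave-one-out. Bit-reproducible for a fixed
#' seed.
#'
#' @param x a [SpectrumSet-class] or numeric matrix (samples x variables).
#' @param y numeric response.
#' @param nSegments number of cross-validation segments (2..n).
#' @param maxFactors largest factor count evaluated; must be feasible for
#'   the smallest training fold.
#' @param seed integer seed for the segment shuffle.
#' @return A [CVResult-class].
#' @export
segmentedCV <- function(x, y, nSegments = 10L, maxFactors = 20L, seed = 1L) {
    d <- .asDesign(x)
    X <- d$X; y <- as.numeric(y)
    n <- nrow(X)
    nSegments <- as.integer(nSegments)
    maxFactors <- as.integer(maxFactors)
    if (length(y) != n) stop("length(y) must equal the sample count")
    if (nSegments < 2L || nSegments > n)
        stop("'nSegments' must be between 2 and the sample count")
    perm <- .withSeed(seed, function() sample.int(n))
    sizes <- rep(n %/% nSegments, nSegments)
    if (n %% nSegments) sizes[seq_len(n %% nSegments)] <-
        sizes[seq_len(n %% nSegments)] + 1L
    segOfPerm <- rep(seq_len(nSegments), times = sizes)
    segments <- integer(n)
    segments[perm] <- segOfPerm
    minTrain <- n - max(sizes)
    if (maxFactors >= minTrain || maxFactors > ncol(X))
        stop("'maxFactors' is too large for the smallest training fold")
    pred <- matrix(NA_real_, n, maxFactors)
    segCoef <- vector("list", nSegments)
    for (k in seq_len(nSegments)) {
        test <- segments == k
        Xtr <- X[!test, , drop = FALSE]; ytr <- y[!test]
        xm <- colMeans(Xtr); ym <- mean(ytr)
        fit <- .plsNipals(sweep(Xtr, 2L, xm), ytr - ym, maxFactors)
        bPath <- .plsCoefPath(fit)
        pred[test, ] <- ym +
            sweep(X[test, , drop = FALSE], 2L, xm) %*% bPath
        segCoef[[k]] <- bPath
    }
    resid2 <- (pred - y)^2
    rmsecv <- sqrt(colMeans(resid2))
    r2cv <- 1 - colSums(resid2) / sum((y - mean(y))^2)
    new("CVResult", rmsecv = rmsecv, r2cv = r2cv, predictions = pred,
        segments = segments, segCoefficients = segCoef,
        maxFactors = maxFactors, seed = as.integer(seed))
}

#' @describeIn segmentedCV cross-validated RMSE per factor count.
#' @param cv a [CVResult-class].
#' @export
rmsecv <- function(cv) cv@rmsecv

#' @describeIn segmentedCV cross-validated R2 per factor count.
#' @export
r2cv <- function(cv) cv@r2cv

setMethod("show", "CVResult", function(object) {
    best <- which.min(object@rmsecv)
    cat(sprintf(
        "CVResult: %d segments, factors 1..%d (min RMSECV %.4g at F = %d)\n",
        length(object@segCoefficients), object@maxFactors,
        object@rmsecv[best], best))
    invisible(NULL)
})

#' Parsimonious factor selection from cross-validation
#'
#' Returns the smallest factor count whose cross-validated RMSE is within
#' `tol` (relative) of the global minimum: near-ties are resolved in favour
#' of the simpler model.
#'
#' @param cv a [CVResult-class].
#' @param tol relative tolerance (default 0.02, i.e. within 2 percent of the
#'   minimum RMSECV).
#' @return integer factor count.
#' @export
selectFactors <- function(cv, tol = 0.02) {
    stopifnot(is(cv, "CVResult"))
    r <- cv@rmsecv
    which(r <= (1 + tol) * min(r))[1]
}

#' Martens' uncertainty test for variable selection
#'
#' Jackknife significance test on the PLS regression coefficients across the
#' cross-validation segment submodels. With M segments, full-model
#' coefficients b and segment coefficients b^(k) at factor count
#' `nFactors`, the jackknife variance per variable is
#' `s_j^2 = sum_k (b_j^(k) - b_j)^2 * (M - 1) / M`; variable j is kept when
#' `|b_j| / s_j` exceeds the two-sided t critical value at `alpha` with
#' M - 1 degrees of freedom (variables with zero jackknife variance and a
#' nonzero coefficient are always kept). The model is then refitted on the
#' kept variables only, at the same factor count unless rank forces fewer.
#'
#' @param x a [SpectrumSet-class] or numeric matrix used for `cv`.
#' @param y numeric response used for `cv`.
#' @param nFactors factor count at which to test (`<=` the CV `maxFactors`).
#' @param cv the [CVResult-class] from [segmentedCV()] on the same data.
#' @param alpha two-sided significance level (default 0.05).
#' @return A list with elements `selected` (logical mask), `model` (the
#'   refitted [PLSModel-class]), `tValues` (|b|/s, `Inf` where s = 0) and
#'   `tCritical`.
#' @export
martensUncertainty <- function(x, y, nFactors, cv, alpha = 0.05) {
    stopifnot(is(cv, "CVResult"))
    d <- .asDesign(x)
    X <- d$X; y <- as.numeric(y)
    nFactors <- as.integer(nFactors)
    if (nFactors > cv@maxFactors)
        stop("'nFactors' exceeds the factor counts available in 'cv'")
    if (nrow(X) != nrow(cv@predictions))
        stop("'x' does not match the data 'cv' was computed on")
    if (ncol(X) != nrow(cv@segCoefficients[[1]]))
        stop("'x' does not match the variables 'cv' was computed on")
    full <- fitPLS1(X, y, nFactors)
    b <- full@coefficients
    M <- length(cv@segCoefficients)
    bk <- vapply(cv@segCoefficients, function(m) m[, nFactors],
                 numeric(length(b)))
    s2 <- rowSums((bk - b)^2) * (M - 1) / M
    s <- sqrt(s2)
    tCrit <- qt(1 - alpha / 2, df = M - 1)
    tVal <- ifelse(s > 0, abs(b) / s, ifelse(b != 0, Inf, 0))
    keep <- tVal > tCrit
    if (!any(keep))
        stop("Martens' test rejected every variable; consider a larger alpha")
    F2 <- nFactors
    model <- NULL
    while (is.null(model) && F2 >= 1L) {
        model <- tryCatch(
            .fitSelected(X, y, F2, keep, d$wn,
                         responseName = full@responseName,
                         preprocessing = d$pp),
            error = function(e) NULL)
        if (is.null(model)) F2 <- F2 - 1L
    }
    if (is.null(model))
        stop("could not refit a model on the selected variables")
    list(selected = keep, model = model, tValues = tVal, tCritical = tCrit)
}
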