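#' Stratified calibration / external-validation split
#'
#' Allocates a fixed fraction of samples (default two thirds) to the
#' calibration set by seeded random sampling within strata (by default the
#' variety x site combination), so that the external validation set contains
#' samples from all varieties and sites. Every stratum with at least two
#' samples is represented in both sets whenever possible. Bit-reproducible
#' for a fixed seed.
#'
#' @param x a [SpectrumSet-class] whose `colData` carries the stratification
#'   columns.
#' @param frac calibration fraction in (0, 1); default 2/3.
#' @param seed integer seed.
#' @param stratifyBy character vector of `colData` columns, or `NULL` to
#'   disable stratification.
#' @return A list with character vectors `calibration` and `validation` of
#'   sample ids.
#' @export
splitCalibration <- function(x, frac = 2/3, seed = 1L,
                             stratifyBy = c("variety", "site")) {
    stopifnot(is(x, "SpectrumSet"))
    if (frac <= 0 || frac >= 1) stop("'frac' must lie in (0, 1)")
    ids <- sampleIds(x)
    if (is.null(stratifyBy) || !length(stratifyBy)) {
        strata <- rep("all", length(ids))
    } else {
        missing <- setdiff(stratifyBy, colnames(colData(x)))
        if (length(missing))
            stop("stratification column(s) missing from colData: ",
                 paste(missing, collapse = ", "))
        strata <- do.call(paste, c(lapply(stratifyBy, function(v)
            as.character(colData(x)[[v]])), sep = "\r"))
    }
    cal <- .withSeed(seed, function() {
        unlist(lapply(split(ids, strata), function(s) {
            n <- length(s)
            nCal <- round(frac * n)
            if (n >= 2L) nCal <- min(max(nCal, 1L), n - 1L)
            else nCal <- n
            s[sample.int(n, nCal)]
        }), use.names = FALSE)
    })
    list(calibration = ids[ids %in% cal],
         validation = ids[!ids %in% cal])
}

#' Coefficient of determination
#'
#' `R2 = 1 - sum((y - f)^2) / sum((y - mean(y))^2)`: the fraction of the
#' response variance explained by the predictions. Equals 1 for a perfect
#' fit and 0 for a predictor no better than the response mean.
#'
#' @param y observed values (length >= 2, non-constant).
#' @param f predicted values.
#' @return numeric scalar.
#' @examples
#' rSquared(c(1, 2, 3), c(1, 2, 4))  # 0.5
#' @export
rSquared <- function(y, f) {
    if (length(y) != length(f)) stop("'y' and 'f' must have equal length")
    if (length(y) < 2L) stop("need at least 2 observations")
    ssy <- sum((y - mean(y))^2)
    if (ssy == 0) stop("'y' has zero variance")
    1 - sum((y - f)^2) / ssy
}

#' Root-mean-square error
#'
#' `RMSE = sqrt(mean((f - y)^2))`, in the units of the response
#' (g/g dry matter for sugar release).
#'
#' @param y observed values.
#' @param f predicted values.
#' @return numeric scalar, `>= 0`.
#' @export
rmse <- function(y, f) {
    if (length(y) != length(f)) stop("'y' and 'f' must have equal length")
    if (!length(y)) stop("need at least 1 observation")
    sqrt(mean((f - y)^2))
}

#' Standard deviation of the laboratory method (SDL)
#'
#' Pooled replicate scatter of the reference assay, the floor on achievable
#' prediction error. For n samples with m laboratory replicates each and
#' per-sample replicate means ybar_j:
#' `SDL = sqrt( sum_j sum_i (y_ij - ybar_j)^2 / D )`.
#' The `"printed"` denominator is `D = m * n - 1` (the form conventionally
#' reported with this assay); `"pooled"` uses `D = n * (m - 1)`, the
#' degrees of freedom actually consumed by the per-sample means, which makes
#' the estimator consistent for the replicate noise standard deviation (the
#' printed form converges to `sigma * sqrt(n(m-1)/(mn-1))`, about 0.82 sigma
#' at m = 3).
#'
#' @param replicates numeric matrix, samples x replicates (m >= 2).
#' @param denominator `"printed"` (default) or `"pooled"`.
#' @return numeric scalar in the response units.
#' @examples
#' sdl(matrix(c(1, 2, 3), nrow = 1))              # sqrt(2/2) = 1
#' sdl(rbind(c(0, 2), c(10, 12)))                 # sqrt(4/3)
#' @export
sdl <- function(replicates, denominator = c("printed", "pooled")) {
    denominator <- match.arg(denominator)
    replicates <- as.matrix(replicates)
    n <- nrow(replicates); m <- ncol(replicates)
    if (m < 2L) stop("need at least m = 2 replicates per sample")
    if (any(!is.finite(replicates))) stop("replicate table must be complete")
    ss <- sum((replicates - rowMeans(replicates))^2)
    d <- if (denominator == "printed") m * n - 1 else n * (m - 1)
    sqrt(ss / d)
}

#' Ratio of external-validation RMSE to laboratory error
#'
#' The closer `RMSE_EV / SDL` is to 1, the closer the calibration's
#' prediction error is to the reproducibility floor of the reference assay.
#'
#' @param rmseEv external-validation RMSE.
#' @param sdl laboratory standard deviation, `> 0`.
#' @return numeric scalar.
#' @examples
#' rmseSdlRatio(0.030, 0.024)  # 1.25
#' @export
rmseSdlRatio <- function(rmseEv, sdl) {
    if (sdl <= 0) stop("'sdl' must be positive")
    rmseEv / sdl
}

.alignResponses <- function(responses, ids) {
    idx <- match(ids, responses$sample_id)
    if (anyNA(idx))
        stop("responses missing for sample(s): ",
             paste(ids[is.na(idx)], collapse = ", "))
    idx
}

#' Run the full calibration workflow for one response and preprocessing
#'
#' Convenience driver covering the complete pipeline: preprocess, split
#' into calibration and external-validation sets, screen calibration
#' outliers on the influence plot, select the factor count by segmented
#' cross-validation, optionally apply Martens' uncertainty variable
#' selection (with a post-selection cross-validation on the same segments
#' for honest CV figures), and evaluate the frozen model on the untouched
#' external-validation set.
#'
#' @param spectra a raw [SpectrumSet-class].
#' @param responses response table (see [readResponses()]); replicates, when
#'   attached, provide the SDL.
#' @param response `"total"`, `"glucose"` or `"xylose"`.
#' @param preprocess a variant name or step list for [applyPipeline()].
#' @param frac,stratifyBy,seed passed to [splitCalibration()].
#' @param nSegments,maxFactors passed to [segmentedCV()].
#' @param factorTol passed to [selectFactors()].
#' @param screen logical; screen calibration outliers before calibration.
#' @param screenFactors factor count of the screening model (default 5).
#' @param t2Quantile,qQuantile passed to [flagOutliers()].
#' @param exclude optional character vector of sample ids to drop from the
#'   calibration set up front (manual curation).
#' @param martens logical; apply Martens' uncertainty test.
#' @param alpha significance level for Martens' test.
#' @param postSelectionCV logical; recompute the cross-validation on the
#'   selected variables for the reported CV figures (slower, honest).
#' @param sdlDenominator passed to [sdl()].
#' @return A list with `report` (one-row `data.frame` with response,
#'   preprocessing, nFactors, R2/RMSE for CV and EV, SDL and RMSE_EV/SDL),
#'   `model`, `cv`, `selection`, `split`, `outliers`.
#' @export
runPipeline <- function(spectra, responses, response = "total",
                        preprocess = "smooth_norm", frac = 2/3, seed = 1L,
                        stratifyBy = c("variety", "site"),
                        nSegments = 10L, maxFactors = 20L, factorTol = 0.02,
                        screen = TRUE, screenFactors = 5L,
                        t2Quantile = 0.975, qQuantile = 0.975,
                        exclude = NULL, martens = TRUE, alpha = 0.05,
                        postSelectionCV = TRUE,
                        sdlDenominator = "printed") {
    stopifnot(is(spectra, "SpectrumSet"))
    if (!response %in% c("total", "glucose", "xylose"))
        stop("'response' must be one of total, glucose, xylose")
    pp <- applyPipeline(spectra, preprocess)
    ppLabel <- if (is.character(preprocess)) preprocess
               else paste(metadata(pp)$preprocessing, collapse = "+")
    split <- splitCalibration(pp, frac = frac, seed = seed,
                              stratifyBy = stratifyBy)
    calIds <- setdiff(split$calibration, exclude)
    X <- unname(spectralMatrix(pp))
    ids <- sampleIds(pp)
    y <- responses[[response]][.alignResponses(responses, ids)]
    calIdx <- match(calIds, ids)
    evIdx <- match(split$validation, ids)
    Xcal <- X[calIdx, , drop = FALSE]; ycal <- y[calIdx]

    outliers <- NULL
    if (screen) {
        sm <- fitPLS1(Xcal, ycal, min(screenFactors, maxFactors))
        st <- influenceStats(sm, Xcal)
        st$sample_id <- calIds
        outliers <- flagOutliers(st, t2Quantile, qQuantile)
        keep <- !outliers$flagged
        Xcal <- Xcal[keep, , drop = FALSE]; ycal <- ycal[keep]
        calIds <- calIds[keep]
    }

    cv <- segmentedCV(Xcal, ycal, nSegments = nSegments,
                      maxFactors = maxFactors, seed = seed)
    F <- selectFactors(cv, tol = factorTol)

    if (martens) {
        sel <- martensUncertainty(Xcal, ycal, F, cv, alpha = alpha)
        model <- sel$model
        model@wavenumbers <- wavenumbers(pp)
        model@responseName <- response
        model@preprocessing <- metadata(pp)$preprocessing %||% character()
        if (postSelectionCV) {
            cvSel <- segmentedCV(Xcal[, sel$selected, drop = FALSE], ycal,
                                 nSegments = nSegments,
                                 maxFactors = model@nFactors, seed = seed)
            r2CV <- cvSel@r2cv[model@nFactors]
            rmseCV <- cvSel@rmsecv[model@nFactors]
        } else {
            r2CV <- cv@r2cv[F]
            rmseCV <- cv@rmsecv[F]
        }
    } else {
        sel <- NULL
        model <- fitPLS1(Xcal, ycal, F, responseName = response)
        model@wavenumbers <- wavenumbers(pp)
        model@preprocessing <- metadata(pp)$preprocessing %||% character()
        r2CV <- cv@r2cv[F]
        rmseCV <- cv@rmsecv[F]
    }

    yhatEv <- predict(model, X[evIdx, , drop = FALSE])
    yEv <- y[evIdx]
    reps <- responseReplicates(responses)
    sdlVal <- if (!is.null(reps))
        sdl(reps[[response]], denominator = sdlDenominator) else NA_real_
    report <- data.frame(
        response = response, preprocessing = ppLabel,
        nFactors = model@nFactors,
        R2_CV = r2CV, R2_EV = rSquared(yEv, yhatEv),
        RMSE_CV = rmseCV, RMSE_EV = rmse(yEv, yhatEv),
        SDL = sdlVal,
        RMSE_EV_SDL = if (is.na(sdlVal)) NA_real_
                      else rmseSdlRatio(rmse(yEv, yhatEv), sdlVal),
        n_calibration = length(ycal), n_validation = length(yEv),
        n_outliers_removed = if (is.null(outliers)) 0L
                             else attr(outliers, "nFlagged"),
        stringsAsFactors = FALSE)
    list(report = report, model = model, cv = cv, selection = sel,
         split = split, outliers = outliers)
}

#' Figures of merit across responses and preprocessing variants
#'
#' Runs [runPipeline()] for every combination of the requested responses and
#' preprocessing variants on one shared split, returning one row per
#' combination (R2 and RMSE for cross-validation and external validation,
#' factor count, SDL and RMSE_EV/SDL).
#'
#' @param spectra a raw [SpectrumSet-class].
#' @param responses response table.
#' @param variants character vector of variant names (see
#'   [preprocessVariants()]).
#' @param responseNames character vector among total, glucose, xylose.
#' @param ... further arguments passed to [runPipeline()].
#' @return A `data.frame`, one row per response x variant.
#' @export
buildReport <- function(spectra, responses,
                        variants = names(preprocessVariants()),
                        responseNames = c("total", "glucose", "xylose"),
                        ...) {
    rows <- lapply(responseNames, function(resp)
        lapply(variants, function(v)
            runPipeline(spectra, responses, response = resp,
                        preprocess = v, ...)$report))
    do.call(rbind, unlist(rows, recursive = FALSE))
}
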