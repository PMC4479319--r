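#' Influence statistics (Hotelling T2 and Q residuals)
#'
#' Projects samples into a fitted model's score space and returns, per
#' sample, the Hotelling T2 statistic over the F score dimensions
#' (`sum_f t_f^2 / var(t_f)`, with training score variances) and the
#' Q residual (squared norm of the part of the centered spectrum left
#' unexplained by the loadings). Together they form the classical
#' influence plot used to locate calibration outliers: T2 captures extreme
#' but in-model samples, Q captures samples off the model plane.
#'
#' @param model a [PLSModel-class].
#' @param x a [SpectrumSet-class] or numeric matrix on the model's grid
#'   (same preprocessing as training).
#' @return A `data.frame` with columns `sample_id`, `T2`, `Q` and, as
#'   attributes, the model's factor count and training size (used by
#'   [flagOutliers()]).
#' @export
influenceStats <- function(model, x) {
    stopifnot(is(model, "PLSModel"))
    if (is(x, "SpectrumSet")) {
        if (!isTRUE(all.equal(wavenumbers(x), model@wavenumbers)))
            stop("wavenumber grid of 'x' does not match the model")
        X <- unname(spectralMatrix(x))
        ids <- sampleIds(x)
    } else {
        X <- as.matrix(x)
        ids <- rownames(X) %||% sprintf("sample_%03d", seq_len(nrow(X)))
    }
    if (ncol(X) != length(model@xMean))
        stop("'x' must have the model's number of variables")
    sel <- model@selected
    Xc <- sweep(X, 2L, model@xMean)[, sel, drop = FALSE]
    PW <- crossprod(model@loadings, model@weights)
    R <- model@weights %*% solve(PW)
    Tm <- Xc %*% R
    v <- model@scoreVar
    T2 <- rowSums(sweep(Tm^2, 2L, ifelse(v > 0, v, Inf), `/`))
    Q <- rowSums((Xc - tcrossprod(Tm, model@loadings))^2)
    out <- data.frame(sample_id = ids, T2 = T2, Q = Q, row.names = NULL)
    attr(out, "nFactors") <- model@nFactors
    attr(out, "nTrain") <- model@nTrain
    out
}

#' Flag calibration outliers from the influence plot
#'
#' Flags a sample when its Hotelling T2 exceeds the F-distribution-based
#' Hotelling limit at `t2Quantile`, or its Q residual exceeds the empirical
#' `qQuantile` of the supplied (training) Q values. The T2 limit for F
#' factors fitted on n training samples is
#' `F (n - 1)(n + 1) / (n (n - F)) * qf(t2Quantile, F, n - F)`. Degenerate
#' inputs with zero spread (all T2 and Q equal 0) yield no flags. The flag
#' count is non-increasing in both quantiles; at quantile 1 nothing is
#' flagged.
#'
#' @param stats the `data.frame` from [influenceStats()] on the training
#'   set.
#' @param t2Quantile,qQuantile probability levels (default 0.975).
#' @return The input `data.frame` with an added logical `flagged` column
#'   and attributes `t2Critical`, `qCritical`, `nFlagged`.
#' @export
flagOutliers <- function(stats, t2Quantile = 0.975, qQuantile = 0.975) {
    stopifnot(is.data.frame(stats), all(c("T2", "Q") %in% colnames(stats)))
    if (t2Quantile <= 0 || t2Quantile > 1 || qQuantile <= 0 || qQuantile > 1)
        stop("quantiles must lie in (0, 1]")
    F <- attr(stats, "nFactors")
    n <- attr(stats, "nTrain")
    if (is.null(F) || is.null(n))
        stop("'stats' must come from influenceStats()")
    if (all(stats$T2 == 0) && all(stats$Q == 0)) {
        stats$flagged <- FALSE
        attr(stats, "t2Critical") <- 0
        attr(stats, "qCritical") <- 0
        attr(stats, "nFlagged") <- 0L
        return(stats)
    }
    t2Crit <- if (t2Quantile == 1) Inf
              else F * (n - 1) * (n + 1) / (n * (n - F)) *
                   qf(t2Quantile, F, n - F)
    qCrit <- unname(quantile(stats$Q, qQuantile))
    stats$flagged <- stats$T2 > t2Crit | stats$Q > qCrit
    attr(stats, "t2Critical") <- t2Crit
    attr(stats, "qCritical") <- qCrit
    attr(stats, "nFlagged") <- sum(stats$flagged)
    stats
}
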