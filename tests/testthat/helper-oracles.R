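## Shared fixtures and independent oracles for the test suite. Everything here
## is deliberately implemented differently from the package code paths it
## checks.

randomSpectra <- function(n = 10, p = 50, seed = 1, wnFrom = 600, step = 4,
                          positive = FALSE) {
    set.seed(seed)
    m <- matrix(rnorm(n * p), n)
    if (positive) m <- abs(m) + 0.5
    SpectrumSet(m, seq(wnFrom, by = step, length.out = p),
                sampleIds = sprintf("s%02d", seq_len(n)))
}

## brute-force Savitzky-Golay: explicit least-squares polynomial fit in every
## window, evaluated (or differentiated) at the output point; windows anchored
## at the boundaries
sgOracle <- function(y, window, polyorder, deriv = 0, delta = 1) {
    p <- length(y)
    half <- (window - 1) %/% 2
    out <- numeric(p)
    for (i in seq_len(p)) {
        lo <- min(max(1, i - half), p - window + 1)
        idx <- lo:(lo + window - 1)
        z <- idx - i                     # offsets from evaluation point
        fit <- qr.solve(outer(z, 0:polyorder, `^`), y[idx])
        out[i] <- if (deriv == 0) fit[1] else factorial(deriv) * fit[deriv + 1]
    }
    out / delta^deriv
}

## independent PLS1: the coefficient vector with F factors lies in the Krylov
## space span{s, Ms, ..., M^(F-1) s} with M = X'X, s = X'y, and equals the
## least-squares solution in that basis
plsKrylov <- function(X, y, F) {
    xm <- colMeans(X); ym <- mean(y)
    Xc <- sweep(X, 2, xm); yc <- y - ym
    M <- crossprod(Xc); s <- crossprod(Xc, yc)
    K <- matrix(0, ncol(X), F)
    v <- s
    for (f in seq_len(F)) { K[, f] <- v; v <- M %*% v }
    K <- qr.Q(qr(K))
    b <- drop(K %*% solve(crossprod(K, M %*% K), crossprod(K, s)))
    list(b = b, xMean = xm, yMean = ym,
         predict = function(Xn) ym + drop(sweep(Xn, 2, xm) %*% b))
}

olsCoef <- function(X, y) {
    Xc <- sweep(X, 2, colMeans(X))
    drop(solve(crossprod(Xc), crossprod(Xc, y - mean(y))))
}

## a PLSModel with prescribed full-grid coefficients, for annotation tests
makeCoefModel <- function(b, wn) {
    p <- length(wn)
    new("PLSModel", nFactors = 1L, weights = matrix(0, p, 1),
        loadings = matrix(0, p, 1), yLoadings = 0, coefficients = b,
        xMean = numeric(p), yMean = 0, scoreVar = 1, nTrain = 10L,
        selected = rep(TRUE, p), wavenumbers = wn, responseName = "",
        preprocessing = character())
}

## small latent-structure design for Martens' test simulations: 50 informative
## variables driven by 3 latent factors, 200 pure-noise variables. Loadings
## are bounded away from zero so every "informative" variable genuinely
## carries signal (a variable whose true coefficient is ~0 is not
## informative, whatever list it sits on).
martensDesign <- function(seed, n = 200) {
    set.seed(seed)
    Tm <- matrix(rnorm(n * 3), n)
    L <- matrix(sample(c(-1, 1), 150, replace = TRUE) *
                    runif(150, 0.5, 1.5), 3)
    X <- cbind(Tm %*% L + 0.2 * matrix(rnorm(n * 50), n),
               matrix(rnorm(n * 200), n))
    y <- rowSums(Tm) + 0.2 * rnorm(n)
    list(X = X, y = y, informative = 1:50, noise = 51:250)
}

writeTempCsv <- function(lines) {
    path <- tempfile(fileext = ".csv")
    writeLines(lines, path)
    path
}
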