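test_that("Savitzky-Golay smoothing preserves what it should", {
    const <- SpectrumSet(matrix(7, 2, 30), seq(600, by = 4, length.out = 30),
                         sampleIds = c("a", "b"))
    expect_equal(unname(spectralMatrix(sgSmooth(const))),
                 matrix(7, 2, 30))
    ## a ramp is invariant under a symmetric moving average (all points, since
    ## boundary windows fit the linear signal exactly with any polyorder >= 1;
    ## with polyorder 0 the interior is exact)
    wn <- seq(600, by = 4, length.out = 50)
    ramp <- SpectrumSet(matrix(seq_len(50), 1), wn, sampleIds = "r")
    sm <- spectralMatrix(sgSmooth(ramp, 7, 0))
    expect_equal(unname(sm[1, 4:47]), unname(spectralMatrix(ramp)[1, 4:47]))
    ## polyorder = window - 1 interpolates: identity everywhere
    r2 <- randomSpectra(2, 40, seed = 2)
    expect_equal(spectralMatrix(sgSmooth(r2, 7, 6)), spectralMatrix(r2),
                 tolerance = 1e-8)
})

test_that("Savitzky-Golay operators match the brute-force window-fit oracle", {
    set.seed(21)
    wn <- seq(600, by = 4, length.out = 100)
    for (cfg in list(c(7, 0, 0), c(7, 2, 0), c(9, 3, 0),
                     c(7, 2, 1), c(7, 2, 2), c(9, 3, 2))) {
        y <- rnorm(100)
        s <- SpectrumSet(matrix(y, 1), wn, sampleIds = "x")
        got <- if (cfg[3] == 0) sgSmooth(s, cfg[1], cfg[2])
               else sgDerivative(s, cfg[1], cfg[2], cfg[3])
        want <- sgOracle(y, cfg[1], cfg[2], cfg[3], delta = 4)
        expect_lt(max(abs(spectralMatrix(got)[1, ] - rev(want))), 1e-8,
                  label = paste("config", paste(cfg, collapse = "/")))
    }
})

test_that("derivatives have physical sign, units and exactness on polynomials", {
    wn <- seq(600, by = 4, length.out = 80)
    quad <- SpectrumSet(matrix((wn / 100)^2, 1), wn, sampleIds = "q")
    d2 <- spectralMatrix(sgDerivative(quad, 7, 2, 2))
    expect_equal(unname(d2[1, ]), rep(2 / 100^2, 80), tolerance = 1e-10)
    lin <- SpectrumSet(matrix(0.3 * wn - 5, 1), wn, sampleIds = "l")
    d1 <- spectralMatrix(sgDerivative(lin, 7, 2, 1))
    expect_equal(unname(d1[1, ]), rep(0.3, 80), tolerance = 1e-10)
    ## order 1 annihilates constants, order 2 annihilates affine spectra
    aff <- SpectrumSet(matrix(c(rep(2, 80), 0.1 * wn + 1), 2, byrow = TRUE),
                       wn, sampleIds = c("c", "a"))
    expect_lt(max(abs(spectralMatrix(sgDerivative(aff, 7, 2, 1))[1, ])), 1e-10)
    expect_lt(max(abs(spectralMatrix(sgDerivative(aff, 7, 2, 2)))), 1e-10)
    ## non-uniform grids are refused with advice
    bumpy <- SpectrumSet(matrix(rnorm(20), 1),
                         c(seq(600, 660, by = 4), seq(670, 700, by = 10)),
                         sampleIds = "b")
    expect_error(sgDerivative(bumpy), "regrid")
})

test_that("sgolayfilt agrees with the interior of our Savitzky-Golay filters", {
    skip_if_not_installed("signal")
    set.seed(33)
    y <- rnorm(120)
    wn <- seq(600, by = 4, length.out = 120)
    s <- SpectrumSet(matrix(y, 1), wn, sampleIds = "x")
    ours <- rev(spectralMatrix(sgSmooth(s, 9, 2))[1, ])
    ref <- signal::sgolayfilt(y, p = 2, n = 9)
    expect_lt(max(abs(ours[5:116] - ref[5:116])), 1e-10)
})

test_that("mean normalisation scales spectra to unit mean", {
    s <- SpectrumSet(matrix(c(2, 4, 6), 1), c(608, 604, 600),
                     sampleIds = "a")
    expect_equal(unname(spectralMatrix(normalizeMean(s))[1, ]),
                 c(0.5, 1, 1.5))
    r <- randomSpectra(5, 40, seed = 4, positive = TRUE)
    nm <- normalizeMean(r)
    expect_equal(unname(rowMeans(spectralMatrix(nm))), rep(1, 5))
    expect_equal(spectralMatrix(normalizeMean(nm)), spectralMatrix(nm))
    ## scale invariance
    sc <- SpectrumSet(3.7 * spectralMatrix(r), wavenumbers(r),
                      sampleIds = sampleIds(r))
    expect_equal(spectralMatrix(normalizeMean(sc)), spectralMatrix(nm),
                 tolerance = 1e-12)
    zero <- SpectrumSet(matrix(c(-1, 0, 1), 1), c(608, 604, 600),
                        sampleIds = "z")
    expect_error(normalizeMean(zero), "zero mean")
})

test_that("SNV centers and scales each spectrum", {
    s <- SpectrumSet(matrix(1:3, 1), c(608, 604, 600), sampleIds = "a")
    expect_equal(unname(spectralMatrix(snv(s))[1, ]), c(-1, 0, 1))
    r <- randomSpectra(6, 50, seed = 8)
    out <- spectralMatrix(snv(r))
    expect_lt(max(abs(rowMeans(out))), 1e-12)
    expect_equal(unname(apply(out, 1, sd)), rep(1, 6), tolerance = 1e-12)
    ## affine invariance: snv(a x + b) = snv(x) for a > 0
    aff <- SpectrumSet(2.5 * spectralMatrix(r) - 7, wavenumbers(r),
                       sampleIds = sampleIds(r))
    expect_equal(spectralMatrix(snv(aff)), out, tolerance = 1e-10)
    const <- SpectrumSet(matrix(4, 1, 10), seq(600, by = 4, length.out = 10),
                         sampleIds = "c")
    expect_error(snv(const), "constant")
})

test_that("pipelines compose operators in order and record provenance", {
    expect_error(applyPipeline(randomSpectra(), list()), "non-empty")
    expect_error(applyPipeline(randomSpectra(), "nope"), "unknown")
    const <- SpectrumSet(matrix(5, 2, 30), seq(600, by = 4, length.out = 30),
                         sampleIds = c("a", "b"))
    out <- applyPipeline(const, "smooth_norm")
    expect_equal(unname(spectralMatrix(out)), matrix(1, 2, 30))
    r <- randomSpectra(4, 60, seed = 13, positive = TRUE)
    expect_equal(spectralMatrix(applyPipeline(r, "smooth_snv")),
                 spectralMatrix(snv(sgSmooth(r, 7, 0))))
    expect_equal(spectralMatrix(applyPipeline(r, "sg1")),
                 spectralMatrix(sgDerivative(r, 7, 2, 1)))
    expect_identical(metadata(applyPipeline(r, "smooth_norm"))$preprocessing,
                     c("sg_smooth(window=7,polyorder=0)", "normalize_mean"))
})

test_that("all operators are row-local: permuting samples commutes", {
    r <- randomSpectra(6, 50, seed = 17, positive = TRUE)
    perm <- c(4, 1, 6, 2, 5, 3)
    rp <- SpectrumSet(spectralMatrix(r)[perm, ], wavenumbers(r),
                      sampleIds = sampleIds(r)[perm])
    for (op in list(function(x) sgSmooth(x), function(x) sgDerivative(x),
                    normalizeMean, snv)) {
        expect_equal(unname(spectralMatrix(op(rp))),
                     unname(spectralMatrix(op(r))[perm, ]),
                     tolerance = 1e-12)
    }
})

test_that("window and polyorder preconditions are enforced", {
    r <- randomSpectra(2, 20, seed = 1)
    expect_error(sgSmooth(r, 6), "odd")
    expect_error(sgSmooth(r, 7, 7), "polyorder")
    expect_error(sgSmooth(r, 21), "exceeds")
    expect_error(sgDerivative(r, 7, 1, 2), "derivOrder")
})
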