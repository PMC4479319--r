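test_that("stratified splitting keeps every stratum in both sets", {
    s <- SpectrumSet(matrix(rnorm(9 * 10), 9),
                     seq(600, by = 4, length.out = 10),
                     sampleIds = sprintf("s%d", 1:9),
                     sampleData = data.frame(
                         variety = rep(c("v1", "v2", "v3"), each = 3),
                         site = "x"))
    sp <- splitCalibration(s, frac = 2/3, seed = 1)
    expect_length(sp$calibration, 6)
    expect_length(sp$validation, 3)
    vEv <- colData(s)[sp$validation, "variety"]
    expect_setequal(vEv, c("v1", "v2", "v3"))
    sp2 <- splitCalibration(s, frac = 2/3, seed = 1)
    expect_identical(sp, sp2)
    expect_error(splitCalibration(s, frac = 1.2), "frac")
    expect_error(splitCalibration(s, stratifyBy = "nope"), "missing")
})

test_that("a two-thirds split of a full campaign lands at the expected sizes", {
    d <- generateDataset(defaultSyntheticConfig(nSamples = 1068), seed = 3)
    sp <- splitCalibration(d$spectra, frac = 2/3, seed = 3)
    nCal <- length(sp$calibration)
    expect_equal(nCal + length(sp$validation), 1068)
    ## per-stratum rounding keeps the calibration set within a few samples
    ## of 2/3 of the campaign (the study design: 713 of 1068)
    expect_lt(abs(nCal - 712), 8)
})

test_that("figures of merit match hand-computed values", {
    expect_equal(rSquared(c(1, 2, 3), c(1, 2, 3)), 1)
    y <- c(4, 5, 6, 9)
    expect_equal(rSquared(y, rep(mean(y), 4)), 0)
    expect_equal(rSquared(c(1, 2, 3), c(1, 2, 4)), 0.5)
    expect_error(rSquared(c(1, 1), c(1, 2)), "zero variance")

    expect_equal(rmse(c(1, 2), c(1, 2)), 0)
    expect_equal(rmse(c(0, 0, 0), c(0.3, 0.3, 0.3)), 0.3)
    expect_equal(rmse(c(0.2, 0.3), c(0.25, 0.25)), sqrt(0.005 / 2))

    ## R2 via the operation equals 1 - RMSE^2 n / SS_y identically
    set.seed(71)
    yy <- rnorm(30); ff <- yy + rnorm(30, sd = 0.5)
    expect_equal(rSquared(yy, ff),
                 1 - rmse(yy, ff)^2 * 30 / sum((yy - mean(yy))^2))
})

test_that("SDL evaluates the replicate-scatter formula exactly", {
    expect_equal(sdl(matrix(c(2, 2, 2), 1)), 0)
    expect_equal(sdl(matrix(c(1, 2, 3), 1)), 1)           # sqrt(2 / 2)
    expect_equal(sdl(rbind(c(0, 2), c(10, 12))), sqrt(4 / 3))
    expect_equal(sdl(rbind(c(0, 2), c(10, 12)), denominator = "pooled"),
                 sqrt(4 / 2))
    expect_error(sdl(matrix(1, 3, 1)), "m = 2")
    ## the two denominators differ by the known finite factor
    set.seed(72)
    reps <- matrix(rnorm(300 * 3), 300)
    expect_equal(sdl(reps), sdl(reps, "pooled") *
                     sqrt(300 * 2 / (3 * 300 - 1)))
})

test_that("SDL with the pooled denominator recovers injected replicate noise", {
    set.seed(73)
    n <- 500; m <- 3; sigma <- 0.016
    y <- runif(n, 0.15, 0.45)
    reps <- y + matrix(rnorm(n * m, sd = sigma), n)
    est <- sdl(reps, denominator = "pooled")
    expect_lt(abs(est - sigma) / sigma, 0.1)
    ## and the printed form converges to sigma * sqrt(n(m-1)/(mn-1))
    expect_lt(abs(sdl(reps) - sigma * sqrt(n * (m - 1) / (m * n - 1))) /
                  sigma, 0.1)
})

test_that("the error-to-laboratory ratio behaves", {
    expect_equal(rmseSdlRatio(0.030, 0.024), 1.25)
    expect_equal(rmseSdlRatio(0.5, 0.5), 1)
    expect_equal(rmseSdlRatio(2 * 0.030, 0.024), 2 * 1.25)
    expect_error(rmseSdlRatio(0.1, 0), "positive")
})

test_that("external-validation RMSE approaches the response noise level", {
    ## correctly specified signal: with enough samples the prediction error
    ## is dominated by the injected assay noise
    cfg <- defaultSyntheticConfig(nSamples = 2000)
    d <- generateDataset(cfg, seed = 81)
    res <- runPipeline(d$spectra, d$responses, response = "total",
                       seed = 81, maxFactors = 10, postSelectionCV = FALSE)
    sigma <- sqrt((cfg$noise$responseShared[["glucose"]] +
                   cfg$noise$responseShared[["xylose"]])^2 +
                  cfg$noise$responseIndep[["glucose"]]^2 +
                  cfg$noise$responseIndep[["xylose"]]^2)
    expect_lt(abs(res$report$RMSE_EV - sigma) / sigma, 0.15)
})

test_that("the report covers all responses and preprocessing variants", {
    d <- generateDataset(defaultSyntheticConfig(nSamples = 180), seed = 91)
    rep1 <- buildReport(d$spectra, d$responses,
                        variants = c("smooth_norm", "sg1"),
                        responseNames = c("total", "glucose"),
                        seed = 91, nSegments = 5, maxFactors = 5,
                        screenFactors = 3, postSelectionCV = FALSE)
    expect_equal(nrow(rep1), 4)
    expect_setequal(unique(rep1$response), c("total", "glucose"))
    expect_true(all(is.finite(rep1$R2_EV)))
    expect_true(all(rep1$RMSE_EV >= 0) && all(rep1$R2_EV <= 1))
    expect_true(all(rep1$SDL > 0) && all(rep1$RMSE_EV_SDL > 0))
    ## identical settings produce identical rows (determinism)
    again <- runPipeline(d$spectra, d$responses, response = "total",
                         preprocess = "sg1", seed = 91, nSegments = 5,
                         maxFactors = 5, screenFactors = 3,
                         postSelectionCV = FALSE)$report
    expect_equal(again, rep1[rep1$preprocessing == "sg1" &
                             rep1$response == "total", ],
                 ignore_attr = TRUE)
})
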