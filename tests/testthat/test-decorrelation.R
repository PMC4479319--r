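test_that("pearsonR matches hand-computed correlations and validates input", {
    a <- c(1, 2, 3)
    expect_equal(pearsonR(a, 2 * a + 1), 1)
    expect_equal(pearsonR(a, -a), -1)
    expect_equal(pearsonR(a, c(1, 3, 2)), 0.5)
    expect_error(pearsonR(a, c(2, 2, 2)), "variance")
    expect_error(pearsonR(c(1, 2), c(3, 4)), "3 observations")
})

test_that("the partition is an equal split that reduces the correlation", {
    d <- generateDataset(defaultSyntheticConfig(nSamples = 240), seed = 201)
    p <- partitionDecorrelate(d$responses, k = 3, seed = 1, nKicks = 1)
    expect_length(p$assignment, 240)
    expect_setequal(names(p$assignment), d$responses$sample_id)
    expect_true(all(abs(p$sizes - 80) <= 1))
    expect_gt(p$fullR, 0.2)
    expect_lt(p$objective, p$fullR)
    ## the reported per-subset correlations are the actual correlations
    for (s in 1:3) {
        idx <- d$responses$sample_id %in%
            names(p$assignment)[p$assignment == s]
        expect_equal(unname(p$subsetR[s]),
                     cor(d$responses$glucose[idx], d$responses$xylose[idx]),
                     tolerance = 1e-10)
    }
    ## deterministic under a fixed seed, and non-divisible n still splits
    p2 <- partitionDecorrelate(d$responses, k = 3, seed = 1, nKicks = 1)
    expect_identical(p$assignment, p2$assignment)
    p4 <- partitionDecorrelate(d$responses[1:50, ], k = 4, seed = 2,
                               nKicks = 0)
    expect_true(all(p4$sizes %in% c(12, 13)))
    expect_error(partitionDecorrelate(d$responses[1:5, ], k = 3), "3 samples")
    expect_error(partitionDecorrelate(d$responses, k = 1), "at least 2")
})

test_that("greedy search beats the random-partition baseline", {
    d <- generateDataset(defaultSyntheticConfig(nSamples = 300), seed = 202)
    pg <- partitionDecorrelate(d$responses, k = 3, seed = 5, nKicks = 1)
    pr <- partitionDecorrelate(d$responses, k = 3, seed = 5,
                               method = "random")
    expect_lt(pg$objective, pr$objective)
    ## random partitions roughly preserve the full-set correlation
    expect_gt(pr$objective, 0.5 * pr$fullR)
})

test_that("already uncorrelated responses stay uncorrelated", {
    set.seed(203)
    df <- data.frame(sample_id = sprintf("u%03d", 1:150),
                     glucose = runif(150, 0.15, 0.35),
                     xylose = runif(150, 0.1, 0.3))
    df$total <- df$glucose + df$xylose
    stopifnot(abs(cor(df$glucose, df$xylose)) < 0.05)
    p <- partitionDecorrelate(df, k = 3, seed = 3, nKicks = 0)
    expect_true(all(abs(p$subsetR) < 0.15))
})

test_that("per-subset calibrations give one glucose and one xylose model each", {
    d <- generateDataset(defaultSyntheticConfig(nSamples = 90), seed = 204)
    p <- partitionDecorrelate(d$responses, k = 3, seed = 1, nKicks = 0,
                              maxSweeps = 4)
    models <- perSubsetModels(d$spectra, d$responses, p, nSegments = 5,
                              maxFactors = 4, seed = 1)
    expect_length(models, 3)
    expect_true(all(vapply(models, function(m)
        setequal(names(m), c("glucose", "xylose")), TRUE)))
    expect_s4_class(models[[1]]$glucose, "PLSModel")
    ## resampled responses give different coefficients (sanity)
    b1 <- coef(models[[1]]$glucose)
    b2 <- coef(models[[2]]$glucose)
    expect_gt(max(abs(b1 - b2)), 0)
})

test_that("duplicated subsets produce near-identical coefficient vectors", {
    d <- generateDataset(defaultSyntheticConfig(nSamples = 40), seed = 205)
    X <- spectralMatrix(d$spectra)
    dup <- SpectrumSet(rbind(X, X), wavenumbers(d$spectra),
                       sampleIds = c(sampleIds(d$spectra),
                                     paste0("copy_", sampleIds(d$spectra))))
    resp <- rbind(d$responses,
                  transform(d$responses,
                            sample_id = paste0("copy_", sample_id)))
    assignment <- setNames(rep(1:2, each = 40), resp$sample_id)
    part <- list(assignment = assignment)
    models <- perSubsetModels(dup, resp, part, nSegments = 5,
                              maxFactors = 3, seed = 9)
    b1 <- coef(models[[1]]$glucose); b2 <- coef(models[[2]]$glucose)
    cosine <- sum(b1 * b2) / sqrt(sum(b1^2) * sum(b2^2))
    expect_gt(cosine, 0.95)
})

test_that("coefficient regions are annotated with the right bands and signs", {
    grid <- seq(4000, 600, by = -4)
    bands <- loadBandTable()
    expect_equal(nrow(bands), 16)
    expect_true(all(bands$wavenumber >= 600 & bands$wavenumber <= 4000))

    b <- numeric(length(grid))
    b[which.min(abs(grid - 898))] <- 0.5
    ann <- annotateCoefficients(makeCoefModel(b, grid))
    expect_equal(nrow(ann), 1)
    expect_identical(ann$sign, "+")
    expect_identical(ann$assignment, "Amorphous cellulose")

    expect_equal(nrow(annotateCoefficients(makeCoefModel(numeric(length(grid)),
                                                         grid))), 0)

    b2 <- numeric(length(grid))
    b2[which.min(abs(grid - 1510))] <- -0.4
    b2[which.min(abs(grid - 1735))] <- 0.6
    ann2 <- annotateCoefficients(makeCoefModel(b2, grid))
    expect_equal(nrow(ann2), 2)
    ann2 <- ann2[order(ann2$peak_wavenumber), ]
    expect_identical(ann2$sign, c("-", "+"))
    expect_identical(ann2$assignment, c("Lignin", "Xylan (hemicellulose)"))
})
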