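Package: pasPLS
Title: Chemometric Calibration of FTIR Photoacoustic Spectra for Biomass
    Sugar Release
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Calibration of mid-infrared photoacoustic spectra of
    lignocellulosic biomass against enzymatic sugar-release assays.
    Provides a SummarizedExperiment-backed container for absorbance
    matrices on a shared wavenumber grid, Savitzky-Golay smoothing and
    derivatives, mean normalisation and standard normal variate scatter
    correction, PLS1 regression by NIPALS with segmented cross-validation
    and Martens' uncertainty variable selection, Hotelling T2/Q-residual
    outlier screening, external-validation figures of merit (R2, RMSE,
    laboratory standard deviation), a subset-decorrelation analysis of
    regression coefficients with mid-infrared band annotation, and a
    synthetic wheat-straw spectrum generator so that the complete
    workflow is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3), SummarizedExperiment
Imports: methods, stats, utils, S4Vectors
Suggests: testthat (>= 3.0.0), jsonlite, signal
Config/testthat/edition: 3
RoxygenNote: 7.3.3
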