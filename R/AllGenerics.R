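#' @rdname wavenumbers
#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))

#' @rdname spectralMatrix
#' @export
setGeneric("spectralMatrix", function(x) standardGeneric("spectralMatrix"))

#' @rdname sampleIds
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname sgSmooth
#' @export
setGeneric("sgSmooth", function(x, window = 7L, polyorder = 0L)
    standardGeneric("sgSmooth"))

#' @rdname sgDerivative
#' @export
setGeneric("sgDerivative", function(x, window = 7L, polyorder = 2L,
                                    derivOrder = 1L)
    standardGeneric("sgDerivative"))

#' @rdname normalizeMean
#' @export
setGeneric("normalizeMean", function(x) standardGeneric("normalizeMean"))

#' @rdname snv
#' @export
setGeneric("snv", function(x) standardGeneric("snv"))

## explicit S4 generics over the stats S3 ones, so dispatch also works for
## code evaluated inside the package namespace (where the imported S3
## generic would otherwise shadow the implicit generic)
#' @export
setGeneric("predict")

#' @export
setGeneric("coef")

#' @rdname nFactors
#' @export
setGeneric("nFactors", function(x) standardGeneric("nFactors"))

#' @rdname selectedVariables
#' @export
setGeneric("selectedVariables", function(x) standardGeneric("selectedVariables"))
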