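#' @import methods
#' @importFrom stats approx cor cov mahalanobis prcomp rnorm sd setNames
#' @importFrom utils read.csv write.csv head
NULL

#' Accessors for spectral and chemometric objects
#'
#' `wavenumbers()` and `absorbance()` return the spectral axes of a
#' [Spectrum-class] object; `sampleId()` and `replicateId()` return its
#' identifiers and `provenance()` its free-form processing log.
#' `scores()`, `pcaLoadings()`, `explainedFraction()` and `variableNames()`
#' extract the corresponding parts of a [PCAResult-class].
#'
#' @param object an object of the documented class.
#' @return the slot contents (numeric vectors, matrices, or character).
#' @name accessors
#' @aliases wavenumbers absorbance sampleId replicateId provenance
#'   scores pcaLoadings explainedFraction variableNames
NULL

#' @rdname accessors
#' @export
setGeneric("wavenumbers", function(object) standardGeneric("wavenumbers"))

#' @rdname accessors
#' @export
setGeneric("absorbance", function(object) standardGeneric("absorbance"))

#' @rdname accessors
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))

#' @rdname accessors
#' @export
setGeneric("replicateId", function(object) standardGeneric("replicateId"))

#' @rdname accessors
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))

#' @rdname accessors
#' @export
setGeneric("scores", function(object) standardGeneric("scores"))

#' @rdname accessors
#' @export
setGeneric("pcaLoadings", function(object) standardGeneric("pcaLoadings"))

#' @rdname accessors
#' @export
setGeneric("explainedFraction", function(object) standardGeneric("explainedFraction"))

#' @rdname accessors
#' @export
setGeneric("variableNames", function(object) standardGeneric("variableNames"))
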