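#' @include AllGenerics.R
NULL

#' Single ATR-FTIR absorbance spectrum
#'
#' Container for one absorbance spectrum on a strictly monotonic wavenumber
#' grid. Spectra are stored with the grid descending (4000 down to 700
#' cm\eqn{^{-1}}, the instrument plotting convention); constructors accept
#' either orientation and reorder on ingest.
#'
#' @slot wavenumbers numeric, cm\eqn{^{-1}}, strictly decreasing.
#' @slot absorbance numeric, absorbance units (AU), same length.
#' @slot sampleId character scalar.
#' @slot replicate integer replicate/fragment index (>= 0).
#' @slot provenance list of free-form processing records (source file,
#'   baseline vectors, averaging notes, generator ground truth, ...).
#'
#' @examples
#' s <- Spectrum(seq(700, 4000, by = 4), rep(0, 826), sampleId = "blank")
#' head(wavenumbers(s))
#' @export
setClass("Spectrum",
  representation(
    wavenumbers = "numeric",
    absorbance  = "numeric",
    sampleId    = "character",
    replicate   = "integer",
    provenance  = "list"
  ),
  prototype(sampleId = NA_character_, replicate = 0L, provenance = list())
)

setValidity("Spectrum", function(object) {
  w <- object@wavenumbers
  a <- object@absorbance
  msg <- character()
  if (length(w) != length(a))
    msg <- c(msg, "wavenumbers and absorbance must have equal length")
  if (length(w) < 2L)
    msg <- c(msg, "a spectrum needs at least two points")
  if (anyNA(w) || anyNA(a))
    msg <- c(msg, "missing values are not allowed")
  if (length(w) >= 2L && !all(diff(w) < 0))
    msg <- c(msg, "wavenumber grid must be strictly decreasing (stored orientation)")
  if (length(object@sampleId) != 1L)
    msg <- c(msg, "sampleId must be a single string")
  if (length(object@replicate) != 1L || is.na(object@replicate) || object@replicate < 0L)
    msg <- c(msg, "replicate must be a single non-negative integer")
  if (length(msg)) msg else TRUE
})

#' Construct a Spectrum
#'
#' @param wavenumbers numeric grid in cm\eqn{^{-1}}, strictly monotonic in
#'   either direction (duplicates are rejected).
#' @param absorbance numeric absorbance values, same length.
#' @param sampleId sample identifier.
#' @param replicate replicate/fragment index (default 0).
#' @param provenance list of processing records.
#' @return a validated [Spectrum-class] object, grid stored descending.
#' @export
Spectrum <- function(wavenumbers, absorbance, sampleId = NA_character_,
                     replicate = 0L, provenance = list()) {
  wavenumbers <- as.numeric(wavenumbers)
  absorbance <- as.numeric(absorbance)
  if (length(wavenumbers) != length(absorbance))
    stop("wavenumbers and absorbance must have equal length")
  if (anyNA(wavenumbers) || anyNA(absorbance))
    stop("missing values are not allowed in a spectrum")
  d <- diff(wavenumbers)
  if (any(d == 0))
    stop("duplicated wavenumbers in grid")
  if (all(d > 0)) {            # ascending on input: flip to convention
    wavenumbers <- rev(wavenumbers)
    absorbance <- rev(absorbance)
  } else if (!all(d < 0)) {
    stop("wavenumber grid must be strictly monotonic")
  }
  new("Spectrum", wavenumbers = wavenumbers, absorbance = absorbance,
      sampleId = as.character(sampleId)[1L], replicate = as.integer(replicate)[1L],
      provenance = provenance)
}

setMethod("show", "Spectrum", function(object) {
  w <- object@wavenumbers
  cat("Spectrum: sample", object@sampleId,
      sprintf("(replicate %d)\n", object@replicate))
  cat(sprintf("  %d points, %.0f-%.0f cm-1, max absorbance %.4g AU\n",
              length(w), max(w), min(w), max(object@absorbance)))
  if (length(object@provenance))
    cat("  provenance:", paste(names(object@provenance), collapse = ", "), "\n")
})

#' @rdname accessors
setMethod("wavenumbers", "Spectrum", function(object) object@wavenumbers)
#' @rdname accessors
setMethod("absorbance", "Spectrum", function(object) object@absorbance)
#' @rdname accessors
setMethod("sampleId", "Spectrum", function(object) object@sampleId)
#' @rdname accessors
setMethod("replicateId", "Spectrum", function(object) object@replicate)
#' @rdname accessors
setMethod("provenance", "Spectrum", function(object) object@provenance)

#' Principal component analysis result
#'
#' PCA of a feature table on z-scored variables (correlation-matrix PCA by
#' default). Loadings columns are unit-norm eigenvectors with signs fixed so
#' the largest-magnitude loading in each component is positive.
#'
#' @slot variableNames character, the analysed variables.
#' @slot loadings variables x components matrix.
#' @slot scores samples x components matrix.
#' @slot explainedFraction numeric fraction of variance per component.
#' @slot center,scale numeric centring/scaling applied per variable.
#' @slot sampleIds character row identifiers of `scores`.
#' @export
setClass("PCAResult",
  representation(
    variableNames = "character",
    loadings = "matrix",
    scores = "matrix",
    explainedFraction = "numeric",
    center = "numeric",
    scale = "numeric",
    sampleIds = "character"
  )
)

setValidity("PCAResult", function(object) {
  L <- object@loadings
  msg <- character()
  if (nrow(L) != length(object@variableNames))
    msg <- c(msg, "loadings rows must match variableNames")
  G <- crossprod(L)
  if (max(abs(G - diag(ncol(L)))) > 1e-8)
    msg <- c(msg, "loadings columns must be orthonormal")
  f <- object@explainedFraction
  if (any(f <= 0) || any(f > 1 + 1e-9))
    msg <- c(msg, "explained fractions must lie in (0, 1]")
  if (any(diff(f) > 1e-9))
    msg <- c(msg, "explained fractions must be non-increasing")
  if (sum(f) > 1 + 1e-9)
    msg <- c(msg, "explained fractions must sum to at most 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PCAResult", function(object) {
  cat("PCAResult:", length(object@variableNames), "variables,",
      nrow(object@scores), "samples\n")
  f <- object@explainedFraction
  cat("  explained: ",
      paste(sprintf("PC%d %.1f%%", seq_along(f), 100 * f), collapse = ", "),
      "\n", sep = "")
})

#' @rdname accessors
setMethod("scores", "PCAResult", function(object) object@scores)
#' @rdname accessors
setMethod("pcaLoadings", "PCAResult", function(object) object@loadings)
#' @rdname accessors
setMethod("explainedFraction", "PCAResult", function(object) object@explainedFraction)
#' @rdname accessors
setMethod("variableNames", "PCAResult", function(object) object@variableNames)

#' Convex-hull species domain in score space
#'
#' The convex hull of a species' sample scores in the first two principal
#' components. One or two member samples give a degenerate point/segment
#' domain with zero area.
#'
#' @slot species character scalar.
#' @slot vertices two-column matrix of hull vertices (counter-clockwise).
#' @slot centroid numeric length-2 mean score of the member samples.
#' @slot area numeric hull area (score units squared).
#' @export
setClass("SpeciesDomain",
  representation(
    species = "character",
    vertices = "matrix",
    centroid = "numeric",
    area = "numeric"
  )
)

setValidity("SpeciesDomain", function(object) {
  msg <- character()
  if (ncol(object@vertices) != 2L)
    msg <- c(msg, "vertices must be a two-column matrix")
  if (object@area < 0)
    msg <- c(msg, "area must be non-negative")
  if (length(object@centroid) != 2L)
    msg <- c(msg, "centroid must have length 2")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SpeciesDomain", function(object) {
  cat(sprintf("SpeciesDomain %s: %d vertices, area %.3f, centroid (%.2f, %.2f)\n",
              object@species, nrow(object@vertices), object@area,
              object@centroid[1], object@centroid[2]))
})

#' Report of the three-step variable selection
#'
#' Records every intermediate quantity of the screening: full-spectrum
#' pairwise correlations (step 1), the candidate PCAs with and without
#' standards and the inter-variable correlations (steps 2 and 3), the
#' discard order, and the final three-variable mineral and organic sets.
#'
#' @slot fullSpectrumCorrelation sample x sample Pearson matrix (step 1),
#'   or a 0 x 0 matrix when no spectra were supplied.
#' @slot mineralPCA,organicPCA lists of [PCAResult-class] (elements
#'   `withStandards`, `withoutStandards`; the former absent when no
#'   standards were supplied).
#' @slot mineralCorrelation,organicCorrelation candidate correlation
#'   matrices used by the discard rule.
#' @slot mineralDiscarded,organicDiscarded character, discard order.
#' @slot mineralSelected,organicSelected character, exactly 3 variables.
#' @export
setClass("SelectionReport",
  representation(
    fullSpectrumCorrelation = "matrix",
    mineralPCA = "list",
    organicPCA = "list",
    mineralCorrelation = "matrix",
    organicCorrelation = "matrix",
    mineralDiscarded = "character",
    organicDiscarded = "character",
    mineralSelected = "character",
    organicSelected = "character"
  )
)

setValidity("SelectionReport", function(object) {
  msg <- character()
  if (length(object@mineralSelected) != 3L)
    msg <- c(msg, "mineral selection must contain exactly 3 variables")
  if (length(object@organicSelected) != 3L)
    msg <- c(msg, "organic selection must contain exactly 3 variables")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SelectionReport", function(object) {
  cat("SelectionReport\n")
  cat("  mineral: kept {", paste(object@mineralSelected, collapse = ", "),
      "} discarded [", paste(object@mineralDiscarded, collapse = " > "), "]\n")
  cat("  organic: kept {", paste(object@organicSelected, collapse = ", "),
      "} discarded [", paste(object@organicDiscarded, collapse = " > "), "]\n")
})

#' Ground-truth composition profile for the synthetic generator
#'
#' Mean component weights (with log-normal dispersion) plus noise and
#' baseline-drift settings that drive [synthesizeSpectrum()] and
#' [generateCohort()].
#'
#' @slot species character label ("Crocuta crocuta", ..., or a standard).
#' @slot weights named numeric mean weight per component template.
#' @slot weightSdLog numeric log-normal dispersion of the weights.
#' @slot driftAmplitude numeric max |baseline drift| in AU.
#' @slot noiseSd numeric additive Gaussian noise sd in AU.
#' @slot replicates integer fragments measured per sample.
#' @export
setClass("SpeciesProfile",
  representation(
    species = "character",
    weights = "numeric",
    weightSdLog = "numeric",
    driftAmplitude = "numeric",
    noiseSd = "numeric",
    replicates = "integer"
  ),
  prototype(weightSdLog = 0.25, driftAmplitude = 0.05, noiseSd = 0.005,
            replicates = 4L)
)

setValidity("SpeciesProfile", function(object) {
  msg <- character()
  if (any(object@weights < 0)) msg <- c(msg, "weights must be >= 0")
  if (is.null(names(object@weights)) || any(!nzchar(names(object@weights))))
    msg <- c(msg, "weights must be named by component")
  if (object@noiseSd < 0 || object@driftAmplitude < 0)
    msg <- c(msg, "noiseSd and driftAmplitude must be >= 0")
  if (object@replicates < 1L) msg <- c(msg, "replicates must be >= 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SpeciesProfile", function(object) {
  cat("SpeciesProfile:", object@species, "\n")
  w <- object@weights[object@weights > 0]
  cat("  weights:", paste(sprintf("%s=%.3g", names(w), w), collapse = " "), "\n")
  cat(sprintf("  sdlog %.2f, drift %.3g AU, noise %.3g AU, %d replicates\n",
              object@weightSdLog, object@driftAmplitude, object@noiseSd,
              object@replicates))
})
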