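#' @include band-features.R
NULL

#' Pairwise full-spectrum Pearson correlations
#'
#' Correlation between whole absorbance spectra, the first screening step
#' of the variable selection: it shows how similar samples are before any
#' band variable is defined. Spectra on differing grids are linearly
#' resampled onto their common range at the coarsest step.
#'
#' @param spectra list of at least two [Spectrum-class] objects.
#' @return symmetric correlation matrix (diagonal 1) with sample ids as
#'   dimnames; correlations involving a constant spectrum are NA (with a
#'   warning).
#' @export
pairwiseCorrelation <- function(spectra) {
  if (!is.list(spectra) || length(spectra) < 2L)
    stop("need at least two spectra")
  grids <- lapply(spectra, wavenumbers)
  lo <- max(vapply(grids, min, numeric(1)))
  hi <- min(vapply(grids, max, numeric(1)))
  if (lo >= hi) stop("spectra have disjoint wavenumber ranges")
  step <- max(vapply(grids, function(g) stats::median(abs(diff(g))), numeric(1)))
  grid <- seq(hi, lo, by = -step)
  A <- vapply(spectra, function(s) approx(s@wavenumbers, s@absorbance,
                                          xout = grid)$y,
              numeric(length(grid)))
  ids <- vapply(spectra, sampleId, character(1))
  colnames(A) <- make.unique(ids)
  if (any(apply(A, 2, sd) == 0))
    warning("constant spectra present; their correlations are undefined (NA)")
  suppressWarnings(R <- cor(A))
  diag(R) <- 1
  R
}

#' Correlation-matrix PCA of band variables
#'
#' PCA of a feature table. Variables are z-scored by default
#' (correlation-matrix PCA), because the band variables mix areas and
#' dimensionless ratios of different magnitudes. Rows holding an undefined
#' (NA) value in any chosen variable are dropped with a message. Component
#' signs are fixed by making the largest-magnitude loading of each
#' component positive; components with zero variance are dropped.
#'
#' @param features data.frame with a `sample_id` column and the band
#'   variables (see [computeFeatureTable()]).
#' @param variables character subset of variables to analyse (>= 2).
#' @param center,scale logical; defaults give correlation-matrix PCA.
#' @return a [PCAResult-class].
#' @export
runPCA <- function(features, variables, center = TRUE, scale = TRUE) {
  stopifnot(is.data.frame(features))
  if (missing(variables))
    variables <- intersect(c(mineralVariables, organicVariables), names(features))
  if (length(variables) < 2L) stop("need at least two variables")
  miss <- setdiff(variables, names(features))
  if (length(miss)) stop("variables absent from table: ", paste(miss, collapse = ", "))
  X <- as.matrix(features[, variables, drop = FALSE])
  ids <- if ("sample_id" %in% names(features)) as.character(features$sample_id)
         else as.character(seq_len(nrow(X)))
  keep <- stats::complete.cases(X)
  if (!all(keep)) {
    message(sum(!keep), " row(s) dropped for undefined variable values")
    X <- X[keep, , drop = FALSE]
    ids <- ids[keep]
  }
  if (nrow(X) < 3L) stop("need at least three complete samples")
  v <- apply(X, 2, sd)
  if (any(v == 0))
    stop("zero-variance variable(s): ", paste(variables[v == 0], collapse = ", "))
  p <- prcomp(X, center = center, scale. = scale)
  nz <- p$sdev > 1e-12
  L <- p$rotation[, nz, drop = FALSE]
  S <- p$x[, nz, drop = FALSE]
  # sign convention: largest-magnitude loading of each component positive
  for (j in seq_len(ncol(L))) {
    k <- which.max(abs(L[, j]))
    if (L[k, j] < 0) { L[, j] <- -L[, j]; S[, j] <- -S[, j] }
  }
  total <- sum(apply(scale(X, center = center, scale = scale), 2, stats::var))
  rownames(S) <- ids
  new("PCAResult", variableNames = variables, loadings = L, scores = S,
      explainedFraction = p$sdev[nz]^2 / total,
      center = if (center) p$center else rep(0, length(variables)),
      scale = if (scale) p$scale else rep(1, length(variables)),
      sampleIds = ids)
}

# iterative redundancy screen: discard the candidate with the highest mean
# |r| to the remaining candidates until `keep` remain; on an exact tie the
# later-listed candidate is discarded (the earlier-listed, primary variable
# is kept), so the rule is deterministic.
.discardByMeanAbsCor <- function(R, candidates, keep = 3L) {
  vars <- candidates
  discarded <- character(0)
  while (length(vars) > keep) {
    sub <- abs(R[vars, vars, drop = FALSE])
    diag(sub) <- NA
    m <- rowMeans(sub, na.rm = TRUE)
    worst <- vars[max(which(m == max(m)))]
    discarded <- c(discarded, worst)
    vars <- setdiff(vars, worst)
  }
  list(selected = vars, discarded = discarded)
}

#' Three-step variable selection
#'
#' Step 1 screens samples by full-spectrum pairwise correlation (when
#' spectra are supplied). Step 2 runs PCA on the mineral candidates (with
#' the reference standards, then excluding them), computes the
#' inter-variable correlations, and reduces the candidates to three by
#' iteratively discarding the variable with the highest mean absolute
#' correlation to the remaining candidates (on an exact tie the
#' later-listed candidate is discarded). Step 3 repeats the procedure for the organic
#' candidates. Correlations feeding the discard rule are computed on the
#' non-standard samples.
#'
#' @param features feature table (>= 6 samples after NA handling).
#' @param mineralCandidates,organicCandidates candidate variable names
#'   (>= 3 each).
#' @param spectra optional list of [Spectrum-class] for step 1.
#' @param standards optional logical vector (per row of `features`) or
#'   character vector of `sample_id`s marking reference standards.
#' @return a [SelectionReport-class].
#' @export
selectVariables <- function(features,
                            mineralCandidates = mineralVariables,
                            organicCandidates = organicVariables,
                            spectra = NULL, standards = NULL) {
  stopifnot(is.data.frame(features))
  if (length(mineralCandidates) < 3L || length(organicCandidates) < 3L)
    stop("need at least three candidates in each set")
  if (nrow(features) < 6L) stop("need at least six samples")
  isStd <- rep(FALSE, nrow(features))
  if (!is.null(standards)) {
    isStd <- if (is.logical(standards)) standards
             else features$sample_id %in% standards
  }
  fullCor <- if (!is.null(spectra)) pairwiseCorrelation(spectra)
             else matrix(numeric(0), 0, 0)

  stepFor <- function(cands) {
    pcas <- list()
    if (any(isStd))
      pcas$withStandards <- runPCA(features, cands)
    pcas$withoutStandards <- runPCA(features[!isStd, , drop = FALSE], cands)
    X <- features[!isStd, cands, drop = FALSE]
    X <- X[stats::complete.cases(X), , drop = FALSE]
    R <- cor(as.matrix(X))
    sel <- .discardByMeanAbsCor(R, cands, keep = 3L)
    list(pcas = pcas, R = R, sel = sel)
  }
  m <- stepFor(mineralCandidates)
  o <- stepFor(organicCandidates)
  new("SelectionReport",
      fullSpectrumCorrelation = fullCor,
      mineralPCA = m$pcas, organicPCA = o$pcas,
      mineralCorrelation = m$R, organicCorrelation = o$R,
      mineralDiscarded = m$sel$discarded, organicDiscarded = o$sel$discarded,
      mineralSelected = m$sel$selected, organicSelected = o$sel$selected)
}

#' Convex-hull species domains in score space
#'
#' Builds the convex hull of each species' samples in the first two
#' principal components. One or two member samples yield a degenerate
#' point/segment domain of zero area.
#'
#' @param pca a [PCAResult-class].
#' @param labels character/factor species label per retained sample (same
#'   order and length as `scores(pca)` rows); missing labels are an error.
#' @return named list of [SpeciesDomain-class].
#' @seealso [domainOverlap()]
#' @export
buildDomains <- function(pca, labels) {
  stopifnot(is(pca, "PCAResult"))
  labels <- as.character(labels)
  if (length(labels) != nrow(pca@scores))
    stop("labels length must match the number of retained samples")
  if (anyNA(labels) || any(!nzchar(labels)))
    stop("unknown (missing/empty) label")
  S <- pca@scores[, 1:2, drop = FALSE]
  out <- lapply(split(seq_len(nrow(S)), labels), function(idx) {
    pts <- S[idx, , drop = FALSE]
    v <- if (nrow(pts) >= 3L) convexHullCCW(pts) else
      matrix(pts, ncol = 2, dimnames = list(NULL, c("PC1", "PC2")))
    new("SpeciesDomain", species = labels[idx[1]], vertices = v,
        centroid = colMeans(pts), area = abs(polygonArea(v)))
  })
  out
}

#' Pairwise domain overlap and containment
#'
#' Overlap areas by convex polygon intersection, plus containment flags
#' (`a_in_b`: every vertex of domain `a` lies inside domain `b`).
#'
#' @param domains list of [SpeciesDomain-class] from [buildDomains()].
#' @return data.frame with columns `a`, `b`, `overlap_area`, `a_in_b`,
#'   `b_in_a`, one row per unordered pair.
#' @export
domainOverlap <- function(domains) {
  nm <- vapply(domains, function(d) d@species, character(1))
  if (length(domains) < 2L)
    return(data.frame(a = character(0), b = character(0),
                      overlap_area = numeric(0), a_in_b = logical(0),
                      b_in_a = logical(0), stringsAsFactors = FALSE))
  pairs <- utils::combn(seq_along(domains), 2)
  contained <- function(a, b) {
    nrow(a@vertices) > 0 &&
      all(apply(a@vertices, 1, pointInConvex, v = b@vertices))
  }
  do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    data.frame(a = nm[i], b = nm[j],
               overlap_area = convexOverlapArea(domains[[i]]@vertices,
                                                domains[[j]]@vertices),
               a_in_b = contained(domains[[i]], domains[[j]]),
               b_in_a = contained(domains[[j]], domains[[i]]),
               stringsAsFactors = FALSE)
  }))
}
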