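#' @include spectra-io.R
NULL

#' Preprocessing configuration
#'
#' Settings for baseline correction and normalization. The rubberband
#' (convex-hull) baseline is parameter-free; the asymmetric least squares
#' (ALS) baseline is controlled by a smoothness weight `als_lambda` and an
#' asymmetry weight `als_p` (fraction of weight given to points above the
#' running baseline estimate).
#'
#' @param baseline_method `"rubberband"`, `"asymmetric_least_squares"` or
#'   `"none"`.
#' @param als_lambda smoothness penalty (> 0); larger values give stiffer
#'   baselines. Default 1e6, appropriate for broad drift under bands a few
#'   tens of cm\eqn{^{-1}} wide on a 4 cm\eqn{^{-1}} grid.
#' @param als_p asymmetry weight in (0, 1); default 0.01.
#' @param normalization `"vector"`, `"max"` or `"none"`.
#' @param normalization_range wavenumber window (cm\eqn{^{-1}}) over which
#'   the norm is computed (the whole spectrum is rescaled). Default
#'   700-1800, the mineral fingerprint region.
#' @param clamp_negative floor post-baseline absorbance at 0 (default TRUE)
#'   so band surfaces are non-negative.
#' @return a list of class `PreprocessConfig`.
#' @export
preprocessConfig <- function(baseline_method = c("rubberband",
                                                 "asymmetric_least_squares",
                                                 "none"),
                             als_lambda = 1e6, als_p = 0.01,
                             normalization = c("vector", "max", "none"),
                             normalization_range = c(700, 1800),
                             clamp_negative = TRUE) {
  baseline_method <- match.arg(baseline_method)
  normalization <- match.arg(normalization)
  if (!is.numeric(als_lambda) || als_lambda <= 0) stop("als_lambda must be > 0")
  if (!is.numeric(als_p) || als_p <= 0 || als_p >= 1)
    stop("als_p must lie strictly between 0 and 1")
  structure(list(baseline_method = baseline_method, als_lambda = als_lambda,
                 als_p = als_p, normalization = normalization,
                 normalization_range = sort(normalization_range),
                 clamp_negative = isTRUE(clamp_negative)),
            class = "PreprocessConfig")
}

# lower convex hull baseline (Andrew monotone chain), points in ascending x
.rubberbandBaseline <- function(x, y) {
  n <- length(x)
  hull <- integer(0)
  for (i in seq_len(n)) {
    while (length(hull) >= 2L) {
      a <- hull[length(hull) - 1L]; b <- hull[length(hull)]
      # drop b if it lies on or above chord a-i
      if ((x[b] - x[a]) * (y[i] - y[a]) - (y[b] - y[a]) * (x[i] - x[a]) <= 0)
        hull <- hull[-length(hull)]
      else break
    }
    hull <- c(hull, i)
  }
  approx(x[hull], y[hull], xout = x)$y
}

# asymmetric least squares (Whittaker smoother with asymmetric weights)
.alsBaseline <- function(y, lambda, p, maxit = 15L) {
  n <- length(y)
  D <- Matrix::bandSparse(n - 2L, n, k = 0:2,
                          diagonals = list(rep(1, n - 2L), rep(-2, n - 2L),
                                           rep(1, n - 2L)))
  DtD <- lambda * Matrix::crossprod(D)
  w <- rep(1, n)
  z <- y
  for (it in seq_len(maxit)) {
    W <- Matrix::Diagonal(n, w)
    z <- as.numeric(Matrix::solve(W + DtD, w * y))
    wnew <- ifelse(y > z, p, 1 - p)
    if (all(wnew == w)) break
    w <- wnew
  }
  z
}

#' Baseline-correct a spectrum
#'
#' Subtracts an estimated baseline. The rubberband method interpolates the
#' lower convex hull of the spectrum; the ALS method iteratively fits a
#' stiff Whittaker smoother that is only weakly attracted to points above
#' it. The estimated baseline is stored in `provenance(s)$baseline` for
#' inspection.
#'
#' @param s a [Spectrum-class] with at least 16 points.
#' @param cfg a [preprocessConfig()] list (its `baseline_method`,
#'   `als_lambda`, `als_p` and `clamp_negative` entries are used).
#' @return the corrected [Spectrum-class].
#' @export
baselineCorrect <- function(s, cfg = preprocessConfig()) {
  stopifnot(is(s, "Spectrum"))
  if (length(s@wavenumbers) < 16L)
    stop("baseline estimation needs at least 16 points")
  # operate in ascending orientation
  x <- rev(s@wavenumbers); y <- rev(s@absorbance)
  base <- switch(cfg$baseline_method,
    rubberband = .rubberbandBaseline(x, y),
    asymmetric_least_squares = .alsBaseline(y, cfg$als_lambda, cfg$als_p),
    none = rep(0, length(y))
  )
  corr <- y - base
  if (cfg$clamp_negative) corr <- pmax(corr, 0)
  prov <- s@provenance
  prov$baseline <- rev(base)          # stored in descending orientation
  prov$baseline_method <- cfg$baseline_method
  Spectrum(x, corr, sampleId = s@sampleId, replicate = s@replicate,
           provenance = prov)
}

#' Normalize a spectrum
#'
#' `"vector"` scales to unit Euclidean norm, `"max"` to a maximum
#' absorbance of 1, `"none"` is the identity. The norm/maximum is computed
#' over `range` (the mineral fingerprint region by default, because ATR
#' contact pressure makes absolute absorbance unreliable) but the whole
#' spectrum is rescaled.
#'
#' @param s a [Spectrum-class].
#' @param mode `"vector"`, `"max"` or `"none"`.
#' @param range wavenumber window used to compute the norm; `NULL` uses the
#'   full spectrum.
#' @return the rescaled [Spectrum-class].
#' @export
normalizeSpectrum <- function(s, mode = c("vector", "max", "none"),
                              range = NULL) {
  mode <- match.arg(mode)
  stopifnot(is(s, "Spectrum"))
  if (mode == "none") return(s)
  a <- s@absorbance
  sel <- if (is.null(range)) rep(TRUE, length(a)) else {
    range <- sort(range)
    s@wavenumbers >= range[1] & s@wavenumbers <= range[2]
  }
  if (!any(sel)) stop("normalization range contains no points")
  denom <- if (mode == "vector") sqrt(sum(a[sel]^2)) else max(abs(a[sel]))
  if (denom == 0) stop("cannot normalize an all-zero spectrum")
  prov <- s@provenance
  prov$normalization <- list(mode = mode, denom = denom)
  Spectrum(s@wavenumbers, a / denom, sampleId = s@sampleId,
           replicate = s@replicate, provenance = prov)
}

#' Full spectrum preprocessing
#'
#' Baseline correction followed by normalization, per the configuration.
#'
#' @inheritParams baselineCorrect
#' @return the preprocessed [Spectrum-class].
#' @export
preprocessSpectrum <- function(s, cfg = preprocessConfig()) {
  s <- baselineCorrect(s, cfg)
  if (cfg$normalization != "none")
    s <- normalizeSpectrum(s, cfg$normalization, cfg$normalization_range)
  s
}
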