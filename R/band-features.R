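#' @include preprocess.R
NULL

#' Names of the mineral and organic band variables
#'
#' The six mineral and five organic variables quantified per sample. The
#' mineral set covers phosphate and carbonate band surfaces, a
#' crystallinity-index surface (CI, 1010-1030 cm\eqn{^{-1}}), and two
#' carbonate-to-phosphate peak-height ratios; the organic set covers the
#' chitin/keratin-S region, the C-H stretch region diagnostic of
#' cholesterol, the amide II and amide I surfaces, and an amide III proxy
#' labelled collagen.
#' @export
mineralVariables <- c("PO4", "CO3", "CO3b", "CI", "CO3PO4", "CO3PO4b")

#' @rdname mineralVariables
#' @export
organicVariables <- c("chitin", "cholesterol", "amideII", "amideI", "collagen")

#' Reference band library
#'
#' Windows, quantification modes and assignments of every band variable,
#' shipped as a user-extensible CSV resource.
#'
#' @param path CSV file; default is the packaged library.
#' @return data.frame with columns `name`, `role`, `mode`, `lo`, `hi`,
#'   `at`, `halfwidth`, `assignment`.
#' @export
bandLibrary <- function(path = system.file("extdata", "band_library.csv",
                                           package = "coproFTIR")) {
  lib <- read.csv(path, stringsAsFactors = FALSE)
  area <- lib$mode == "area"
  if (any(area & !(lib$lo < lib$hi)))
    stop("band library: area bands need lo < hi")
  if (any(area & (lib$lo < 400 | lib$hi > 4000)))
    stop("band library: windows must lie within 400-4000 cm-1")
  lib
}

.windowIdx <- function(s, lo, hi, what) {
  w <- s@wavenumbers
  if (lo < min(w) || hi > max(w))
    stop(sprintf("window %.0f-%.0f cm-1 for %s lies outside the spectrum range %.0f-%.0f",
                 lo, hi, what, min(w), max(w)))
  which(w >= lo & w <= hi)
}

#' Integrate a band surface
#'
#' Trapezoidal integral of absorbance over `[lo, hi]` after subtracting a
#' local linear baseline. The baseline is the chord through the spectrum at
#' the anchor points `baseLo`/`baseHi` (interpolated when they fall between
#' grid points); anchors default to the window endpoints, but a band may
#' pin them at the band feet instead (as FTIR integration software does)
#' when the integration limits sit on the band itself, e.g. the phosphate
#' \eqn{\nu_4} window whose bounds coincide with the doublet peaks.
#' Negative results are floored at 0.
#'
#' @param s a (preprocessed) [Spectrum-class].
#' @param lo,hi window bounds in cm\eqn{^{-1}}; alternatively `lo` may be a
#'   band-library row (list/one-row data.frame with `name`, `lo`, `hi` and
#'   optional `base_lo`, `base_hi`).
#' @param baseLo,baseHi baseline anchor points (default: the window
#'   endpoints).
#' @return band surface in AU cm\eqn{^{-1}}.
#' @export
integrateBand <- function(s, lo, hi = NULL, baseLo = NULL, baseHi = NULL) {
  name <- "band"
  if (is.list(lo)) {
    band <- lo; name <- band$name; hi <- band$hi
    if (!is.null(band$base_lo) && !is.na(band$base_lo)) baseLo <- band$base_lo
    if (!is.null(band$base_hi) && !is.na(band$base_hi)) baseHi <- band$base_hi
    lo <- band$lo
  }
  if (is.null(baseLo)) baseLo <- lo
  if (is.null(baseHi)) baseHi <- hi
  stopifnot(is(s, "Spectrum"), is.numeric(lo), is.numeric(hi), lo < hi,
            baseLo <= lo, baseHi >= hi)
  .windowIdx(s, baseLo, baseHi, name)
  # ascending orientation with exact interpolated endpoints
  x <- rev(s@wavenumbers); y <- rev(s@absorbance)
  yb <- approx(x, y, xout = c(baseLo, baseHi))$y
  chordAt <- function(xs) yb[1] + (xs - baseLo) * (yb[2] - yb[1]) / (baseHi - baseLo)
  yend <- approx(x, y, xout = c(lo, hi))$y
  keep <- x > lo & x < hi
  xs <- c(lo, x[keep], hi)
  ys <- c(yend[1], y[keep], yend[2])
  d <- ys - chordAt(xs)
  area <- sum(diff(xs) * (head(d, -1) + d[-1]) / 2)
  max(area, 0)
}

#' Peak height within a search window
#'
#' Maximum absorbance within `at` +/- `halfwidth`; the default half-width
#' of 8 cm\eqn{^{-1}} spans two steps of a 4 cm\eqn{^{-1}} grid. When the
#' discrete maximum is an interior point, the height is refined by the
#' parabola through it and its neighbours, compensating the sampling bias
#' of a coarse grid.
#'
#' @param s a (preprocessed) [Spectrum-class].
#' @param at nominal band position, cm\eqn{^{-1}}.
#' @param halfwidth search half-width, cm\eqn{^{-1}}.
#' @return height in AU.
#' @export
peakHeight <- function(s, at, halfwidth = 8) {
  stopifnot(is(s, "Spectrum"))
  idx <- .windowIdx(s, at - halfwidth, at + halfwidth,
                    sprintf("peak %.0f", at))
  y <- s@absorbance[idx]
  i <- which.max(y)
  if (i == 1L || i == length(y)) return(y[i])
  den <- y[i - 1L] - 2 * y[i] + y[i + 1L]
  if (den >= 0) return(y[i])
  y[i] - (y[i - 1L] - y[i + 1L])^2 / (8 * den)
}

#' Peak position with parabolic refinement
#'
#' Wavenumber of the absorbance maximum in `[lo, hi]`, refined by fitting a
#' parabola through the three grid points around the discrete maximum
#' (skipped when the maximum sits on the window edge).
#'
#' @param s a [Spectrum-class].
#' @param lo,hi search window, cm\eqn{^{-1}} (at least 3 grid points).
#' @return position in cm\eqn{^{-1}}.
#' @seealso [localMaxima()] for resolving doublets.
#' @export
peakPosition <- function(s, lo, hi) {
  stopifnot(is(s, "Spectrum"))
  idx <- .windowIdx(s, lo, hi, "peak search")
  if (length(idx) < 3L) stop("peak search window spans fewer than 3 grid points")
  x <- rev(s@wavenumbers[idx]); y <- rev(s@absorbance[idx])
  i <- which.max(y)
  .refineParabolic(x, y, i)
}

.refineParabolic <- function(x, y, i) {
  if (i == 1L || i == length(x)) return(x[i])
  y1 <- y[i - 1L]; y2 <- y[i]; y3 <- y[i + 1L]
  den <- y1 - 2 * y2 + y3
  if (den >= 0) return(x[i])     # not a proper maximum
  delta <- 0.5 * (y1 - y3) / den
  h <- (x[i + 1L] - x[i - 1L]) / 2
  x[i] + delta * h
}

#' Local maxima within a window
#'
#' Grid points higher than both neighbours inside `[lo, hi]`, each refined
#' parabolically; used e.g. to resolve the phosphate \eqn{\nu_4} doublet of
#' fresh bone.
#'
#' @inheritParams peakPosition
#' @param minHeight discard maxima below this absorbance (default 0).
#' @return data.frame with columns `position` and `height`, ordered by
#'   decreasing height.
#' @export
localMaxima <- function(s, lo, hi, minHeight = 0) {
  stopifnot(is(s, "Spectrum"))
  idx <- .windowIdx(s, lo, hi, "local maxima search")
  if (length(idx) < 3L) stop("window spans fewer than 3 grid points")
  x <- rev(s@wavenumbers[idx]); y <- rev(s@absorbance[idx])
  n <- length(y)
  i <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  i <- i[y[i] >= minHeight]
  pos <- vapply(i, function(k) .refineParabolic(x, y, k), numeric(1))
  out <- data.frame(position = pos, height = y[i])
  out[order(-out$height), , drop = FALSE]
}

#' Crystallinity splitting factor
#'
#' The conventional infrared splitting factor of the phosphate
#' \eqn{\nu_4} doublet: (height at 565 + height at 605) divided by the
#' absorbance at the intervening minimum. Complements the surface-based
#' crystallinity index `CI` (1010-1030 cm\eqn{^{-1}}), which is the
#' default crystallinity variable in the feature vector.
#'
#' @param s a (preprocessed) [Spectrum-class].
#' @return dimensionless splitting factor (NA when the valley absorbance
#'   is not positive).
#' @export
splittingFactor <- function(s) {
  h1 <- peakHeight(s, 565, 8)
  h2 <- peakHeight(s, 605, 8)
  idx <- .windowIdx(s, 570, 600, "splitting factor valley")
  valley <- min(s@absorbance[idx])
  if (valley <= 0) return(NA_real_)
  (h1 + h2) / valley
}

#' Compute the 11 band variables for one sample
#'
#' Quantifies every variable in [mineralVariables] and [organicVariables]
#' from a preprocessed spectrum: band surfaces by local-baseline trapezoidal
#' integration, and the two carbonate-to-phosphate ratios from peak heights
#' (871/1017 and 1415/575 cm\eqn{^{-1}}). A ratio whose denominator height
#' falls below `ratioFloor` times the spectrum maximum is flagged undefined
#' (NA), not set to 0.
#'
#' @param s a preprocessed [Spectrum-class] covering at least 560-2935
#'   cm\eqn{^{-1}}.
#' @param library band library data.frame (see [bandLibrary()]).
#' @param ratioFloor relative denominator threshold (default 1e-4).
#' @return one-row data.frame: `sample_id` plus the 11 variables; the
#'   attribute `"undefined"` names any flagged ratios.
#' @export
computeFeatures <- function(s, library = bandLibrary(), ratioFloor = 1e-4) {
  stopifnot(is(s, "Spectrum"))
  w <- s@wavenumbers
  lib <- split(library, library$name)
  areas <- library[library$mode == "area", ]
  aLo <- ifelse(is.na(areas$base_lo), areas$lo, pmin(areas$lo, areas$base_lo))
  aHi <- ifelse(is.na(areas$base_hi), areas$hi, pmax(areas$hi, areas$base_hi))
  needLo <- min(aLo, 575 - 8)
  needHi <- max(aHi, 1415 + 8)
  if (min(w) > needLo || max(w) < needHi) {
    missing <- areas$name[aLo < min(w) | aHi > max(w)]
    stop("spectrum does not cover the windows of: ",
         paste(unique(c(missing, "CO3PO4", "CO3PO4b")), collapse = ", "))
  }
  val <- list(sample_id = s@sampleId)
  for (nm in c("PO4", "CO3", "CO3b", "CI", organicVariables))
    val[[nm]] <- integrateBand(s, lib[[nm]])
  hgt <- function(nm) {
    b <- lib[[nm]]
    peakHeight(s, b$at, b$halfwidth)
  }
  floorAbs <- ratioFloor * max(s@absorbance)
  ratio <- function(num, den) {
    d <- hgt(den)
    if (d < floorAbs) NA_real_ else hgt(num) / d
  }
  val$CO3PO4 <- ratio("CO3PO4_num", "CO3PO4_den")
  val$CO3PO4b <- ratio("CO3PO4b_num", "CO3PO4b_den")
  out <- as.data.frame(val, stringsAsFactors = FALSE)
  out <- out[, c("sample_id", mineralVariables, organicVariables)]
  undef <- c("CO3PO4", "CO3PO4b")[is.na(c(out$CO3PO4, out$CO3PO4b))]
  attr(out, "undefined") <- undef
  out
}

#' Feature table for a set of spectra
#'
#' Applies preprocessing (optional) and [computeFeatures()] to each
#' spectrum and binds the rows.
#'
#' @param spectra list of [Spectrum-class].
#' @param cfg a [preprocessConfig()]; `NULL` skips preprocessing (inputs
#'   already corrected).
#' @param library band library data.frame.
#' @return data.frame, one row per spectrum.
#' @export
computeFeatureTable <- function(spectra, cfg = NULL, library = bandLibrary()) {
  rows <- lapply(spectra, function(s) {
    if (!is.null(cfg)) s <- preprocessSpectrum(s, cfg)
    computeFeatures(s, library)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
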