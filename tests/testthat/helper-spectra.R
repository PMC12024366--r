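# fixture builders used across the suite

flatSpectrum <- function(value = 0, lo = 700, hi = 4000, step = 4,
                         sampleId = "flat") {
  g <- seq(lo, hi, by = step)
  Spectrum(g, rep(value, length(g)), sampleId = sampleId)
}

# single Gaussian band on an optional linear ramp
gaussianSpectrum <- function(center, sigma = 5, amp = 1, lo = 500, hi = 4000,
                             step = 1, slope = 0, intercept = 0,
                             sampleId = "gauss") {
  g <- seq(lo, hi, by = step)
  y <- amp * exp(-(g - center)^2 / (2 * sigma^2)) + slope * g + intercept
  Spectrum(g, y, sampleId = sampleId)
}

# closed-form Gaussian band surface over [lo, hi] minus the endpoint chord
gaussianChordArea <- function(center, sigma, amp, lo, hi) {
  I <- amp * sigma * sqrt(2 * pi) *
    (pnorm((hi - center) / sigma) - pnorm((lo - center) / sigma))
  f <- function(x) amp * exp(-(x - center)^2 / (2 * sigma^2))
  I - (f(lo) + f(hi)) / 2 * (hi - lo)
}

# replicate-averaged feature table for a generated cohort
cohortFeatures <- function(coh, cfg = preprocessConfig()) {
  ids <- vapply(coh$spectra, sampleId, character(1))
  grouped <- split(coh$spectra, ids)[unique(ids)]
  avg <- lapply(grouped, function(reps)
    if (length(reps) > 1L) averageReplicates(reps) else reps[[1]])
  ft <- computeFeatureTable(avg, cfg = cfg)
  ft$species <- coh$labels$species[match(ft$sample_id, coh$labels$sample_id)]
  ft
}
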