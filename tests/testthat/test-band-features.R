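test_that("band integration matches a fine-grid quadrature oracle", {
  expect_equal(integrateBand(flatSpectrum(0), 860, 880), 0)

  g <- gaussianSpectrum(870, sigma = 5, amp = 1, step = 1)
  got <- integrateBand(g, 860, 880)
  # oracle: trapezoid at 0.01 cm-1 over the chord-subtracted band
  xs <- seq(860, 880, by = 0.01)
  ys <- exp(-(xs - 870)^2 / 50)
  chord <- ys[1] + (xs - 860) * (ys[length(ys)] - ys[1]) / 20
  d <- ys - chord
  want <- sum(diff(xs) * (head(d, -1) + d[-1]) / 2)
  expect_lt(abs(got - want) / want, 0.005)

  far <- gaussianSpectrum(2900, sigma = 5)
  expect_equal(integrateBand(far, 860, 880), 0)
  expect_error(integrateBand(g, 300, 400), "outside the spectrum range")
})

test_that("peak height is the window maximum", {
  g <- gaussianSpectrum(871, sigma = 5)
  expect_equal(peakHeight(g, 871), 1, tolerance = 1e-6)
  expect_equal(peakHeight(flatSpectrum(0), 871), 0)

  # two overlapping Gaussians vs a dense-grid maximum oracle
  g2 <- wavenumbers(g)
  y2 <- exp(-(g2 - 865)^2 / (2 * 36)) + 0.8 * exp(-(g2 - 880)^2 / (2 * 36))
  s2 <- Spectrum(g2, y2, sampleId = "pair")
  xs <- seq(863, 879, by = 0.001)
  oracle <- max(exp(-(xs - 865)^2 / 72) + 0.8 * exp(-(xs - 880)^2 / 72))
  expect_lt(abs(peakHeight(s2, 871) - oracle), 1e-3)
})

test_that("peak position refines parabolically and guards tiny windows", {
  narrow <- gaussianSpectrum(1000, sigma = 2, step = 1)
  expect_equal(peakPosition(narrow, 980, 1020), 1000, tolerance = 1e-6)
  off <- gaussianSpectrum(1001.7, sigma = 6, step = 4)
  expect_lt(abs(peakPosition(off, 980, 1024) - 1001.7), 0.5)
  expect_error(peakPosition(off, 1000, 1004), "fewer than 3")
})

test_that("local maxima resolve the bone phosphate doublet", {
  bone <- synthesizeSpectrum(standardProfiles()[["Sus bone"]])
  lm <- localMaxima(bone, 500, 650)
  expect_gte(nrow(lm), 2)
  expect_lt(abs(lm$position[1] - 559), 1)
  expect_lt(abs(lm$position[2] - 600), 2)
  expect_gt(lm$height[1], lm$height[2])
  expect_gt(splittingFactor(bone), 1)
})

test_that("feature vector covers the 11 variables with flagged ratios", {
  # equal peaks at 871 and 1017 -> CO3PO4 exactly 1 by symmetry
  g <- seq(500, 4000, by = 1)
  y <- exp(-(g - 871)^2 / (2 * 25)) + exp(-(g - 1017)^2 / (2 * 25))
  s <- Spectrum(g, y, sampleId = "sym")
  fv <- computeFeatures(s)
  expect_equal(fv$CO3PO4, 1, tolerance = 1e-9)
  expect_named(fv, c("sample_id", mineralVariables, organicVariables))

  # a phosphate-free profile leaves the 1415/575 ratio undefined, not 0
  pro <- speciesProfile("no-apatite", c(chitin = 1, protein = 0.5),
                        weightSdLog = 0, driftAmplitude = 0, noiseSd = 0)
  sp <- synthesizeSpectrum(pro, grid = seq(4000, 500, by = -4))
  fp <- computeFeatures(sp)
  expect_true(is.na(fp$CO3PO4b))
  expect_true("CO3PO4b" %in% attr(fp, "undefined"))

  short <- gaussianSpectrum(2000, lo = 1000, hi = 4000)
  expect_error(computeFeatures(short), "does not cover.*PO4")
})

test_that("area features are additive and ratios respond to composition", {
  # components whose bands do not spill into each other's windows:
  # flooring under overlap breaks additivity by construction
  pa <- speciesProfile("a", c(bioapatite_PO4 = 0.7),
                       weightSdLog = 0, driftAmplitude = 0, noiseSd = 0)
  pb <- speciesProfile("b", c(protein = 0.5),
                       weightSdLog = 0, driftAmplitude = 0, noiseSd = 0)
  pab <- speciesProfile("ab", c(bioapatite_PO4 = 0.7, protein = 0.5),
                        weightSdLog = 0, driftAmplitude = 0, noiseSd = 0)
  grid <- seq(4000, 500, by = -4)
  fa <- computeFeatures(synthesizeSpectrum(pa, grid = grid))
  fb <- computeFeatures(synthesizeSpectrum(pb, grid = grid))
  fab <- computeFeatures(synthesizeSpectrum(pab, grid = grid))
  # additivity holds for surfaces whose components are individually
  # un-floored; ratios are not additive and are excluded
  areas <- c("PO4", "CO3", "CO3b", "CI", "amideI", "amideII", "collagen")
  for (v in areas) {
    sum2 <- fa[[v]] + fb[[v]]
    if (sum2 > 0.05)     # additivity asserted where the surface is material
      expect_lt(abs(fab[[v]] - sum2) / sum2, 0.01)
  }

  # monotonicity: more apatite -> larger PO4, smaller CO3/PO4 ratio
  vals <- vapply(c(0.5, 0.8, 1.2), function(w) {
    s <- synthesizeSpectrum(
      speciesProfile("m", c(bioapatite_PO4 = w, bioapatite_CO3 = 0.4),
                     weightSdLog = 0, driftAmplitude = 0, noiseSd = 0),
      grid = grid)
    f <- computeFeatures(s)
    c(f$PO4, f$CO3PO4)
  }, numeric(2))
  expect_true(all(diff(vals[1, ]) > 0))
  expect_true(all(diff(vals[2, ]) < 0))
})

test_that("carbonate-to-phosphate ratios are exactly scale invariant", {
  s <- synthesizeSpectrum(speciesProfiles()[["Crocuta crocuta"]],
                          grid = seq(4000, 500, by = -4),
                          driftAmplitude = 0, noiseSd = 0)
  f1 <- computeFeatures(s)
  s9 <- Spectrum(wavenumbers(s), absorbance(s) * 9.3, sampleId = "x")
  f9 <- computeFeatures(s9)
  expect_equal(f9$CO3PO4, f1$CO3PO4, tolerance = 1e-12)
  expect_equal(f9$CO3PO4b, f1$CO3PO4b, tolerance = 1e-12)
})
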