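test_that("the generator is linear, zero-consistent, and grid-valid", {
  grid <- seq(4000, 500, by = -4)
  zero <- synthesizeSpectrum(
    speciesProfile("none", c(calcite = 0), weightSdLog = 0,
                   driftAmplitude = 0, noiseSd = 0), grid = grid)
  expect_true(all(absorbance(zero) == 0))
  expect_error(speciesProfile("empty", numeric(0)), "empty profile")

  a <- synthesizeSpectrum(speciesProfile("a", c(calcite = 0.6, protein = 0.2),
                                         weightSdLog = 0, driftAmplitude = 0,
                                         noiseSd = 0), grid = grid)
  b <- synthesizeSpectrum(speciesProfile("b", c(calcite = 0.1, chitin = 0.9),
                                         weightSdLog = 0, driftAmplitude = 0,
                                         noiseSd = 0), grid = grid)
  ab <- synthesizeSpectrum(speciesProfile("ab", c(calcite = 0.7, protein = 0.2,
                                                  chitin = 0.9),
                                          weightSdLog = 0, driftAmplitude = 0,
                                          noiseSd = 0), grid = grid)
  expect_lt(max(abs(absorbance(ab) - absorbance(a) - absorbance(b))), 1e-12)
  expect_true(validObject(ab))
})

test_that("pure reference spectra peak at the library positions", {
  cal <- pureComponentSpectrum("calcite")
  w <- wavenumbers(cal); y <- absorbance(cal)
  sel <- w >= 1350 & w <= 1500
  expect_equal(w[sel][which.max(y[sel])], 1429)
  expect_equal(max(y[sel]), max(y))  # nu3 is the global maximum
})

test_that("cohort generation is deterministic and every spectrum is valid", {
  c1 <- generateCohort(nPerSpecies = 2, seed = 99)
  c2 <- generateCohort(nPerSpecies = 2, seed = 99)
  expect_identical(lapply(c1$spectra, absorbance),
                   lapply(c2$spectra, absorbance))
  expect_identical(c1$truth, c2$truth)
  expect_equal(length(c1$spectra), 2 * 4 * 4)   # samples x species x replicates
  expect_true(all(vapply(c1$spectra, validObject, logical(1))))
  expect_error(generateCohort(nPerSpecies = -3), "nPerSpecies")
})

test_that("species contrasts hold in the generated ground truth", {
  coh <- generateCohort(nPerSpecies = 50, seed = 14, replicates = 1)
  tr <- coh$truth
  sp <- coh$labels$species[match(tr$sample_id, coh$labels$sample_id)]
  chitinBy <- tapply(tr$chitin, sp, mean)
  expect_gt(chitinBy[["Proteles cristatus"]],
            5 * chitinBy[["Crocuta crocuta"]])
  po4By <- tapply(tr$PO4, sp, mean)
  expect_gt(po4By[["Crocuta crocuta"]], 10 * po4By[["Proteles cristatus"]])
})

test_that("planted cohorts reach the target correlations", {
  feat <- plantedFeatureCohort(n = 200, seed = 4)
  R <- cor(as.matrix(feat[, -1]))
  expect_lt(abs(R["amideI", "amideII"] - 0.99), 0.02)
  expect_lt(max(abs(R - plantedCorrelationDefault())), 1e-8)  # exact mode

  fs <- plantedFeatureCohort(n = 2000, seed = 4, mode = "stochastic")
  Rs <- cor(as.matrix(fs[, -1]))
  expect_lt(abs(Rs["amideI", "amideII"] - 0.99), 0.02)
  expect_lt(abs(Rs["CI", "CO3"] - 0.67), 0.1)
})

test_that("noise-free spectra reproduce their analytic band surfaces", {
  coh <- generateCohort(nPerSpecies = 2, seed = 6, replicates = 1,
                        noiseSd = 0, driftAmplitude = 0)
  ft <- computeFeatureTable(coh$spectra)
  for (i in seq_len(nrow(ft))) {
    tr <- coh$truth[coh$truth$sample_id == ft$sample_id[i], ]
    for (v in c(mineralVariables, organicVariables)) {
      want <- tr[[v]]; got <- ft[[v]][i]
      if (!is.na(want) && want > 0.05)
        expect_lt(abs(got - want) / want, 0.05)
    }
  }
})
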