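test_that("CSV spectra parse, re-orient, and round-trip to 1e-9", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  g <- seq(700, 4000, by = 4)
  writeLines(c("wavenumber,absorbance", paste(g, 0, sep = ",")), tmp)
  s <- readSpectrum(tmp, "csv")
  expect_s4_class(s, "Spectrum")
  expect_length(wavenumbers(s), 826)
  expect_true(all(absorbance(s) == 0))
  expect_true(all(diff(wavenumbers(s)) < 0))  # stored descending

  # round trip of a non-trivial spectrum, both orientations
  set.seed(11)
  s2 <- Spectrum(g, runif(length(g)), sampleId = "rt")
  writeSpectrum(s2, tmp, "csv")
  s3 <- readSpectrum(tmp, "csv", sampleId = "rt")
  expect_equal(wavenumbers(s3), wavenumbers(s2), tolerance = 1e-12)
  expect_lt(max(abs(absorbance(s3) - absorbance(s2))), 1e-9)
})

test_that("malformed CSV grids are rejected with informative errors", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("700,0.0", "704,0.1", "704,0.2", "712,0.0"), tmp)
  expect_error(readSpectrum(tmp, "csv"), "duplicated")
  writeLines(c("700,0.0", "704,abc"), tmp)
  expect_error(readSpectrum(tmp, "csv"), "line 2")
  writeLines(c("700,0.0,9", "704,0.1"), tmp)
  expect_error(readSpectrum(tmp, "csv"), "expected 2 fields")
})

test_that("JCAMP-DX round trip preserves both XYDATA and XYPOINTS forms", {
  set.seed(7)
  tmp <- withr::local_tempfile(fileext = ".jdx")
  even <- Spectrum(seq(700, 4000, by = 4), runif(826), sampleId = "even")
  writeSpectrum(even, tmp, "jcamp")
  expect_match(readLines(tmp, n = 30), "XYDATA", all = FALSE)
  back <- readSpectrum(tmp, "jcamp")
  expect_equal(sampleId(back), "even")
  expect_lt(max(abs(wavenumbers(back) - wavenumbers(even))), 1e-9)
  expect_lt(max(abs(absorbance(back) - absorbance(even))), 1e-9)

  g <- sort(c(seq(700, 4000, by = 7), 1001.5))   # uneven grid -> XYPOINTS
  uneven <- Spectrum(g, runif(length(g)), sampleId = "uneven")
  writeSpectrum(uneven, tmp, "jcamp")
  expect_match(readLines(tmp, n = 30), "XYPOINTS", all = FALSE)
  # grid tops out below 4000, so the coverage warning must fire
  expect_warning(back2 <- readSpectrum(tmp, "jcamp"), "narrower")
  expect_lt(max(abs(wavenumbers(back2) - wavenumbers(uneven))), 1e-9)
  expect_lt(max(abs(absorbance(back2) - absorbance(uneven))), 1e-9)
})

test_that("replicate averaging is an arithmetic mean and order-invariant", {
  s <- gaussianSpectrum(1500, sampleId = "a")
  expect_equal(absorbance(averageReplicates(list(s, s, s, s))), absorbance(s))

  f0 <- flatSpectrum(0, sampleId = "a"); f1 <- flatSpectrum(1, sampleId = "a")
  expect_true(all(absorbance(averageReplicates(list(f0, f1))) == 0.5))

  set.seed(3)
  reps <- lapply(1:4, function(i) {
    g <- seq(700, 4000, by = 4)
    Spectrum(g, rnorm(length(g)), sampleId = "a", replicate = i)
  })
  m1 <- averageReplicates(reps)
  m2 <- averageReplicates(rev(reps))
  expect_equal(absorbance(m1), absorbance(m2))
  prov <- provenance(m1)
  expect_equal(prov$n_replicates, 4L)
})

test_that("averaging four noisy replicates approaches the noise-free template", {
  coh <- generateCohort(profiles = speciesProfiles()["Crocuta crocuta"],
                        nPerSpecies = 1, seed = 5, replicates = 4,
                        noiseSd = 0.01, driftAmplitude = 0)
  avg <- averageReplicates(coh$spectra)
  # noise-free template rebuilt from the drawn ground-truth weights
  w <- provenance(coh$spectra[[1]])$truth$weights
  clean <- synthesizeSpectrum(
    speciesProfile("Crocuta crocuta", w, weightSdLog = 0,
                   driftAmplitude = 0, noiseSd = 0),
    grid = wavenumbers(avg))
  resid <- absorbance(avg) - absorbance(clean)
  expect_lt(sqrt(mean(resid^2)), 0.01 / sqrt(4) * 1.5)
})

test_that("averaging resamples differing grids and rejects bad input", {
  a <- gaussianSpectrum(1500, lo = 700, hi = 3000, step = 4, sampleId = "x")
  b <- gaussianSpectrum(1500, lo = 1000, hi = 4000, step = 8, sampleId = "x")
  m <- averageReplicates(list(a, b))
  expect_gte(min(wavenumbers(m)), 1000)
  expect_lte(max(wavenumbers(m)), 3000)
  expect_error(averageReplicates(list(a)), "at least two")
  c1 <- gaussianSpectrum(800, lo = 700, hi = 1200, sampleId = "x")
  c2 <- gaussianSpectrum(3000, lo = 2500, hi = 4000, sampleId = "x")
  expect_error(averageReplicates(list(c1, c2)), "disjoint")
  d <- gaussianSpectrum(1500, sampleId = "y")
  expect_error(averageReplicates(list(a, d)), "mixed sample ids")
})

test_that("packaged sample table has the published structure", {
  tab <- readSampleTable()
  expect_equal(nrow(tab), 18L)
  counts <- table(tab$species)
  expect_equal(as.integer(counts[hyaenidSpecies]), c(9L, 4L, 3L, 2L))
  kip5 <- tab[tab$code == "CC-kip5", ]
  expect_equal(kip5$length_mm, 28)
  expect_equal(kip5$width_mm, 38.5)
  expect_true(is.na(tab$length_mm[tab$code == "CC-kip"]))
  expect_true(is.na(tab$length_mm[tab$code == "CC-djib2"]))
  expect_equal(tab$width_mm[tab$code == "CC-djib2"], 19.5)
  expect_true(all(is.na(tab$length_mm[tab$code %in% c("HBp", "HBg")])))
  expect_equal(tab$size_raw[tab$code == "HBp"], "small specimen")
})

test_that("unknown species in a sample table is rejected with allowed values", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,country,region,collector,code,size,context",
               "Canis lupus,Kenya,X,Y,W-1,10x10,isolated"), tmp)
  expect_error(readSampleTable(tmp), "Canis lupus.*Crocuta crocuta")
})
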