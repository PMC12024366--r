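#' @include classify.R
NULL

#' Component band templates
#'
#' Reference band lists (centre, width, relative amplitude, shape) for the
#' spectral components the generator mixes: calcite and aragonite
#' carbonate, bioapatite phosphate and carbonate, protein (amides A/I/II/
#' III), lipid C-H stretch, chitin and keratin with its sulfur-group
#' region. Centres follow the packaged band assignments (calcite \eqn{\nu_3}
#' 1429, \eqn{\nu_2} 877/848, \eqn{\nu_4} 713; aragonite \eqn{\nu_3} 1471,
#' 858/844, 713/700, \eqn{\nu_1} 1083; apatite PO4 559/600, 961, 1020,
#' 1100 and CO3 878 with the coprolite carbonate band near 1420; amide I
#' ~1650, amide II ~1550, amide III 1240-1310, amide A ~3300; C-H stretch
#' 2850-2935). Widths default to roughly 12 cm\eqn{^{-1}} for sharp
#' mineral bands and 25 cm\eqn{^{-1}} for amides, so the 559/600
#' \eqn{\nu_4} doublet stays resolved at 4 cm\eqn{^{-1}} resolution.
#'
#' @return named list; each element is a data.frame with columns `center`,
#'   `width`, `amplitude`, `shape`.
#' @export
componentTemplates <- function() {
  band <- function(center, width, amplitude, shape = "gaussian")
    data.frame(center = center, width = width, amplitude = amplitude,
               shape = shape, stringsAsFactors = FALSE)
  list(
    calcite = band(c(1429, 877, 848, 713), c(30, 12, 12, 10),
                   c(1.0, 0.35, 0.12, 0.20)),
    aragonite = band(c(1471, 858, 844, 713, 700, 1083),
                     c(30, 12, 12, 10, 10, 10),
                     c(1.0, 0.30, 0.15, 0.15, 0.10, 0.05)),
    bioapatite_PO4 = band(c(1020, 1100, 961, 559, 600),
                          c(18, 20, 10, 14, 14),
                          c(1.0, 0.35, 0.45, 0.55, 0.30)),
    bioapatite_CO3 = band(c(1420, 1457, 878), c(30, 25, 12),
                          c(1.0, 0.50, 0.50)),
    protein = band(c(1650, 1550, 1275, 3300), c(25, 25, 30, 60),
                   c(1.0, 0.80, 0.40, 0.50)),
    lipid_CH = band(c(2924, 2852, 2956, 1740), c(18, 15, 12, 20),
                    c(1.0, 0.70, 0.40, 0.25)),
    chitin = band(c(1070, 1115, 1030, 1655, 1555, 3270, 2880),
                  c(35, 25, 20, 25, 25, 60, 20),
                  c(1.0, 0.60, 0.40, 0.70, 0.50, 0.40, 0.30)),
    keratin_S = band(c(1040, 1075, 1650, 1540, 3280),
                     c(25, 25, 25, 25, 60),
                     c(0.60, 0.40, 0.80, 0.70, 0.50))
  )
}

.bandValue <- function(x, center, width, amplitude, shape) {
  if (shape == "lorentzian")
    amplitude * width^2 / ((x - center)^2 + width^2)
  else
    amplitude * exp(-(x - center)^2 / (2 * width^2))
}

.bandIntegral <- function(lo, hi, center, width, amplitude, shape) {
  if (shape == "lorentzian")
    amplitude * width * (atan((hi - center) / width) - atan((lo - center) / width))
  else
    amplitude * width * sqrt(2 * pi) *
      (stats::pnorm((hi - center) / width) - stats::pnorm((lo - center) / width))
}

# analytic noise-free signal of a weighted component mixture
.mixtureSignal <- function(x, weights, templates) {
  y <- numeric(length(x))
  for (nm in names(weights)) {
    w <- weights[[nm]]
    if (w == 0) next
    tb <- templates[[nm]]
    if (is.null(tb)) stop("unknown component template: ", nm)
    for (k in seq_len(nrow(tb)))
      y <- y + w * .bandValue(x, tb$center[k], tb$width[k], tb$amplitude[k],
                              tb$shape[k])
  }
  y
}

.mixtureIntegral <- function(lo, hi, weights, templates) {
  total <- 0
  for (nm in names(weights)) {
    w <- weights[[nm]]
    if (w == 0) next
    tb <- templates[[nm]]
    for (k in seq_len(nrow(tb)))
      total <- total + w * .bandIntegral(lo, hi, tb$center[k], tb$width[k],
                                         tb$amplitude[k], tb$shape[k])
  }
  total
}

# closed-form ground truth of every band variable for given weights
.analyticFeatures <- function(weights, templates, library = bandLibrary(),
                              ratioFloor = 1e-4) {
  f <- function(x) .mixtureSignal(x, weights, templates)
  lib <- split(library, library$name)
  vals <- list()
  for (nm in c("PO4", "CO3", "CO3b", "CI", organicVariables)) {
    b <- lib[[nm]]
    bLo <- if (is.na(b$base_lo)) b$lo else b$base_lo
    bHi <- if (is.na(b$base_hi)) b$hi else b$base_hi
    I <- .mixtureIntegral(b$lo, b$hi, weights, templates)
    # chord anchored at the baseline points, integrated over the window
    cAt <- function(x) f(bLo) + (x - bLo) * (f(bHi) - f(bLo)) / (bHi - bLo)
    chord <- (cAt(b$lo) + cAt(b$hi)) / 2 * (b$hi - b$lo)
    vals[[nm]] <- max(I - chord, 0)
  }
  dense <- function(at, hw) {
    xs <- seq(at - hw, at + hw, by = 0.1)
    max(f(xs))
  }
  overall <- max(f(seq(700, 4000, by = 0.5)))
  ratio <- function(numAt, denAt, hw = 8) {
    den <- dense(denAt, hw)
    if (den < ratioFloor * overall) NA_real_ else dense(numAt, hw) / den
  }
  vals$CO3PO4 <- ratio(871, 1017)
  vals$CO3PO4b <- ratio(1415, 575)
  unlist(vals)[c(mineralVariables, organicVariables)]
}

#' Construct a species profile
#'
#' @param species label.
#' @param weights named numeric mean component weights (names must match
#'   [componentTemplates()] entries).
#' @param weightSdLog log-normal dispersion of the drawn weights.
#' @param driftAmplitude maximum |baseline drift| in AU (degree-3
#'   polynomial).
#' @param noiseSd additive Gaussian noise sd in AU.
#' @param replicates fragments per sample.
#' @return a [SpeciesProfile-class].
#' @export
speciesProfile <- function(species, weights, weightSdLog = 0.25,
                           driftAmplitude = 0.05, noiseSd = 0.005,
                           replicates = 4L) {
  if (!length(weights)) stop("empty profile: no component weights")
  new("SpeciesProfile", species = species, weights = weights,
      weightSdLog = weightSdLog, driftAmplitude = driftAmplitude,
      noiseSd = noiseSd, replicates = as.integer(replicates))
}

#' Default hyaenid species profiles
#'
#' Qualitative encodings of the compositional contrasts reported for the
#' four species: Crocuta mineral-dominant with weak organics; Hyaena
#' mineral-rich but relatively cholesterol-rich; Parahyaena a distinct
#' intermediate with more protein; Proteles organic/chitin-dominant with
#' weak-to-absent phosphate (weight 0.02 of the Crocuta apatite weight, so
#' carbonate-to-phosphate ratios stay finite).
#'
#' @return named list of [SpeciesProfile-class].
#' @export
speciesProfiles <- function() {
  list(
    `Crocuta crocuta` = speciesProfile("Crocuta crocuta", c(
      bioapatite_PO4 = 1.0, bioapatite_CO3 = 0.55, calcite = 0.10,
      protein = 0.08, lipid_CH = 0.05, chitin = 0.01, keratin_S = 0.05),
      weightSdLog = 0.35),
    `Hyaena hyaena` = speciesProfile("Hyaena hyaena", c(
      bioapatite_PO4 = 0.95, bioapatite_CO3 = 0.50, calcite = 0.09,
      protein = 0.10, lipid_CH = 0.14, chitin = 0.01, keratin_S = 0.08)),
    `Parahyaena brunnea` = speciesProfile("Parahyaena brunnea", c(
      bioapatite_PO4 = 0.55, bioapatite_CO3 = 0.20, calcite = 0.05,
      protein = 0.40, lipid_CH = 0.10, chitin = 0.06, keratin_S = 0.18)),
    `Proteles cristatus` = speciesProfile("Proteles cristatus", c(
      bioapatite_PO4 = 0.02, bioapatite_CO3 = 0.02, calcite = 0.02,
      protein = 0.60, lipid_CH = 0.30, chitin = 1.0, keratin_S = 0.10))
  )
}

#' Reference standard profiles
#'
#' Noise- and drift-free pure (or near-pure) profiles emulating the
#' measurement standards: fresh bone (apatite plus its organic matrix) and
#' the organic standards cholesterol, chitin, keratin and collagen.
#'
#' @return named list of [SpeciesProfile-class].
#' @export
standardProfiles <- function() {
  std <- function(species, weights)
    speciesProfile(species, weights, weightSdLog = 0, driftAmplitude = 0,
                   noiseSd = 0, replicates = 1L)
  list(
    `Sus bone` = std("Sus bone", c(bioapatite_PO4 = 1.0,
                                   bioapatite_CO3 = 0.35, protein = 0.50,
                                   lipid_CH = 0.10)),
    `cholesterol std` = std("cholesterol std", c(lipid_CH = 1.0)),
    `chitin std` = std("chitin std", c(chitin = 1.0)),
    `keratin std` = std("keratin std", c(keratin_S = 1.0)),
    `collagen std` = std("collagen std", c(protein = 1.0))
  )
}

#' Noise-free pure component spectrum
#'
#' @param component a [componentTemplates()] name.
#' @param grid wavenumber grid (default 4000-700 cm\eqn{^{-1}} at 1
#'   cm\eqn{^{-1}}).
#' @return a [Spectrum-class] with generator ground truth in provenance.
#' @export
pureComponentSpectrum <- function(component, grid = seq(4000, 500, by = -1)) {
  w <- setNames(1, component)
  synthesizeSpectrum(speciesProfile(component, w, weightSdLog = 0,
                                    driftAmplitude = 0, noiseSd = 0,
                                    replicates = 1L),
                     grid = grid)
}

#' Synthesize one spectrum from a profile
#'
#' Absorbance = weighted sum of component band templates + degree-3
#' polynomial baseline drift + additive Gaussian noise. Ground truth (the
#' weights used, closed-form band-variable values, and the drift vector)
#' is returned in `provenance(s)$truth`.
#'
#' @param profile a [SpeciesProfile-class].
#' @param grid wavenumber grid covering 700-4000 cm\eqn{^{-1}} (1
#'   cm\eqn{^{-1}} default for noise-free references; cohorts use 4
#'   cm\eqn{^{-1}}).
#' @param seed optional seed (set when reproducibility of a single call is
#'   wanted; [generateCohort()] manages the stream itself).
#' @param jitterWeights draw weights log-normally around the profile means
#'   (FALSE uses the means as-is).
#' @param noiseSd,driftAmplitude overrides of the profile settings.
#' @param sampleId,replicate identifiers for the result.
#' @param templates component template list.
#' @return a [Spectrum-class].
#' @export
synthesizeSpectrum <- function(profile, grid = seq(4000, 500, by = -1),
                               seed = NULL, jitterWeights = FALSE,
                               noiseSd = NULL, driftAmplitude = NULL,
                               sampleId = profile@species, replicate = 0L,
                               templates = componentTemplates()) {
  stopifnot(is(profile, "SpeciesProfile"))
  if (!length(profile@weights)) stop("empty profile: no component weights")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(noiseSd)) noiseSd <- profile@noiseSd
  if (is.null(driftAmplitude)) driftAmplitude <- profile@driftAmplitude
  w <- profile@weights
  if (jitterWeights && profile@weightSdLog > 0) {
    sdl <- profile@weightSdLog
    w <- w * stats::rlnorm(length(w), meanlog = -sdl^2 / 2, sdlog = sdl)
  }
  signal <- .mixtureSignal(grid, as.list(w), templates)
  drift <- numeric(length(grid))
  if (driftAmplitude > 0) {
    u <- (grid - mean(range(grid))) / (diff(range(grid)) / 2)
    co <- rnorm(4)
    d <- co[1] + co[2] * u + co[3] * u^2 + co[4] * u^3
    drift <- d / max(abs(d)) * driftAmplitude
  }
  noise <- if (noiseSd > 0) rnorm(length(grid), 0, noiseSd) else numeric(length(grid))
  truth <- list(weights = w,
                features = .analyticFeatures(as.list(w), templates),
                drift = drift)
  Spectrum(grid, signal + drift + noise, sampleId = sampleId,
           replicate = replicate, provenance = list(truth = truth))
}

#' Generate a labelled synthetic cohort
#'
#' Draws `nPerSpecies` samples per profile; each sample has one weight draw
#' and `replicates` fragment spectra with independent baseline drift and
#' noise, for replicate-averaging workflows. Fully reproducible under a
#' fixed seed (R's default Mersenne-Twister stream; all draws go through
#' this one stream in a fixed order).
#'
#' @param profiles named list of [SpeciesProfile-class].
#' @param nPerSpecies samples per profile (>= 1).
#' @param seed integer seed.
#' @param grid wavenumber grid (4 cm\eqn{^{-1}} instrument-like default).
#' @param replicates,noiseSd,driftAmplitude optional overrides applied to
#'   every profile.
#' @return list with `spectra` (flat list of replicate [Spectrum-class]),
#'   `labels` (data.frame `sample_id`, `species`) and `truth` (data.frame
#'   of drawn weights and closed-form band-variable values per sample).
#' @export
generateCohort <- function(profiles = speciesProfiles(), nPerSpecies = 10,
                           seed = 1, grid = seq(4000, 500, by = -4),
                           replicates = NULL, noiseSd = NULL,
                           driftAmplitude = NULL) {
  if (nPerSpecies < 1) stop("nPerSpecies must be >= 1")
  set.seed(seed)
  templates <- componentTemplates()
  spectra <- list()
  labels <- list()
  truth <- list()
  for (profile in profiles) {
    nr <- if (is.null(replicates)) profile@replicates else as.integer(replicates)
    for (i in seq_len(nPerSpecies)) {
      sid <- sprintf("%s_%02d", gsub(" ", "_", profile@species), i)
      w <- profile@weights
      if (profile@weightSdLog > 0) {
        sdl <- profile@weightSdLog
        w <- w * stats::rlnorm(length(w), meanlog = -sdl^2 / 2, sdlog = sdl)
      }
      base <- speciesProfile(profile@species, w, weightSdLog = 0,
                             driftAmplitude = if (is.null(driftAmplitude))
                               profile@driftAmplitude else driftAmplitude,
                             noiseSd = if (is.null(noiseSd)) profile@noiseSd
                               else noiseSd,
                             replicates = nr)
      reps <- lapply(seq_len(nr), function(r)
        synthesizeSpectrum(base, grid = grid, sampleId = sid, replicate = r,
                           templates = templates))
      spectra <- c(spectra, reps)
      labels[[sid]] <- data.frame(sample_id = sid, species = profile@species,
                                  stringsAsFactors = FALSE)
      truth[[sid]] <- data.frame(
        sample_id = sid,
        as.list(setNames(w, paste0("weight_", names(w)))),
        as.list(.analyticFeatures(as.list(w), templates)),
        stringsAsFactors = FALSE, check.names = FALSE)
    }
  }
  list(spectra = spectra,
       labels = do.call(rbind, c(labels, make.row.names = FALSE)),
       truth = do.call(rbind, c(truth, make.row.names = FALSE)))
}

#' Default planted correlation structure
#'
#' Target correlation matrix for [plantedFeatureCohort()]. The reported
#' redundancies among the band variables are planted directly (CI-CO3
#' 0.67, CI-PO4 0.56, CO3b-CO3PO4b 0.50, amide I-amide II 0.99); the
#' remaining non-zero entries encode moderate redundancy between measures
#' that share a physical driver (the two carbonate-to-phosphate ratios,
#' the carbonate surfaces, the protein amide surfaces and the amide III
#' proxy, chitin and the amide-bearing biopolymers), which also makes the
#' discard order of the selection rule determinate.
#'
#' @return 11 x 11 correlation matrix over
#'   `c(mineralVariables, organicVariables)`.
#' @export
plantedCorrelationDefault <- function() {
  vars <- c(mineralVariables, organicVariables)
  R <- diag(length(vars))
  dimnames(R) <- list(vars, vars)
  set <- function(a, b, r) { R[a, b] <<- r; R[b, a] <<- r }
  set("CI", "CO3", 0.67); set("CI", "PO4", 0.56)
  set("CO3b", "CO3PO4b", 0.50)
  set("CO3b", "CO3PO4", 0.45); set("CO3PO4", "CO3PO4b", 0.40)
  set("CO3b", "CO3", 0.20); set("CO3PO4", "CO3", 0.15)
  set("amideI", "amideII", 0.99)
  set("collagen", "amideII", 0.55); set("collagen", "amideI", 0.48)
  set("cholesterol", "amideII", 0.25); set("cholesterol", "amideI", 0.20)
  set("chitin", "collagen", 0.35)
  R
}

#' Feature cohort with a planted correlation structure
#'
#' Draws band-variable vectors directly (bypassing spectra) with a target
#' correlation matrix, for testing the variable-selection machinery. In
#' `"exact"` mode the sample correlation matrix equals the target exactly
#' (the draw is whitened empirically before colouring); `"stochastic"`
#' mode colours an iid draw, so empirical correlations fluctuate around
#' the target by about n^-1/2.
#'
#' @param n samples (must exceed the number of variables).
#' @param seed integer seed.
#' @param R target correlation matrix (default
#'   [plantedCorrelationDefault()]).
#' @param mode `"exact"` or `"stochastic"`.
#' @param means,sds per-variable location/scale on the feature scale.
#' @return data.frame `sample_id` plus one column per variable.
#' @export
plantedFeatureCohort <- function(n = 200, seed = 1,
                                 R = plantedCorrelationDefault(),
                                 mode = c("exact", "stochastic"),
                                 means = NULL, sds = NULL) {
  mode <- match.arg(mode)
  vars <- colnames(R)
  p <- length(vars)
  if (n <= p + 1) stop("n must exceed the number of variables")
  if (is.null(means))
    means <- setNames(c(4, 1.5, 1.2, 2.5, 0.5, 0.8, 2, 1, 0.8, 1, 0.6)[seq_len(p)],
                      vars)
  if (is.null(sds)) sds <- 0.2 * means
  set.seed(seed)
  Z <- matrix(rnorm(n * p), n, p)
  if (mode == "exact") {
    Z <- scale(Z, center = TRUE, scale = FALSE)
    Z <- Z %*% solve(chol(cov(Z)))
  }
  X <- Z %*% chol(R)
  X <- sweep(sweep(X, 2, apply(X, 2, sd) / sds[vars], "/"), 2, means[vars], "+")
  # recentre exactly on the requested means
  X <- sweep(X, 2, colMeans(X) - means[vars], "-")
  colnames(X) <- vars
  data.frame(sample_id = sprintf("synth%03d", seq_len(n)), X,
             stringsAsFactors = FALSE)
}
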