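#' @include synthetic.R
NULL

#' Read a pipeline run configuration
#'
#' YAML configuration with blocks `seed`, `output_dir`, `generator`
#' (synthetic input: `type` `"cohort"` or `"planted"`, `n_per_species` or
#' `n`, optional `include_standards`, `noise_sd`, `drift_amplitude`),
#' `inputs` (measured input: `spectra_dir`, `labels`, `format`),
#' `preprocess` (passed to [preprocessConfig()]), `candidates`
#' (`mineral`, `organic`) and `classify_test` (`n_per_species`). Exactly
#' one of `generator`/`inputs` must be present.
#'
#' @param path YAML file.
#' @return config list (class `coproRunConfig`) with defaults filled in.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$config_text <- paste(readLines(path, warn = FALSE), collapse = "\n")
  validateRunConfig(cfg)
}

#' @rdname readRunConfig
#' @param cfg a config list (as from [yaml::read_yaml()]).
#' @export
validateRunConfig <- function(cfg) {
  if (is.null(cfg$generator) && is.null(cfg$inputs))
    stop("config error: one of 'generator' or 'inputs' is required")
  if (!is.null(cfg$generator) && !is.null(cfg$inputs))
    stop("config error: 'generator' and 'inputs' are mutually exclusive")
  cfg$seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  if (is.null(cfg$output_dir)) cfg$output_dir <- "coproFTIR_run"
  if (is.null(cfg$candidates))
    cfg$candidates <- list(mineral = mineralVariables,
                           organic = organicVariables)
  pp <- cfg$preprocess
  if (is.null(pp)) pp <- list()
  cfg$preprocess <- do.call(preprocessConfig,
                            pp[intersect(names(pp),
                                         names(formals(preprocessConfig)))])
  if (is.null(cfg$config_text))
    cfg$config_text <- paste(deparse(cfg[setdiff(names(cfg), "config_text")]),
                             collapse = "\n")
  class(cfg) <- "coproRunConfig"
  cfg
}

.logStage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

.writeMatrixCSV <- function(m, path) {
  df <- data.frame(name = rownames(m), m, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
}

.writePCA <- function(pca, prefix) {
  .writeMatrixCSV(pca@loadings, paste0(prefix, "_loadings.csv"))
  .writeMatrixCSV(pca@scores, paste0(prefix, "_scores.csv"))
  write.csv(data.frame(component = seq_along(pca@explainedFraction),
                       explained_fraction = pca@explainedFraction),
            paste0(prefix, "_explained.csv"), row.names = FALSE)
}

.writeSelectionReport <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  kv <- function(key, val) writeLines(paste0(key, ": ", val), con)
  kv("mineral_selected", paste(report@mineralSelected, collapse = " "))
  kv("organic_selected", paste(report@organicSelected, collapse = " "))
  kv("mineral_discard_order", paste(report@mineralDiscarded, collapse = " "))
  kv("organic_discard_order", paste(report@organicDiscarded, collapse = " "))
  writeMat <- function(key, m) {
    kv(key, "")
    if (!length(m)) return()
    writeLines(paste0("  vars: ", paste(colnames(m), collapse = ",")), con)
    for (i in seq_len(nrow(m)))
      writeLines(paste0("  ", rownames(m)[i], ": ",
                        paste(formatC(m[i, ], format = "g", digits = 6),
                              collapse = ",")), con)
  }
  writeMat("mineral_correlation", report@mineralCorrelation)
  writeMat("organic_correlation", report@organicCorrelation)
  if (length(report@fullSpectrumCorrelation))
    writeMat("full_spectrum_correlation", report@fullSpectrumCorrelation)
}

.writeDomains <- function(domains, overlap, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (d in domains) {
    ring <- paste(sprintf("%.6g %.6g", d@vertices[, 1], d@vertices[, 2]),
                  collapse = ", ")
    writeLines(sprintf("%s | area=%.6g | centroid=%.6g %.6g | POLYGON((%s))",
                       d@species, d@area, d@centroid[1], d@centroid[2], ring),
               con)
  }
  writeLines("# pairwise overlap", con)
  for (i in seq_len(nrow(overlap)))
    writeLines(sprintf("%s ~ %s | overlap=%.6g | a_in_b=%s | b_in_a=%s",
                       overlap$a[i], overlap$b[i], overlap$overlap_area[i],
                       overlap$a_in_b[i], overlap$b_in_a[i]), con)
}

# read a directory of spectra plus a labels CSV (sample_id,species,
# optional replicate column); replicates of one sample are averaged
.ingestMeasured <- function(inputs, cfg) {
  labs <- read.csv(inputs$labels, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "file") %in% names(labs)))
    stop("labels CSV needs 'sample_id' and 'file' columns")
  dialect <- if (identical(inputs$format, "jcamp")) "jcamp" else "csv"
  bySample <- split(labs, labs$sample_id)
  spectra <- lapply(bySample, function(rows) {
    reps <- lapply(seq_len(nrow(rows)), function(i)
      readSpectrum(file.path(inputs$spectra_dir, rows$file[i]),
                   dialect = dialect, sampleId = rows$sample_id[i],
                   replicate = i - 1L))
    if (length(reps) > 1L) averageReplicates(reps) else reps[[1]]
  })
  species <- vapply(bySample, function(rows)
    as.character(rows$species[1]), character(1))
  list(spectra = unname(spectra),
       labels = data.frame(sample_id = names(bySample), species = species,
                           stringsAsFactors = FALSE, row.names = NULL))
}

#' Run the full pipeline
#'
#' Orchestrates ingest (measured spectra or synthetic generator),
#' preprocessing and replicate averaging, band-feature computation, the
#' three-step variable selection, the five PCAs (mineral and organic
#' candidates each with and without standards, plus the combined selected
#' set), species domains, and optional classification of a held-out test
#' cohort. All numeric outputs are written under `output_dir` and are
#' byte-identical across reruns with the same config and seed.
#'
#' @param config a config list/path (see [readRunConfig()]).
#' @return run report list (invisible elements: `features`, `selection`,
#'   `pcas`, `domains`, `overlap`, `classification`, `output_dir`,
#'   `config_hash`).
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  if (!inherits(config, "coproRunConfig")) config <- validateRunConfig(config)
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  hash <- fnv1a32(config$config_text)
  failed <- file.path(out, "FAILED")
  if (file.exists(failed)) unlink(failed)
  stage <- "validate"
  report <- try({
    writeLines(c(paste0("seed: ", config$seed), paste0("config_hash: ", hash)),
               file.path(out, "run_info.txt"))

    stage <- "ingest"
    planted <- FALSE
    spectra <- NULL
    standardsIds <- character(0)
    if (!is.null(config$generator)) {
      g <- config$generator
      if (identical(g$type, "planted")) {
        planted <- TRUE
        .logStage(stage, "planted feature cohort, n=", g$n %||% 200)
        features <- plantedFeatureCohort(n = g$n %||% 200, seed = config$seed)
        labels <- data.frame(sample_id = features$sample_id,
                             species = "synthetic", stringsAsFactors = FALSE)
      } else {
        .logStage(stage, "synthetic cohort, n/species=", g$n_per_species %||% 10)
        coh <- generateCohort(nPerSpecies = g$n_per_species %||% 10,
                              seed = config$seed,
                              noiseSd = g$noise_sd,
                              driftAmplitude = g$drift_amplitude)
        labels <- coh$labels
        grouped <- split(coh$spectra,
                         vapply(coh$spectra, sampleId, character(1)))
        spectra <- lapply(labels$sample_id, function(sid) {
          reps <- grouped[[sid]]
          if (length(reps) > 1L) averageReplicates(reps) else reps[[1]]
        })
        if (isTRUE(g$include_standards)) {
          stds <- lapply(standardProfiles(), synthesizeSpectrum,
                         grid = seq(4000, 500, by = -4))
          spectra <- c(spectra, unname(stds))
          standardsIds <- names(standardProfiles())
          labels <- rbind(labels,
                          data.frame(sample_id = standardsIds,
                                     species = standardsIds,
                                     stringsAsFactors = FALSE))
        }
      }
    } else {
      ing <- .ingestMeasured(config$inputs, config)
      spectra <- ing$spectra
      labels <- ing$labels
      standardsIds <- intersect(labels$sample_id, config$inputs$standards %||% character(0))
    }

    if (!planted) {
      stage <- "preprocess"
      .logStage(stage, config$preprocess$baseline_method, " baseline, ",
                config$preprocess$normalization, " normalization")
      spectra <- lapply(spectra, preprocessSpectrum, cfg = config$preprocess)
      stage <- "features"
      features <- computeFeatureTable(spectra)
    }
    write.csv(features, file.path(out, "features.csv"), row.names = FALSE)

    stage <- "selection"
    selection <- selectVariables(features,
                                 mineralCandidates = config$candidates$mineral,
                                 organicCandidates = config$candidates$organic,
                                 spectra = spectra,
                                 standards = if (length(standardsIds)) standardsIds)
    .writeSelectionReport(selection, file.path(out, "selection_report.txt"))
    .logStage(stage, "mineral {", paste(selection@mineralSelected, collapse = ","),
              "} organic {", paste(selection@organicSelected, collapse = ","), "}")

    stage <- "pca"
    isStd <- features$sample_id %in% standardsIds
    copro <- features[!isStd, , drop = FALSE]
    combined <- c(selection@mineralSelected, selection@organicSelected)
    pcas <- list(
      mineral_with_standards = if (any(isStd))
        runPCA(features, config$candidates$mineral),
      mineral_without_standards = runPCA(copro, config$candidates$mineral),
      organic_with_standards = if (any(isStd))
        runPCA(features, config$candidates$organic),
      organic_without_standards = runPCA(copro, config$candidates$organic),
      combined = runPCA(copro, combined))
    for (nm in names(pcas))
      if (!is.null(pcas[[nm]]))
        .writePCA(pcas[[nm]], file.path(out, paste0("pca_", nm)))

    stage <- "domains"
    pcaC <- pcas$combined
    labs <- labels$species[match(pcaC@sampleIds, labels$sample_id)]
    domains <- buildDomains(pcaC, labs)
    overlap <- domainOverlap(domains)
    .writeDomains(domains, overlap, file.path(out, "domains.txt"))

    stage <- "classification"
    classification <- NULL
    ct <- config$classify_test
    if (!planted && !is.null(ct) && (ct$n_per_species %||% 0) > 0) {
      ref <- fitReference(copro,
                          labels$species[match(copro$sample_id, labels$sample_id)],
                          variables = combined)
      test <- generateCohort(nPerSpecies = ct$n_per_species,
                             seed = config$seed + 1L)
      grouped <- split(test$spectra, vapply(test$spectra, sampleId, character(1)))
      testSpec <- lapply(test$labels$sample_id, function(sid) {
        reps <- grouped[[sid]]
        if (length(reps) > 1L) averageReplicates(reps) else reps[[1]]
      })
      testFeat <- computeFeatureTable(testSpec, cfg = config$preprocess)
      pred <- vapply(seq_len(nrow(testFeat)), function(i) {
        res <- try(classifySample(testFeat[i, , drop = FALSE], ref),
                   silent = TRUE)
        if (inherits(res, "try-error")) NA_character_ else res$species
      }, character(1))
      classification <- data.frame(sample_id = testFeat$sample_id,
                                   truth = test$labels$species,
                                   predicted = pred,
                                   stringsAsFactors = FALSE)
      write.csv(classification, file.path(out, "classification.csv"),
                row.names = FALSE)
      acc <- mean(classification$predicted == classification$truth,
                  na.rm = FALSE)
      .logStage(stage, sprintf("accuracy %.3f", acc))
    }

    list(features = features, selection = selection, pcas = pcas,
         domains = domains, overlap = overlap,
         classification = classification, output_dir = out,
         config_hash = hash, seed = config$seed)
  }, silent = TRUE)
  if (inherits(report, "try-error")) {
    writeLines(c(paste0("stage: ", stage),
                 paste0("error: ", attr(report, "condition")$message)),
               failed)
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 attr(report, "condition")$message), call. = FALSE)
  }
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
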