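#' @include AllClasses.R
NULL

#' The four extant hyaenid species
#'
#' Closed set of species labels accepted in sample metadata.
#' @export
hyaenidSpecies <- c("Crocuta crocuta", "Hyaena hyaena",
                    "Parahyaena brunnea", "Proteles cristatus")

.FULL_RANGE <- c(700, 4000)  # acquisition range needed for the full pipeline

.checkCoverage <- function(s, where) {
  w <- range(s@wavenumbers)
  if (w[1] > .FULL_RANGE[1] || w[2] < .FULL_RANGE[2])
    warning(sprintf(
      "%s: spectrum covers %.0f-%.0f cm-1, narrower than the %d-%d cm-1 full-pipeline range",
      where, w[1], w[2], .FULL_RANGE[1], .FULL_RANGE[2]), call. = FALSE)
  invisible(s)
}

#' Read a spectrum from disk
#'
#' Reads a two-column CSV (wavenumber, absorbance; header optional) or a
#' JCAMP-DX file (`##XYDATA=(X++(Y..Y))` with AFFN values, or
#' `##XYPOINTS=(XY..XY)`). The grid is re-oriented to descending
#' wavenumber; duplicated or non-monotonic grids are rejected. A warning is
#' issued when the acquisition range does not cover 700-4000
#' cm\eqn{^{-1}}.
#'
#' @param path file to read.
#' @param dialect `"csv"` or `"jcamp"`; `NULL` guesses from the extension
#'   (`.jdx`/`.dx` are JCAMP, anything else CSV).
#' @param sampleId,replicate identifiers attached to the result; default
#'   sampleId is the file base name (or the JCAMP `##TITLE`).
#' @return a [Spectrum-class].
#' @seealso [writeSpectrum()], [averageReplicates()]
#' @export
readSpectrum <- function(path, dialect = NULL, sampleId = NULL, replicate = 0L) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(dialect)) {
    dialect <- if (grepl("\\.(jdx|dx)$", tolower(path))) "jcamp" else "csv"
  }
  dialect <- match.arg(dialect, c("csv", "jcamp"))
  s <- if (dialect == "csv") .readSpectrumCSV(path) else .readSpectrumJCAMP(path)
  if (!is.null(sampleId)) s@sampleId <- as.character(sampleId)
  s@replicate <- as.integer(replicate)
  s@provenance$source <- path
  validObject(s)
  .checkCoverage(s, path)
  s
}

.readSpectrumCSV <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty CSV spectrum file: ", path)
  first <- strsplit(lines[1], ",")[[1]]
  skip <- suppressWarnings(anyNA(as.numeric(first)))
  rows <- lines[(1 + skip):length(lines)]
  parts <- strsplit(rows, ",")
  nf <- lengths(parts)
  if (any(nf != 2L))
    stop(sprintf("CSV parse failure in %s at line %d: expected 2 fields, found %d",
                 path, which(nf != 2L)[1] + skip, nf[nf != 2L][1]))
  vals <- suppressWarnings(vapply(parts, function(p) as.numeric(trimws(p)), numeric(2)))
  if (anyNA(vals)) {
    bad <- which(colSums(is.na(vals)) > 0)[1]
    stop(sprintf("CSV parse failure in %s at line %d: non-numeric value", path, bad + skip))
  }
  Spectrum(vals[1, ], vals[2, ],
           sampleId = sub("\\.[^.]*$", "", basename(path)))
}

.readSpectrumJCAMP <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lab <- grepl("^##", lines)
  labels <- list()
  for (ln in lines[lab]) {
    kv <- sub("^##", "", ln)
    key <- toupper(gsub("[ _-]", "", sub("=.*$", "", kv)))
    labels[[key]] <- trimws(sub("^[^=]*=", "", kv))
  }
  num <- function(key, default = NA_real_) {
    v <- labels[[key]]
    if (is.null(v)) default else as.numeric(v)
  }
  xf <- num("XFACTOR", 1); yf <- num("YFACTOR", 1)
  start <- grep("^##(XYDATA|XYPOINTS)", lines)
  if (!length(start)) stop("no ##XYDATA or ##XYPOINTS record in ", path)
  start <- start[1]
  body <- lines[(start + 1):length(lines)]
  endAt <- grep("^##", body)
  if (length(endAt)) body <- body[seq_len(endAt[1] - 1L)]
  body <- trimws(body[nzchar(trimws(body))])
  if (!length(body)) stop("empty data block in ", path)

  if (grepl("^##XYDATA", lines[start])) {
    npoints <- num("NPOINTS"); firstx <- num("FIRSTX"); lastx <- num("LASTX")
    if (anyNA(c(npoints, firstx, lastx)))
      stop("JCAMP XYDATA requires NPOINTS, FIRSTX and LASTX labels: ", path)
    dx <- (lastx - firstx) / (npoints - 1)
    x <- numeric(0); y <- numeric(0)
    for (i in seq_along(body)) {
      toks <- strsplit(body[i], "[,;[:space:]]+")[[1]]
      vals <- suppressWarnings(as.numeric(toks[nzchar(toks)]))
      if (anyNA(vals) || length(vals) < 2)
        stop(sprintf("JCAMP parse failure in %s, data line %d", path, i))
      yi <- vals[-1]
      x <- c(x, vals[1] * xf + dx * (seq_along(yi) - 1L))
      y <- c(y, yi * yf)
    }
    if (length(y) != npoints)
      stop(sprintf("JCAMP %s: NPOINTS=%d but %d values read", path, npoints, length(y)))
  } else {
    toks <- unlist(strsplit(body, "[;[:space:]]+"))
    toks <- toks[nzchar(toks)]
    pairs <- strsplit(toks, ",")
    if (any(lengths(pairs) != 2L))
      stop("JCAMP XYPOINTS parse failure in ", path, ": expected x,y pairs")
    vals <- suppressWarnings(vapply(pairs, as.numeric, numeric(2)))
    if (anyNA(vals)) stop("JCAMP XYPOINTS parse failure in ", path, ": non-numeric value")
    x <- vals[1, ] * xf; y <- vals[2, ] * yf
  }
  title <- labels[["TITLE"]]
  Spectrum(x, y, sampleId = if (is.null(title) || !nzchar(title))
    sub("\\.[^.]*$", "", basename(path)) else title)
}

#' Write a spectrum to disk
#'
#' CSV output is two columns with a header; JCAMP-DX output uses
#' `(X++(Y..Y))` AFFN encoding for evenly spaced grids and `XYPOINTS`
#' otherwise. Values are written with enough digits for a 1e-9 AU
#' round trip.
#'
#' @param s a [Spectrum-class].
#' @param path output file.
#' @param dialect `"csv"` or `"jcamp"`.
#' @return `path`, invisibly.
#' @export
writeSpectrum <- function(s, path, dialect = c("csv", "jcamp")) {
  dialect <- match.arg(dialect)
  stopifnot(is(s, "Spectrum"))
  w <- s@wavenumbers; a <- s@absorbance
  fmt <- function(v) sprintf("%.15g", v)
  if (dialect == "csv") {
    writeLines(c("wavenumber,absorbance", paste(fmt(w), fmt(a), sep = ",")), path)
    return(invisible(path))
  }
  d <- diff(w)
  even <- max(abs(d - d[1])) < 1e-9 * max(abs(d))
  hdr <- c(
    paste0("##TITLE=", if (is.na(s@sampleId)) "" else s@sampleId),
    "##JCAMP-DX=4.24",
    "##DATA TYPE=INFRARED SPECTRUM",
    "##XUNITS=1/CM",
    "##YUNITS=ABSORBANCE",
    "##XFACTOR=1",
    "##YFACTOR=1",
    paste0("##FIRSTX=", fmt(w[1])),
    paste0("##LASTX=", fmt(w[length(w)])),
    paste0("##NPOINTS=", length(w)),
    paste0("##FIRSTY=", fmt(a[1]))
  )
  if (even) {
    block <- vapply(seq(1, length(w), by = 4L), function(i) {
      j <- min(i + 3L, length(w))
      paste(c(fmt(w[i]), fmt(a[i:j])), collapse = " ")
    }, character(1))
    writeLines(c(hdr, "##XYDATA=(X++(Y..Y))", block, "##END="), path)
  } else {
    writeLines(c(hdr, "##XYPOINTS=(XY..XY)",
                 paste(fmt(w), fmt(a), sep = ","), "##END="), path)
  }
  invisible(path)
}

# linear resampling onto an explicit descending grid
resampleSpectrum <- function(s, grid) {
  a <- approx(s@wavenumbers, s@absorbance, xout = grid, rule = 1)$y
  if (anyNA(a)) stop("resampling grid extends beyond the spectrum range")
  Spectrum(grid, a, sampleId = s@sampleId, replicate = s@replicate,
           provenance = s@provenance)
}

#' Average replicate spectra of one sample
#'
#' Pointwise arithmetic mean of two or more replicate (fragment) spectra of
#' the same sample, mirroring instrument practice of measuring several
#' fragments per specimen. Differing grids are first linearly interpolated
#' onto their common (intersection) range at the coarsest step among the
#' inputs.
#'
#' @param spectra list of [Spectrum-class] with identical `sampleId`.
#' @return a [Spectrum-class]; `provenance$n_replicates` records the
#'   replicate-set size.
#' @export
averageReplicates <- function(spectra) {
  if (!is.list(spectra) || length(spectra) < 2L)
    stop("need at least two replicate spectra")
  stopifnot(all(vapply(spectra, is, logical(1), "Spectrum")))
  ids <- unique(vapply(spectra, sampleId, character(1)))
  if (length(ids) != 1L)
    stop("mixed sample ids in replicate set: ", paste(ids, collapse = ", "))
  grids <- lapply(spectra, wavenumbers)
  same <- all(vapply(grids[-1], function(g)
    length(g) == length(grids[[1]]) && all(g == grids[[1]]), logical(1)))
  if (same) {
    grid <- grids[[1]]
  } else {
    lo <- max(vapply(grids, min, numeric(1)))
    hi <- min(vapply(grids, max, numeric(1)))
    if (lo >= hi) stop("replicate spectra have disjoint wavenumber ranges")
    step <- max(vapply(grids, function(g) stats::median(abs(diff(g))), numeric(1)))
    grid <- seq(hi, lo, by = -step)
    spectra <- lapply(spectra, resampleSpectrum, grid = grid)
  }
  A <- vapply(spectra, absorbance, numeric(length(grid)))
  Spectrum(grid, rowMeans(A), sampleId = ids, replicate = 0L,
           provenance = list(n_replicates = length(spectra),
                             averaged = TRUE))
}

#' Read the sample metadata table
#'
#' Reads a comma-separated sample table (species, country, region,
#' collector, code, size, context). The packaged fixture transcribes the
#' study's 18 hyaenid field samples. Size strings `"L x ep"` are parsed as
#' length x thickness in millimetres; `"-"` or descriptive entries
#' (e.g. `"small specimen"`) yield absent sizes with the raw string kept in
#' `size_raw`.
#'
#' @param path CSV file; default is the packaged fixture.
#' @return data.frame with columns `species`, `country`, `region`, `code`,
#'   `length_mm`, `width_mm`, `context`, `size_raw`.
#' @examples
#' tab <- readSampleTable()
#' table(tab$species)
#' @export
readSampleTable <- function(path = system.file("extdata", "sample_table.csv",
                                               package = "coproFTIR")) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "country", "region", "code", "size", "context")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("sample table lacks columns: ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(tab$species), hyaenidSpecies)
  if (length(bad))
    stop("unknown species ", paste(sQuote(bad), collapse = ", "),
         "; allowed: ", paste(hyaenidSpecies, collapse = ", "))
  if (anyDuplicated(tab$code))
    stop("duplicated sample codes: ",
         paste(tab$code[duplicated(tab$code)], collapse = ", "))
  sz <- .parseSizes(tab$size)
  out <- data.frame(
    species = tab$species, country = tab$country, region = tab$region,
    code = tab$code, length_mm = sz$length, width_mm = sz$width,
    context = tab$context, size_raw = tab$size,
    stringsAsFactors = FALSE
  )
  pos <- c(out$length_mm, out$width_mm)
  if (any(pos <= 0, na.rm = TRUE)) stop("sizes must be positive when present")
  out
}

.parseSizes <- function(raw) {
  one <- function(s) {
    s <- trimws(s)
    if (!grepl("x", s, fixed = TRUE)) return(c(NA_real_, NA_real_))
    parts <- trimws(strsplit(s, "x", fixed = TRUE)[[1]])
    vals <- suppressWarnings(as.numeric(parts))
    vals[parts == "-"] <- NA_real_
    if (length(vals) != 2L) c(NA_real_, NA_real_) else vals
  }
  m <- t(vapply(raw, one, numeric(2), USE.NAMES = FALSE))
  list(length = m[, 1], width = m[, 2])
}
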