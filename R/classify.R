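#' @include chemometrics.R
NULL

#' Fit a classification reference
#'
#' Fits the reference against which unknown samples are classified: a
#' correlation-matrix PCA of the selected variables, per-species convex
#' hull domains in PC1-PC2, species centroids in the z-scored variable
#' space, and a pooled within-species covariance shrunk toward the
#' identity (weight `shrinkage`) to stabilise small classes.
#'
#' @param features feature table of the reference samples.
#' @param labels species label per row of `features`.
#' @param variables the variables used for classification; default is the
#'   six-variable set CO3, PO4, CO3PO4b, chitin, cholesterol, amideI.
#' @param shrinkage weight of the identity in the pooled covariance
#'   (default 0.1).
#' @return an object of class `coproReference` (list with elements
#'   `variables`, `pca`, `domains`, `centroids`, `covInv`, `center`,
#'   `scale`, `labels`).
#' @seealso [classifySample()]
#' @export
fitReference <- function(features, labels,
                         variables = c("CO3", "PO4", "CO3PO4b",
                                       "chitin", "cholesterol", "amideI"),
                         shrinkage = 0.1) {
  labels <- as.character(labels)
  stopifnot(nrow(features) == length(labels))
  pca <- runPCA(features, variables)
  keep <- pca@sampleIds
  ids <- if ("sample_id" %in% names(features)) as.character(features$sample_id)
         else as.character(seq_len(nrow(features)))
  labs <- labels[match(keep, ids)]
  domains <- buildDomains(pca, labs)
  Z <- scale(as.matrix(features[match(keep, ids), variables, drop = FALSE]),
             center = pca@center, scale = pca@scale)
  centroids <- do.call(rbind, lapply(split(seq_len(nrow(Z)), labs),
                                     function(i) colMeans(Z[i, , drop = FALSE])))
  # pooled within-class covariance, shrunk toward identity
  Sw <- Reduce(`+`, lapply(split(seq_len(nrow(Z)), labs), function(i) {
    if (length(i) < 2L) return(matrix(0, ncol(Z), ncol(Z)))
    cov(Z[i, , drop = FALSE]) * (length(i) - 1L)
  })) / max(nrow(Z) - length(unique(labs)), 1L)
  Ssh <- (1 - shrinkage) * Sw + shrinkage * diag(ncol(Z))
  covInv <- solve(Ssh)
  structure(list(variables = variables, pca = pca, domains = domains,
                 centroids = centroids, covInv = covInv,
                 center = pca@center, scale = pca@scale, labels = labs),
            class = "coproReference")
}

#' @export
print.coproReference <- function(x, ...) {
  cat("coproReference:", length(x$variables), "variables,",
      nrow(x$centroids), "species\n")
  cat("  variables:", paste(x$variables, collapse = ", "), "\n")
  cat("  species:", paste(rownames(x$centroids), collapse = ", "), "\n")
  invisible(x)
}

#' Classify a sample against a fitted reference
#'
#' Assigns the species whose centroid is nearest in Mahalanobis distance
#' within the z-scored selected-variable space. The confidence is a
#' softmin over squared distances, `exp(-d^2/2)` renormalised across
#' species. Membership of the sample's PC1-PC2 projection in each species
#' hull is reported separately.
#'
#' @param fv one-row data.frame (or named numeric) holding the reference's
#'   variables; an undefined (NA) required variable is an error.
#' @param reference a fitted [fitReference()] object.
#' @return list with `species`, `confidence`, `distances` (named, per
#'   species), `scores` (PC1-PC2 projection) and `in_hull` (named logical).
#' @export
classifySample <- function(fv, reference) {
  stopifnot(inherits(reference, "coproReference"))
  vars <- reference$variables
  x <- if (is.data.frame(fv)) unlist(fv[1, vars, drop = TRUE]) else fv[vars]
  x <- as.numeric(x)
  if (anyNA(x))
    stop("undefined required variable(s): ",
         paste(vars[is.na(x)], collapse = ", "))
  z <- (x - reference$center) / reference$scale
  d2 <- apply(reference$centroids, 1, function(mu)
    mahalanobis(matrix(z, 1), mu, reference$covInv, inverted = TRUE))
  best <- names(d2)[which.min(d2)]
  w <- exp(-(d2 - min(d2)) / 2)
  conf <- w / sum(w)
  sc <- drop(z %*% reference$pca@loadings[, 1:2, drop = FALSE])
  inHull <- vapply(reference$domains, function(d)
    pointInConvex(sc, d@vertices), logical(1))
  list(species = best, confidence = unname(conf[best]),
       distances = sqrt(d2), scores = sc, in_hull = inHull)
}
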