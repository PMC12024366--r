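test_that("full-spectrum correlations match the covariance formula", {
  s <- gaussianSpectrum(1500, sampleId = "a")
  neg <- Spectrum(wavenumbers(s), -absorbance(s), sampleId = "b")
  R <- pairwiseCorrelation(list(s, neg, s))
  expect_equal(unname(diag(R)), c(1, 1, 1))
  expect_equal(R["a", "b"], -1)

  set.seed(31)
  g <- seq(700, 4000, by = 4)
  x <- rnorm(length(g)); y <- 0.4 * x + rnorm(length(g))
  sx <- Spectrum(g, x, sampleId = "x"); sy <- Spectrum(g, y, sampleId = "y")
  # direct covariance-formula oracle
  oracle <- mean((x - mean(x)) * (y - mean(y))) /
    sqrt(mean((x - mean(x))^2) * mean((y - mean(y))^2))
  expect_equal(pairwiseCorrelation(list(sx, sy))["x", "y"], oracle,
               tolerance = 1e-12)

  expect_warning(R2 <- pairwiseCorrelation(list(sx, flatSpectrum(1))),
                 "constant")
  expect_true(is.na(R2[1, 2]))
})

test_that("PCA equals the correlation-matrix eigendecomposition oracle", {
  set.seed(32)
  for (i in 1:100) {
    n <- sample(10:50, 1); p <- sample(2:11, 1)
    X <- matrix(rnorm(n * p), n, p) %*% matrix(runif(p * p, -1, 1), p)
    colnames(X) <- paste0("v", seq_len(p))
    feat <- data.frame(sample_id = as.character(seq_len(n)), X)
    res <- runPCA(feat, colnames(X))
    e <- eigen(cor(X), symmetric = TRUE)
    k <- length(explainedFraction(res))
    expect_equal(explainedFraction(res), e$values[seq_len(k)] / p,
                 tolerance = 1e-8)
    expect_equal(abs(pcaLoadings(res)), abs(e$vectors[, seq_len(k), drop = FALSE]),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("PCA handles degenerate and flagged inputs per contract", {
  feat <- data.frame(sample_id = letters[1:6], a = rnorm(6))
  feat$b <- 2 * feat$a
  res <- runPCA(feat, c("a", "b"))
  expect_equal(explainedFraction(res)[1], 1.0, tolerance = 1e-12)

  set.seed(33)
  big <- data.frame(sample_id = as.character(1:10000),
                    matrix(rnorm(60000), ncol = 6,
                           dimnames = list(NULL, paste0("v", 1:6))))
  fr <- explainedFraction(runPCA(big, paste0("v", 1:6)))
  expect_true(all(abs(fr - 1 / 6) < 0.05))

  feat$z <- 1
  expect_error(runPCA(feat, c("a", "z")), "zero-variance.*z")
  feat$w <- c(NA, rnorm(5))
  expect_message(res2 <- runPCA(feat, c("a", "b", "w")), "1 row")
  expect_equal(nrow(scores(res2)), 5L)

  # sample order does not change explained fractions
  set.seed(34)
  X <- data.frame(sample_id = as.character(1:30),
                  matrix(rnorm(150), ncol = 5,
                         dimnames = list(NULL, paste0("v", 1:5))))
  f1 <- explainedFraction(runPCA(X, paste0("v", 1:5)))
  f2 <- explainedFraction(runPCA(X[sample(30), ], paste0("v", 1:5)))
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("an exact duplicate variable is discarded first", {
  set.seed(35)
  n <- 60
  feat <- data.frame(sample_id = as.character(seq_len(n)),
                     PO4 = rnorm(n), CO3 = rnorm(n), CO3b = rnorm(n),
                     CO3PO4 = rnorm(n), CO3PO4b = rnorm(n),
                     chitin = rnorm(n), cholesterol = rnorm(n),
                     amideII = rnorm(n), amideI = rnorm(n),
                     collagen = rnorm(n))
  feat$CI <- feat$CO3          # perfect redundancy
  rep <- selectVariables(feat)
  expect_equal(rep@mineralDiscarded[1], "CI")
  expect_false("CI" %in% rep@mineralSelected)
})

test_that("planted correlation structure drives selection to the reported sets", {
  for (seed in c(101, 202, 303, 404, 505)) {
    feat <- plantedFeatureCohort(n = 200, seed = seed)
    rep <- selectVariables(feat)
    expect_setequal(rep@mineralSelected, c("CO3", "PO4", "CO3PO4b"))
    expect_setequal(rep@organicSelected, c("chitin", "cholesterol", "amideI"))
    # sample order invariance of the outcome
    rep2 <- selectVariables(feat[sample(nrow(feat)), ])
    expect_setequal(rep2@mineralSelected, rep@mineralSelected)
  }
  # a 0.99-correlated amide pair never survives together
  feat <- plantedFeatureCohort(n = 200, seed = 9)
  rep <- selectVariables(feat)
  expect_length(intersect(c("amideI", "amideII"), rep@organicSelected), 1L)
  expect_error(selectVariables(feat, mineralCandidates = c("PO4", "CO3")),
               "at least three")
})

test_that("domains are hulls with exact degenerate and disjoint behaviour", {
  S <- matrix(c(0, 0, 1, 0, 0, 1), ncol = 2, byrow = TRUE)
  fake <- new("PCAResult", variableNames = c("a", "b"),
              loadings = diag(2), scores = S,
              explainedFraction = c(0.6, 0.4),
              center = c(0, 0), scale = c(1, 1),
              sampleIds = as.character(1:3))
  d <- buildDomains(fake, rep("one", 3))
  expect_equal(d[["one"]]@area, 0.5)
  expect_true(all(apply(S, 1, function(p)
    coproFTIR:::pointInConvex(p, d[["one"]]@vertices))))

  set.seed(36)
  A <- cbind(rnorm(20), rnorm(20))
  B <- cbind(rnorm(20) + 20, rnorm(20))    # 10+ SD apart
  fake2 <- new("PCAResult", variableNames = c("a", "b"),
               loadings = diag(2), scores = rbind(A, B),
               explainedFraction = c(0.6, 0.4), center = c(0, 0),
               scale = c(1, 1), sampleIds = as.character(1:40))
  doms <- buildDomains(fake2, rep(c("p", "q"), each = 20))
  ov <- domainOverlap(doms)
  expect_equal(ov$overlap_area, 0)
  expect_error(buildDomains(fake2, c(rep("p", 39), NA)), "unknown")

  # one- and two-point species give zero-area degenerate domains
  d2 <- buildDomains(fake, c("one", "one", "two"))
  expect_equal(d2[["two"]]@area, 0)
  expect_equal(nrow(d2[["two"]]@vertices), 1L)
})

test_that("classification returns the centroid's own species at distance 0", {
  set.seed(37)
  coh <- plantedFeatureCohort(n = 60, seed = 12)
  labs <- rep(c("s1", "s2", "s3"), each = 20)
  vars <- c("CO3", "PO4", "CO3PO4b", "chitin", "cholesterol", "amideI")
  # separate the classes
  coh$PO4 <- coh$PO4 + c(0, 5, 10)[as.integer(factor(labs))]
  ref <- fitReference(coh, labs, variables = vars)
  centroidRaw <- ref$centroids["s2", ] * ref$scale + ref$center
  fv <- as.data.frame(as.list(setNames(centroidRaw, vars)))
  res <- classifySample(fv, ref)
  expect_equal(res$species, "s2")
  expect_lt(res$distances[["s2"]], 1e-8)
  expect_gt(res$confidence, 1 / 3)
  expect_named(res$in_hull, c("s1", "s2", "s3"))

  fv$CO3 <- NA_real_
  expect_error(classifySample(fv, ref), "undefined required")

  coh$zero <- 0
  expect_error(fitReference(coh, labs, variables = c("zero", "PO4")),
               "zero-variance")
})
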