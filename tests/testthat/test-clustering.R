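tinyImage <- function(Y, rows, cols, axis = NULL, mask = NULL) {
  n <- ncol(Y)
  if (is.null(axis)) axis <- seq(2000, by = -2, length.out = n)
  SpectralImage(axis, array(Y, c(rows, cols, n)), mask = mask)
}

test_that("pixel pooling stacks unmasked pixels with provenance", {
  set.seed(1)
  m1 <- matrix(TRUE, 2, 5); m1[1, 1] <- FALSE               # 9 pixels
  img1 <- tinyImage(matrix(rnorm(10 * 4), 10), 2, 5, mask = m1)
  img2 <- tinyImage(matrix(rnorm(12 * 4), 12), 3, 4)        # 12 pixels
  pool <- poolPixels(list(img1, img2))
  expect_equal(nrow(pool$X), 21)
  expect_equal(nrow(pool$provenance), 21)
  expect_equal(sum(pool$provenance$image == 1), 9)

  # provenance round-trip: scattering rows repopulates exactly the mask
  back <- matrix(FALSE, 3, 4)
  p2 <- pool$provenance[pool$provenance$image == 2, ]
  back[cbind(p2$row, p2$col)] <- TRUE
  expect_identical(back, tissueMask(img2))

  img3 <- tinyImage(matrix(rnorm(4 * 4), 4), 2, 2,
                    mask = matrix(FALSE, 2, 2))
  expect_equal(nrow(poolPixels(list(img1, img3))$X), 9)

  imgBad <- tinyImage(matrix(rnorm(4 * 4), 4), 2, 2,
                      axis = seq(3000, by = -2, length.out = 4))
  expect_error(poolPixels(list(img1, imgBad)), "axis mismatch")
})

test_that("k-means handles exact and well-separated configurations", {
  X <- matrix(c(0, 0, 10, 10, 0, 10, 0, 10), 4, 2)
  fit <- kmeansFit(X, 4, seed = 1, nInit = 5)
  expect_equal(fit@inertia, 0)
  expect_equal(nrow(unique(centroids(fit))), 4)

  X2 <- matrix(c(0, 0.1, 0.2, 10, 10.1, 10.2), ncol = 1)
  fit2 <- kmeansFit(X2, 2, seed = 1, nInit = 10)
  expect_equal(sort(as.vector(centroids(fit2))), c(0.1, 10.1),
               tolerance = 1e-9)
  expect_error(kmeansFit(X2, 7), "fewer rows")
  X2[1] <- NA
  expect_error(kmeansFit(X2, 2), "data error")
})

test_that("restarted k-means attains the exhaustive-partition optimum", {
  set.seed(42)
  for (i in 1:6) {
    n <- sample(6:9, 1)
    k <- sample(2:3, 1)
    X <- matrix(rnorm(n * 2), n)
    fit <- kmeansFit(X, k, seed = i, nInit = 50)
    expect_equal(fit@inertia, exhaustiveInertia(X, k), tolerance = 1e-9)
  }
})

test_that("k-means agrees with an independent Lloyd implementation", {
  set.seed(7)
  X <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 4), 20))
  fit <- kmeansFit(X, 2, seed = 3, nInit = 20)
  ref <- stats::kmeans(X, 2, nstart = 20, algorithm = "Lloyd")
  expect_equal(fit@inertia, ref$tot.withinss, tolerance = 1e-9)
})

test_that("label assignment is nearest-centroid with lowest-id tie break", {
  model1 <- new("ClusterModel", k = 2L, centroids = matrix(c(0, 2), 2, 1),
                axis = numeric(), inertia = 0, seed = 1L, nInit = 1L,
                colorTable = clusterPalette(2))
  img1 <- SpectralImage(c(1000, 998), array(c(5, 1, 5, 1), c(1, 2, 2)))
  expect_error(assignLabels(img1, model1), "axis mismatch")
  model2 <- new("ClusterModel", k = 3L,
                centroids = rbind(c(0, 0), c(2, 2), c(5, 5)), axis = numeric(),
                inertia = 0, seed = 1L, nInit = 1L,
                colorTable = clusterPalette(3))
  lm <- assignLabels(img1, model2)
  # (5,5) matches centroid 2 exactly; (1,1) ties centroids 0 and 1 -> 0
  expect_equal(labelMatrix(lm)[1, ], c(2L, 0L))

  # pixel equidistant to two centroids takes the lower id
  imgTie <- SpectralImage(c(1000, 998), array(c(1, 1), c(1, 1, 2)))
  modelTie <- new("ClusterModel", k = 2L,
                  centroids = rbind(c(0, 0), c(2, 2)), axis = numeric(),
                  inertia = 0, seed = 1L, nInit = 1L,
                  colorTable = clusterPalette(2))
  expect_equal(labelMatrix(assignLabels(imgTie, modelTie))[1, 1], 0L)

  # masked pixels stay -1
  imgM <- SpectralImage(c(1000, 998), array(c(1, 1), c(1, 1, 2)),
                        mask = matrix(FALSE, 1, 1))
  expect_equal(labelMatrix(assignLabels(imgM, modelTie))[1, 1], -1L)
})

test_that("relabelling the training pixels reproduces the fitted inertia", {
  set.seed(9)
  Y <- rbind(matrix(rnorm(60, 0, 0.2), 20), matrix(rnorm(60, 3, 0.2), 20))
  img <- tinyImage(Y, 8, 5)
  cm <- commonKMeans(list(img), k = 2, seed = 4, nInit = 10)
  lm <- cm$labelMaps[[1]]
  lab <- as.vector(labelMatrix(lm))
  inertia <- sum(vapply(0:1, function(j) {
    S <- Y[lab == j, , drop = FALSE]
    sum(sweep(S, 2, centroids(cm$model)[j + 1, ])^2)
  }, 0))
  expect_equal(inertia, cm$model@inertia, tolerance = 1e-9)
})

test_that("common k-means shares cluster identity across images", {
  set.seed(11)
  Y1 <- rbind(matrix(rnorm(40, 0, 0.1), 10), matrix(rnorm(40, 5, 0.1), 10))
  Y2 <- rbind(matrix(rnorm(40, 0, 0.1), 10), matrix(rnorm(40, 5, 0.1), 10))
  img1 <- tinyImage(Y1, 4, 5); img2 <- tinyImage(Y2, 4, 5)
  cm <- commonKMeans(list(img1, img2), k = 2, seed = 2, nInit = 10)
  expect_length(cm$labelMaps, 2)
  # the same blob gets the same label in both images
  expect_equal(labelMatrix(cm$labelMaps[[1]])[1, 1],
               labelMatrix(cm$labelMaps[[2]])[1, 1])
  # single image: identical to a direct fit with the same seed policy
  single <- commonKMeans(list(img1), k = 2, seed = 2, nInit = 10)
  direct <- kmeansFit(poolPixels(list(img1))$X, 2, seed = 2, nInit = 10)
  expect_identical(single$model@inertia, direct@inertia)
  # pooling order does not change the achieved optimum
  swapped <- commonKMeans(list(img2, img1), k = 2, seed = 2, nInit = 10)
  expect_equal(cm$model@inertia, swapped$model@inertia, tolerance = 1e-9)
})

test_that("cluster percentages cover all clusters and sum to 100", {
  lm <- LabelMap(matrix(c(rep(0L, 30), rep(1L, 70)), 10, 10), k = 3)
  pct <- clusterPercentages(lm)
  expect_equal(unname(pct), c(30, 70, 0))
  expect_equal(sum(pct), 100, tolerance = 1e-9)

  one <- LabelMap(matrix(2L, 4, 4), k = 3)
  expect_equal(unname(clusterPercentages(one)), c(0, 0, 100))

  none <- LabelMap(matrix(-1L, 2, 2), k = 2)
  expect_error(clusterPercentages(none), "no unmasked pixels")

  # abundance tables keep the per-image sum invariant
  ab <- abundanceTable(list(lm, one), c("a", "b"), c("WT", "KO"))
  sums <- tapply(ab$percent, ab$image_id, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
})

test_that("cluster-truth matching is exact and permutation invariant", {
  truth <- generateLayout(smallConfig(seed = 4))
  self <- matchClustersToTruth(truth, truth)
  expect_equal(self$agreement, 1)
  expect_equal(self$mapping, 0:5)

  perm <- c(3L, 0L, 5L, 1L, 4L, 2L)
  permuted <- LabelMap(matrix(perm[labelMatrix(truth) + 1L],
                              nrow(labelMatrix(truth))), k = 6)
  m <- matchClustersToTruth(permuted, truth)
  expect_equal(m$agreement, 1)
  expect_equal(m$mapping[perm + 1L], 0:5)

  expect_error(matchClustersToTruth(LabelMap(matrix(0L, 2, 2), k = 1), truth),
               "shape mismatch")
})

test_that("assignment matching equals exhaustive search on a toy confusion", {
  conf <- matrix(c(5, 0, 2, 0, 4, 0, 1, 0, 6), 3, 3)  # rows pred, cols truth
  # build a 1 x N label pair realising this confusion matrix
  pred <- integer(0); tru <- integer(0)
  for (i in 1:3) for (j in 1:3) {
    pred <- c(pred, rep(i - 1L, conf[i, j]))
    tru <- c(tru, rep(j - 1L, conf[i, j]))
  }
  lmP <- LabelMap(matrix(pred, 1), k = 3)
  lmT <- LabelMap(matrix(tru, 1), k = 3)
  got <- matchClustersToTruth(lmP, lmT)
  perms <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  bestScore <- max(vapply(perms, function(p)
    sum(conf[cbind(1:3, p)]), 0))
  expect_equal(got$agreement, bestScore / sum(conf))
  expect_equal(sum(conf[cbind(1:3, got$mapping + 1L)]), bestScore)
})

test_that("both published class counts run on a pooled cohort", {
  wt <- smallConfig(rows = 24, cols = 24, group = "WT", nHairBulbs = 1)
  ko <- phantomConfig(rows = 24, cols = 24, group = "KO", nHairBulbs = 1,
                      seed = 1)
  coh <- generateCohort(wt, ko, 3, seed = 5)
  corrected <- dewaxCohort(coh)
  for (k in c(5, 10)) {
    cm <- commonKMeans(corrected, k, seed = 6, nInit = 3)
    expect_equal(cm$model@k, as.integer(k))
    expect_length(cm$labelMaps, 6)
    ab <- abundanceTable(cm$labelMaps,
                         vapply(coh, function(p) p@image@meta$sample_id, ""),
                         vapply(coh, function(p) p@image@meta$group, ""))
    expect_equal(nrow(ab), 6 * k)
    sums <- tapply(ab$percent, ab$image_id, sum)
    expect_true(all(abs(sums - 100) < 1e-9))
  }
})
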