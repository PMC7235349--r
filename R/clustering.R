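# Squared Euclidean distances between rows of X (n x p) and C (k x p).
sqDistMatrix <- function(X, C) {
  d2 <- outer(rowSums(X^2), rowSums(C^2), `+`) - 2 * tcrossprod(X, C)
  d2[d2 < 0] <- 0
  d2
}

# k-means++ seeding: first centre uniform, then points sampled with
# probability proportional to their squared distance to the nearest centre.
kmeansPlusPlus <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1L), ]
  if (k > 1) {
    d2min <- sqDistMatrix(X, centers[1, , drop = FALSE])[, 1]
    for (j in 2:k) {
      pick <- if (sum(d2min) > 0) sample.int(n, 1L, prob = d2min)
              else sample.int(n, 1L)
      centers[j, ] <- X[pick, ]
      d2min <- pmin(d2min, sqDistMatrix(X, centers[j, , drop = FALSE])[, 1])
    }
  }
  centers
}

# One Lloyd run from given centres; returns centres, assignment, inertia.
lloydRun <- function(X, centers, maxIter, tol) {
  k <- nrow(centers)
  n <- nrow(X)
  lastInertia <- Inf
  for (iter in seq_len(maxIter)) {
    d2 <- sqDistMatrix(X, centers)
    assign <- max.col(-d2, ties.method = "first")
    # empty-cluster repair: re-seed to the point farthest from its centroid
    repeat {
      sizes <- tabulate(assign, nbins = k)
      empty <- which(sizes == 0L)
      if (length(empty) == 0L) break
      dOwn <- d2[cbind(seq_len(n), assign)]
      far <- which.max(dOwn)
      centers[empty[1L], ] <- X[far, ]
      d2[, empty[1L]] <- sqDistMatrix(X, centers[empty[1L], , drop = FALSE])
      assign <- max.col(-d2, ties.method = "first")
    }
    inertia <- sum(d2[cbind(seq_len(n), assign)])
    stopifnot(inertia <= lastInertia * (1 + 1e-8) + 1e-12) # Lloyd monotonicity
    lastInertia <- inertia
    newCenters <- rowsum(X, assign) / tabulate(assign, nbins = k)
    shift <- sqrt(max(rowSums((newCenters - centers)^2)))
    centers <- newCenters
    if (shift < tol) break
  }
  d2 <- sqDistMatrix(X, centers)
  assign <- max.col(-d2, ties.method = "first")
  list(centers = centers, assign = assign,
       inertia = sum(d2[cbind(seq_len(n), assign)]))
}

#' Fit K-means to a pixel matrix
#'
#' Lloyd iterations with squared Euclidean distance and k-means++
#' initialisation; `nInit` seeded restarts, lowest inertia wins. Empty
#' clusters are re-seeded to the point farthest from its current centroid.
#' Convergence when the maximum centroid displacement falls below `tol`.
#'
#' @param X numeric matrix, rows = pixel spectra (rows >= k).
#' @param k number of clusters.
#' @param seed integer seed for the restarts.
#' @param nInit number of k-means++ restarts (default 20).
#' @param maxIter maximum Lloyd iterations per restart (default 300).
#' @param tol convergence tolerance on centroid displacement (default 1e-6).
#' @return a [ClusterModel-class].
#' @export
kmeansFit <- function(X, k, seed = 1, nInit = 20, maxIter = 300, tol = 1e-6) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("data error: non-finite entries in pixel matrix")
  k <- as.integer(k)
  if (nrow(X) < k)
    stop("fewer rows (", nrow(X), ") than clusters (", k, ")")
  best <- NULL
  for (r in seq_len(nInit)) {
    run <- withSeed(deriveSeed(seed, r), {
      lloydRun(X, kmeansPlusPlus(X, k), maxIter, tol)
    })
    if (is.null(best) || run$inertia < best$inertia) best <- run
  }
  new("ClusterModel", k = k, centroids = best$centers, axis = numeric(),
      inertia = best$inertia, seed = as.integer(seed),
      nInit = as.integer(nInit), colorTable = clusterPalette(k))
}

#' Pool unmasked pixels from several images
#'
#' Stacks the unmasked pixel spectra of all images (in list order) into one
#' matrix so a single K-means model can be fitted across groups.
#'
#' @param images list of [SpectralImage-class] sharing one processed axis.
#' @return a list with `X` (pixels x channels matrix) and `provenance`
#'   (data.frame image_id, image index, row, col per matrix row).
#' @export
poolPixels <- function(images) {
  stopifnot(length(images) >= 1)
  axis <- images[[1]]@axis
  blocks <- vector("list", length(images))
  prov <- vector("list", length(images))
  for (i in seq_along(images)) {
    img <- images[[i]]
    if (!identical(img@axis, axis))
      stop("axis mismatch: image ", i, " is not on the common axis")
    Y <- pixelMatrix(img)
    idx <- attr(Y, "pixelIndex")
    id <- img@meta$sample_id
    if (is.null(id)) id <- sprintf("image%d", i)
    blocks[[i]] <- Y
    prov[[i]] <- if (nrow(Y)) data.frame(image_id = id, image = i,
                                         row = idx[, 1], col = idx[, 2])
  }
  list(X = do.call(rbind, blocks), provenance = do.call(rbind, prov))
}

#' Assign cluster labels to an image
#'
#' Each unmasked pixel gets the id of the nearest centroid (squared Euclidean
#' distance; ties broken towards the lowest cluster id); masked pixels get
#' -1.
#'
#' @param img a [SpectralImage-class] on the model axis.
#' @param model a [ClusterModel-class].
#' @return a [LabelMap-class] with the model's colour table.
#' @export
assignLabels <- function(img, model) {
  stopifnot(is(img, "SpectralImage"), is(model, "ClusterModel"))
  if (length(model@axis) && !identical(img@axis, model@axis))
    stop("axis mismatch: image is not on the model axis")
  if (dim(img@cube)[3] != ncol(model@centroids))
    stop("axis mismatch: channel count differs from centroids")
  Y <- pixelMatrix(img)
  labels <- matrix(-1L, nrow(img@mask), ncol(img@mask))
  if (nrow(Y)) {
    d2 <- sqDistMatrix(Y, model@centroids)
    idx <- attr(Y, "pixelIndex")
    labels[idx[, 1] + (idx[, 2] - 1L) * nrow(labels)] <-
      max.col(-d2, ties.method = "first") - 1L
  }
  LabelMap(labels, k = model@k, colorTable = model@colorTable)
}

#' Common K-means across a set of images
#'
#' Pools the unmasked pixels of all images, fits one K-means model, and
#' labels every image with it, so cluster identities (and colours) are
#' directly comparable across samples and groups.
#'
#' @inheritParams kmeansFit
#' @param images list of [SpectralImage-class] on one axis.
#' @return a list with `model` ([ClusterModel-class], axis attached) and
#'   `labelMaps` (one [LabelMap-class] per image, in input order).
#' @export
commonKMeans <- function(images, k, seed = 1, nInit = 20, maxIter = 300,
                         tol = 1e-6) {
  pool <- poolPixels(images)
  model <- kmeansFit(pool$X, k, seed = seed, nInit = nInit,
                     maxIter = maxIter, tol = tol)
  model@axis <- images[[1]]@axis
  list(model = model, labelMaps = lapply(images, assignLabels, model = model))
}

#' Per-cluster abundance percentages of a label map
#'
#' `percent(j) = 100 * count(labels == j) / count(labels != -1)`; the vector
#' always covers all k clusters (absent clusters get 0) and sums to 100.
#'
#' @param lm a [LabelMap-class].
#' @return named numeric vector of length `k` (names "0".."k-1").
#' @export
clusterPercentages <- function(lm) {
  stopifnot(is(lm, "LabelMap"))
  tissue <- lm@labels[lm@labels != -1L]
  if (length(tissue) == 0) stop("no unmasked pixels in label map")
  counts <- tabulate(tissue + 1L, nbins = lm@k)
  stats::setNames(100 * counts / length(tissue), as.character(0:(lm@k - 1L)))
}

#' Long-format abundance table for a cohort
#'
#' @param labelMaps list of [LabelMap-class], one per image.
#' @param imageIds character image identifiers.
#' @param groups character group labels ("WT"/"KO"), one per image.
#' @return data.frame with columns image_id, group, cluster_id, percent.
#' @export
abundanceTable <- function(labelMaps, imageIds, groups) {
  stopifnot(length(labelMaps) == length(imageIds),
            length(labelMaps) == length(groups))
  rows <- lapply(seq_along(labelMaps), function(i) {
    pct <- clusterPercentages(labelMaps[[i]])
    data.frame(image_id = imageIds[i], group = groups[i],
               cluster_id = as.integer(names(pct)), percent = as.numeric(pct))
  })
  do.call(rbind, rows)
}

#' Optimally match predicted clusters to ground-truth classes
#'
#' Solves the one-to-one assignment maximising the confusion-matrix diagonal
#' exactly (Hungarian method) and reports the matched-pixel agreement over
#' the pixels unmasked in both maps.
#'
#' @param lm predicted [LabelMap-class].
#' @param truth ground-truth [LabelMap-class] of the same shape.
#' @return list with `mapping` (integer vector: truth class matched to each
#'   predicted cluster, NA where unmatched), `agreement` (fraction in [0, 1])
#'   and `confusion` (k_pred x k_truth count matrix).
#' @export
matchClustersToTruth <- function(lm, truth) {
  stopifnot(is(lm, "LabelMap"), is(truth, "LabelMap"))
  if (!identical(dim(lm@labels), dim(truth@labels)))
    stop("shape mismatch between label map and truth")
  sel <- lm@labels != -1L & truth@labels != -1L
  if (!any(sel)) stop("no pixels unmasked in both maps")
  conf <- table(factor(lm@labels[sel], levels = 0:(lm@k - 1L)),
                factor(truth@labels[sel], levels = 0:(truth@k - 1L)))
  conf <- unclass(conf)
  kSq <- max(dim(conf))
  pad <- matrix(0, kSq, kSq)
  pad[seq_len(nrow(conf)), seq_len(ncol(conf))] <- conf
  sol <- clue::solve_LSAP(pad, maximum = TRUE)
  mapping <- as.integer(sol)[seq_len(lm@k)] - 1L
  mapping[mapping >= truth@k] <- NA_integer_
  matched <- sum(pad[cbind(seq_len(kSq), as.integer(sol))])
  list(mapping = mapping, agreement = matched / sum(conf),
       confusion = conf)
}

#' Find the cluster matched to a named tissue class
#'
#' Aggregates confusion matrices over a cohort and returns the cluster id the
#' optimal assignment pairs with the requested ground-truth class.
#'
#' @param labelMaps list of predicted [LabelMap-class].
#' @param truths list of ground-truth [LabelMap-class] with class names.
#' @param class tissue class name (one of the truth class names).
#' @return integer cluster id (0-based).
#' @export
clusterForClass <- function(labelMaps, truths, class = "dermis") {
  stopifnot(length(labelMaps) == length(truths), length(labelMaps) >= 1)
  kPred <- labelMaps[[1]]@k
  kTruth <- truths[[1]]@k
  classIdx <- match(class, truths[[1]]@classNames)
  if (is.na(classIdx)) stop("unknown tissue class: ", class)
  agg <- matrix(0, kPred, kTruth)
  for (i in seq_along(labelMaps)) {
    sel <- labelMaps[[i]]@labels != -1L & truths[[i]]@labels != -1L
    agg <- agg + unclass(table(
      factor(labelMaps[[i]]@labels[sel], levels = 0:(kPred - 1L)),
      factor(truths[[i]]@labels[sel], levels = 0:(kTruth - 1L))))
  }
  kSq <- max(dim(agg))
  pad <- matrix(0, kSq, kSq)
  pad[seq_len(kPred), seq_len(kTruth)] <- agg
  sol <- as.integer(clue::solve_LSAP(pad, maximum = TRUE))
  cl <- which(sol == classIdx) - 1L
  if (length(cl) != 1 || cl >= kPred)
    stop("no cluster matched to class ", class)
  cl
}
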