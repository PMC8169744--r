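#' Summarise predicted lesions on one slice
#'
#' Four components per slice: the summed predicted calcified area (all
#' predicted pixels, mm2), the maximum intensity in HU within the predicted
#' calcified region (0 for an empty slice; floored at 0 so components stay
#' non-negative), the sum over lesions of area weighted by the lesion's
#' maximum intensity, and the number of predicted lesions.
#'
#' @param lesions lesion table rows belonging to one slice (from
#'   [extractLesions()] / [scoreVolume()]).
#' @return Named numeric length 4: area, maxHu, weightedArea, nLesions.
#' @examples
#' summarizeSlice(emptyLesionTable())
#' @export
summarizeSlice <- function(lesions) {
  if (!nrow(lesions))
    return(c(area = 0, maxHu = 0, weightedArea = 0, nLesions = 0))
  c(area = sum(lesions$grossAreaMm2),
    maxHu = max(0, max(lesions$maxHu)),
    weightedArea = sum(lesions$grossAreaMm2 * pmax(lesions$maxHu, 0)),
    nLesions = nrow(lesions))
}

#' 20-component exam feature vector for the risk-bucket classifier
#'
#' Slice summary vectors are computed for every axial slice; the summaries of
#' the 5 slices with the highest predicted area (ties broken by slice index)
#' are concatenated in descending-area order, zero-padded when the exam has
#' fewer than 5 slices.
#'
#' @param probVolume a [ProbabilityVolume-class].
#' @param volume the matching [CTVolume-class].
#' @param cfg a [scoringConfig()].
#' @return Named numeric of length 20 (s1_area ... s5_nLesions).
#' @export
examFeatures <- function(probVolume, volume, cfg = scoringConfig()) {
  mask <- binarizeCalcium(probVolume, cfg)
  les <- extractLesions(mask, volume, cfg)
  featuresFromLesions(les, nSlices(volume))
}

#' @rdname examFeatures
#' @param lesions a full-exam lesion table.
#' @param nSlices number of slices in the exam.
#' @export
featuresFromLesions <- function(lesions, nSlices) {
  summaries <- t(vapply(seq_len(nSlices), function(s)
    summarizeSlice(lesions[lesions$slice == s, , drop = FALSE]), numeric(4)))
  ord <- order(-summaries[, 1], seq_len(nSlices))
  top <- utils::head(ord, 5)
  feat <- numeric(20)
  for (i in seq_along(top)) feat[(i - 1) * 4 + 1:4] <- summaries[top[i], ]
  names(feat) <- as.vector(t(outer(paste0("s", 1:5),
                                   c("area", "maxHu", "weightedArea", "nLesions"),
                                   paste, sep = "_")))
  feat
}

#' Fit the gradient-boosted risk-bucket classifier
#'
#' Multiclass gradient-boosted decision trees over the 20-component exam
#' features, with risk buckets from paired gated reference scores as labels.
#' Deterministic for a fixed seed (single-threaded boosting).
#'
#' @param features numeric matrix, one 20-component row per exam.
#' @param buckets reference buckets (factor/character I-V), one per exam.
#' @param nrounds boosting rounds (default 200).
#' @param maxDepth tree depth (default 3).
#' @param eta learning rate (default 0.1).
#' @param seed RNG seed.
#' @param cvSplits optional fold assignment (integer vector, one entry per
#'   exam, mirroring the dataset splits used for the segmentation model);
#'   when given, held-out predictions are computed per fold and returned in
#'   the `cv` element together with the cross-validated kappa.
#' @return List of class `cac_bucket_classifier` (booster fitted on all
#'   exams + bucket levels + feature layout tag; `cv` when requested).
#' @export
fitBucketClassifier <- function(features, buckets, nrounds = 200,
                                maxDepth = 3, eta = 0.1, seed = 1L,
                                cvSplits = NULL) {
  features <- as.matrix(features)
  stopifnot(ncol(features) == 20, nrow(features) == length(buckets))
  lev <- BUCKETS[BUCKETS %in% as.character(buckets)]
  if (length(lev) < 2)
    stop("training set contains a single bucket class; at least two required")
  fitOne <- function(X, b) {
    y <- match(as.character(b), lev) - 1L
    dm <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
    withSeed(seed, xgboost::xgb.train(
      params = list(objective = "multi:softprob", num_class = length(lev),
                    max_depth = maxDepth, eta = eta, nthread = 1,
                    seed = seed),
      data = dm, nrounds = nrounds, verbose = 0))
  }
  out <- structure(list(booster = fitOne(features, buckets), levels = lev,
                        featureLayout = "cacfeat-v1"),
                   class = "cac_bucket_classifier")
  if (!is.null(cvSplits)) {
    stopifnot(length(cvSplits) == length(buckets))
    pred <- character(length(buckets))
    for (f in unique(cvSplits)) {
      ho <- which(cvSplits == f)
      bst <- fitOne(features[-ho, , drop = FALSE], buckets[-ho])
      pr <- matrix(predict(bst, features[ho, , drop = FALSE]),
                   nrow = length(ho))
      pred[ho] <- lev[max.col(pr, ties.method = "first")]
    }
    out$cv <- data.frame(fold = cvSplits,
                         truth = as.character(buckets), pred = pred,
                         stringsAsFactors = FALSE)
    out$cvKappa <- cohenKappa(out$cv$truth, out$cv$pred)$kappa
  }
  out
}

#' Predict risk buckets from exam features
#'
#' @param classifier a [fitBucketClassifier()] result.
#' @param features numeric matrix (or a single named length-20 vector).
#' @return Ordered factor of buckets with levels I < ... < V.
#' @export
predictBucket <- function(classifier, features) {
  stopifnot(inherits(classifier, "cac_bucket_classifier"))
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  features <- as.matrix(features)
  pr <- predict(classifier$booster, features)
  pr <- matrix(pr, nrow = nrow(features))
  idx <- max.col(pr, ties.method = "first")
  factor(classifier$levels[idx], levels = BUCKETS, ordered = TRUE)
}

#' Save / load a bucket classifier
#'
#' The file carries a feature-layout version tag checked on load.
#' @param classifier a [fitBucketClassifier()] result.
#' @param path file path.
#' @return `saveBucketClassifier`: invisibly `path`; `loadBucketClassifier`:
#'   the classifier.
#' @export
saveBucketClassifier <- function(classifier, path) {
  stopifnot(inherits(classifier, "cac_bucket_classifier"))
  saveRDS(list(raw = xgboost::xgb.save.raw(classifier$booster),
               levels = classifier$levels,
               featureLayout = classifier$featureLayout), path)
  invisible(path)
}

#' @rdname saveBucketClassifier
#' @export
loadBucketClassifier <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$featureLayout, "cacfeat-v1"))
    stop("unrecognised feature layout tag")
  structure(list(booster = xgboost::xgb.load.raw(obj$raw),
                 levels = obj$levels, featureLayout = obj$featureLayout),
            class = "cac_bucket_classifier")
}
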