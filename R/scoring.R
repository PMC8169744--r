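#' Scoring configuration
#'
#' Parameters of the deterministic second stage that converts per-pixel
#' probabilities into vessel-specific Agatston scores.
#'
#' @param calcProbThreshold calcium positivity threshold on p_calc; strict
#'   (pixels with p_calc > threshold are calcium). Default 0.5.
#' @param huThreshold attenuation threshold in HU; strict (> 130) for both the
#'   area count and the density weight. Default 130.
#' @param minLesionAreaMm2 optional minimum lesion area; lesions whose
#'   >130 HU area falls below it are dropped. Default 0 (no minimum); the
#'   conventional >= 1 mm2 filter can be requested explicitly.
#' @param weightMode "binned" applies the standard 4-bin Agatston density
#'   weight of the lesion peak HU; "literal" multiplies area by the peak HU
#'   itself. Default "binned".
#' @return A list of class `cac_scoring_config`.
#' @export
scoringConfig <- function(calcProbThreshold = 0.5, huThreshold = 130,
                          minLesionAreaMm2 = 0,
                          weightMode = c("binned", "literal")) {
  weightMode <- match.arg(weightMode)
  stopifnot(calcProbThreshold > 0, calcProbThreshold < 1,
            huThreshold > 0, minLesionAreaMm2 >= 0)
  structure(list(calcProbThreshold = calcProbThreshold,
                 huThreshold = huThreshold,
                 minLesionAreaMm2 = minLesionAreaMm2,
                 weightMode = weightMode),
            class = "cac_scoring_config")
}

#' Agatston density weight from the lesion peak attenuation
#'
#' Standard binning: 130 < HU < 200 -> 1; 200 <= HU < 300 -> 2;
#' 300 <= HU < 400 -> 3; HU >= 400 -> 4. Vectorised.
#'
#' @param maxHu lesion peak attenuation in HU, must exceed 130.
#' @return Integer weight(s) in 1..4.
#' @examples
#' agatstonWeight(c(150, 200, 399, 400))
#' @export
agatstonWeight <- function(maxHu) {
  if (any(maxHu <= 130))
    stop("agatstonWeight is defined only for peak attenuation > 130 HU")
  findInterval(maxHu, c(200, 300, 400)) + 1L
}

#' Threshold the calcium probability channel
#'
#' Pixels with p_calc strictly above the threshold are marked calcium.
#'
#' @param probVolume a [ProbabilityVolume-class].
#' @param cfg a [scoringConfig()].
#' @return Logical array (nSlices, H, W).
#' @export
binarizeCalcium <- function(probVolume, cfg = scoringConfig()) {
  stopifnot(is(probVolume, "ProbabilityVolume"))
  p <- probValues(probVolume)
  mask <- p[, , , 1, drop = FALSE] > cfg$calcProbThreshold
  array(mask, dim = dim(p)[1:3])
}

#' Extract in-slice 8-connected calcium lesions
#'
#' Connected components are computed per slice (2-D, never merged across
#' slices) with 8-connectivity. A lesion's Agatston area counts only its
#' pixels with attenuation strictly above the HU threshold; its peak HU is
#' taken over all component pixels.
#'
#' @param mask logical array (nSlices, H, W) of predicted calcium.
#' @param volume the original-resolution [CTVolume-class] (Agatston thresholds
#'   are defined in raw HU; never pass a preprocessed volume).
#' @param cfg a [scoringConfig()].
#' @return Unlabeled lesion table (vessel column NA); see [CacScores-class].
#' @export
extractLesions <- function(mask, volume, cfg = scoringConfig()) {
  stopifnot(is(volume, "CTVolume"))
  hu <- huValues(volume)
  if (!identical(dim(mask), dim(hu)))
    stop("mask and HU volume dimensions differ")
  pxArea <- prod(pixelSpacing(volume))
  out <- list()
  nS <- dim(mask)[1]
  for (s in seq_len(nS)) {
    m <- matrix(mask[s, , ], dim(mask)[2], dim(mask)[3])
    if (!any(m)) next
    lab <- .label8(m)
    huS <- matrix(hu[s, , ], dim(hu)[2], dim(hu)[3])
    for (k in seq_len(max(lab))) {
      idx <- which(lab == k, arr.ind = TRUE)
      vals <- huS[idx]
      nOver <- sum(vals > cfg$huThreshold)
      areaMm2 <- nOver * pxArea
      if (areaMm2 < cfg$minLesionAreaMm2 && cfg$minLesionAreaMm2 > 0) next
      maxHu <- max(vals)
      les <- data.frame(slice = s, vessel = NA_character_,
                        nPixels = nrow(idx),
                        grossAreaMm2 = nrow(idx) * pxArea,
                        areaMm2 = areaMm2, maxHu = maxHu,
                        weight = NA_real_, agatston = NA_real_,
                        stringsAsFactors = FALSE)
      les$pixels <- I(list(unname(idx)))
      out[[length(out) + 1L]] <- les
    }
  }
  if (!length(out)) return(emptyLesionTable())
  les <- do.call(rbind, out)
  les$weight <- ifelse(les$areaMm2 > 0,
                       if (cfg$weightMode == "binned")
                         agatstonWeight(pmax(les$maxHu, 130.5)) else les$maxHu,
                       0)
  les$weight[les$areaMm2 == 0] <- 0
  les$agatston <- les$areaMm2 * les$weight
  rownames(les) <- NULL
  les
}

#' Attribute lesions to coronary arteries
#'
#' Each lesion pixel gets the artery of the largest vessel probability;
#' the lesion takes the most frequent pixel label. Ties are broken by the
#' larger summed probability mass over the lesion, then by the fixed order
#' LCA < LAD < LCX < RCA.
#'
#' @param lesions lesion table from [extractLesions()].
#' @param probVolume the [ProbabilityVolume-class] the mask came from.
#' @return The lesion table with the vessel column filled in.
#' @export
assignVessel <- function(lesions, probVolume) {
  stopifnot(is(probVolume, "ProbabilityVolume"))
  if (!nrow(lesions)) return(lesions)
  p <- probValues(probVolume)
  d <- dim(p)
  for (r in seq_len(nrow(lesions))) {
    px <- lesions$pixels[[r]]
    s <- lesions$slice[r]
    pv <- vapply(seq_len(4), function(ch)
      matrix(p[s, , , ch + 1], d[2], d[3])[px], numeric(nrow(px)))
    pv <- matrix(pv, nrow = nrow(px))
    arg <- max.col(pv, ties.method = "first")
    votes <- tabulate(arg, 4L)
    top <- which(votes == max(votes))
    if (length(top) > 1) {
      mass <- colSums(pv)[top]
      top <- top[mass == max(mass)]
    }
    lesions$vessel[r] <- VESSELS[min(top)]
  }
  lesions
}

#' Score a CT exam from a probability volume
#'
#' Runs the full deterministic stage: threshold p_calc, extract 8-connected
#' in-slice lesions, attribute vessels, accumulate per-vessel Agatston scores,
#' sum slice-wise scores into the exam total and assign the risk bucket.
#'
#' @param probVolume a [ProbabilityVolume-class].
#' @param volume the matching original-resolution [CTVolume-class].
#' @param cfg a [scoringConfig()].
#' @return A [CacScores-class] with the labeled lesion table attached.
#' @export
scoreVolume <- function(probVolume, volume, cfg = scoringConfig()) {
  mask <- binarizeCalcium(probVolume, cfg)
  les <- extractLesions(mask, volume, cfg)
  les <- assignVessel(les, probVolume)
  vessel <- setNames(numeric(4), VESSELS)
  if (nrow(les)) {
    agg <- tapply(les$agatston, factor(les$vessel, levels = VESSELS), sum)
    agg[is.na(agg)] <- 0
    vessel[VESSELS] <- agg[VESSELS]
  }
  CacScores(vessel, lesions = les)
}

#' Risk bucket from a total Agatston score
#'
#' Buckets I-V for scores 0, (0, 10], (10, 100], (100, 400], > 400.
#' Fractional scores are supported.
#'
#' @param total total Agatston score(s), >= 0.
#' @return Ordered factor with levels I < II < III < IV < V.
#' @examples
#' cacBucket(c(0, 5, 100, 101, 401))
#' @export
cacBucket <- function(total) {
  stopifnot(all(total >= 0))
  cut(total, breaks = c(-Inf, 0, 10, 100, 400, Inf),
      labels = BUCKETS, right = TRUE, ordered_result = TRUE)
}

#' Binary call at a clinical CAC cutoff
#'
#' Positive iff score >= cutoff, for the cutoffs 1, 10, 100 and 400 used in
#' diagnostic-performance reporting (CAC >= 100 is the statin-initiation
#' threshold).
#'
#' @param total total Agatston score(s).
#' @param cutoff one of 1, 10, 100, 400.
#' @return Logical vector.
#' @export
binaryAtCutoff <- function(total, cutoff) {
  if (!cutoff %in% c(1, 10, 100, 400))
    stop("cutoff must be one of 1, 10, 100, 400")
  total >= cutoff
}

#' Binary call at a cutoff from a risk bucket
#'
#' Buckets are mapped to cutoff calls at the bucket boundaries:
#' cutoff 1 -> bucket >= II, 10 -> >= III, 100 -> >= IV, 400 -> V.
#' This is the positivity rule for classifiers whose output space is the
#' bucket, not a continuous score.
#'
#' @param bucket bucket values (factor or character I-V).
#' @param cutoff one of 1, 10, 100, 400.
#' @return Logical vector.
#' @export
bucketAtCutoff <- function(bucket, cutoff) {
  if (!cutoff %in% c(1, 10, 100, 400))
    stop("cutoff must be one of 1, 10, 100, 400")
  b <- match(as.character(bucket), BUCKETS)
  if (any(is.na(b))) stop("bucket values must be I..V")
  minB <- c(`1` = 2L, `10` = 3L, `100` = 4L, `400` = 5L)[[as.character(cutoff)]]
  b >= minB
}

#' Probability volume from a ground-truth label volume
#'
#' Turns integer per-pixel labels (0 background, 1-4 vessels, 5 non-coronary
#' calcium) into a valid [ProbabilityVolume-class]: vessel-labeled pixels get
#' p_calc = `pHigh` and a near-one-hot vessel vector; everything else
#' (including non-coronary calcium, which the segmentation model is expected
#' to suppress) gets p_calc = `pLow` and a uniform vessel vector.
#'
#' @param labels integer array (nSlices, H, W) or a [PhantomGroundTruth-class].
#' @param pHigh calcium probability on vessel pixels (default 0.99).
#' @param pLow calcium probability elsewhere (default 0.01).
#' @return A [ProbabilityVolume-class].
#' @export
probabilityFromLabels <- function(labels, pHigh = 0.99, pLow = 0.01) {
  if (is(labels, "PhantomGroundTruth")) labels <- labelVolume(labels)
  d <- dim(labels)
  stopifnot(length(d) == 3, pHigh > 0.5, pHigh < 1, pLow > 0, pLow < 0.5)
  p <- array(0, dim = c(d, 5))
  isVessel <- labels >= 1 & labels <= 4
  p[, , , 1] <- ifelse(isVessel, pHigh, pLow)
  for (ch in 1:4) {
    p[, , , ch + 1] <- ifelse(isVessel & labels == ch, 0.97,
                              ifelse(isVessel, 0.01, 0.25))
  }
  ProbabilityVolume(p)
}

#' Write a score report to JSON and/or CSV
#'
#' @param scores a [CacScores-class].
#' @param jsonPath optional path for a JSON report.
#' @param csvPath optional path for a CSV lesion table.
#' @return Invisibly, the report list.
#' @export
writeScoreReport <- function(scores, jsonPath = NULL, csvPath = NULL) {
  stopifnot(is(scores, "CacScores"))
  les <- lesionTable(scores)
  rep <- list(vessel = as.list(vesselScores(scores)),
              total = totalScore(scores),
              bucket = as.character(riskBucket(scores)),
              lesions = les[, setdiff(names(les), "pixels")])
  if (!is.null(jsonPath))
    jsonlite::write_json(rep, jsonPath, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  if (!is.null(csvPath))
    utils::write.csv(les[, setdiff(names(les), "pixels")], csvPath,
                     row.names = FALSE)
  invisible(rep)
}

#' Lesion label volume colored by vessel
#'
#' @param scores a [CacScores-class] with lesion table.
#' @param dim volume dimensions (nSlices, H, W).
#' @return Integer array with vessel codes 1-4 at lesion pixels.
#' @export
lesionLabelVolume <- function(scores, dim) {
  lab <- array(0L, dim = dim)
  les <- lesionTable(scores)
  for (r in seq_len(nrow(les))) {
    px <- les$pixels[[r]]
    code <- match(les$vessel[r], VESSELS)
    lab[cbind(les$slice[r], px)] <- code
  }
  lab
}
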