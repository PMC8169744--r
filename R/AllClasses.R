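#' CTVolume: an ordered stack of axial CT slices in Hounsfield Units
#'
#' Voxels are stored as a rank-3 array indexed (slice, row, col). Pixel spacing
#' is in mm/pixel (row, col) and slice spacing in mm. All downstream Agatston
#' arithmetic derives physical areas from `pixelSpacing`.
#'
#' @slot voxels numeric array, dim (nSlices, H, W), finite HU values.
#' @slot pixelSpacing numeric length-2, mm per pixel (row, col), > 0.
#' @slot sliceSpacing numeric scalar, mm between slice centres, > 0.
#' @slot sourceId character exam identifier.
#' @export
setClass("CTVolume", representation(
  voxels = "array",
  pixelSpacing = "numeric",
  sliceSpacing = "numeric",
  sourceId = "character"
))

setValidity("CTVolume", function(object) {
  d <- dim(object@voxels)
  if (length(d) != 3) return("voxels must be a rank-3 (slice, row, col) array")
  if (!all(is.finite(object@voxels))) return("HU values must be finite")
  if (length(object@pixelSpacing) != 2 || any(object@pixelSpacing <= 0))
    return("pixelSpacing must be two positive mm/pixel values")
  if (length(object@sliceSpacing) != 1 || object@sliceSpacing <= 0)
    return("sliceSpacing must be a positive scalar (mm)")
  TRUE
})

#' Construct a CTVolume
#'
#' @param voxels rank-3 HU array (slice, row, col).
#' @param pixelSpacing mm/pixel; a scalar is recycled to (row, col).
#' @param sliceSpacing mm between slices.
#' @param sourceId exam identifier.
#' @return A [CTVolume-class] object.
#' @examples
#' v <- CTVolume(array(0, c(2, 8, 8)), pixelSpacing = 0.5, sliceSpacing = 5)
#' nSlices(v)
#' @export
CTVolume <- function(voxels, pixelSpacing, sliceSpacing, sourceId = "exam") {
  if (length(pixelSpacing) == 1) pixelSpacing <- rep(pixelSpacing, 2)
  new("CTVolume", voxels = voxels, pixelSpacing = as.numeric(pixelSpacing),
      sliceSpacing = as.numeric(sliceSpacing), sourceId = sourceId)
}

#' ProbabilityVolume: per-pixel segmentation probabilities
#'
#' For every pixel of every slice a 5-component vector
#' (p_calc, p_LCA, p_LAD, p_LCX, p_RCA): channel "calc" is the binary calcium
#' probability in (0, 1); the four vessel channels lie in (0, 1) and sum to 1
#' at every pixel.
#'
#' @slot probs numeric array, dim (nSlices, H, W, 5); channel order
#'   calc, LCA, LAD, LCX, RCA.
#' @export
setClass("ProbabilityVolume", representation(probs = "array"))

setValidity("ProbabilityVolume", function(object) {
  d <- dim(object@probs)
  if (length(d) != 4 || d[4] != 5)
    return("probs must have dim (nSlices, H, W, 5)")
  if (d[1] == 0) return(TRUE)
  p <- object@probs
  if (any(p <= 0) || any(p >= 1))
    return("all probabilities must lie strictly inside (0, 1)")
  vs <- p[, , , 2] + p[, , , 3] + p[, , , 4] + p[, , , 5]
  if (max(abs(vs - 1)) > 1e-6)
    return("vessel probabilities must sum to 1 at every pixel")
  TRUE
})

#' Construct a ProbabilityVolume
#' @param probs array (nSlices, H, W, 5), channels calc, LCA, LAD, LCX, RCA.
#' @return A [ProbabilityVolume-class] object.
#' @export
ProbabilityVolume <- function(probs) new("ProbabilityVolume", probs = probs)

#' CacScores: vessel-specific Agatston scores for one exam
#'
#' @slot vessel named numeric, Agatston score per artery (LCA, LAD, LCX, RCA).
#' @slot total numeric, sum of the four vessel scores.
#' @slot bucket ordered factor, risk bucket I-V
#'   (scores 0, 1-10, 11-100, 101-400, >400).
#' @slot lesions data.frame, one row per lesion: slice, vessel, nPixels,
#'   grossAreaMm2, areaMm2 (pixels >130 HU only), maxHu, weight, agatston, and
#'   a list-column `pixels` of (row, col) index matrices.
#' @export
setClass("CacScores", representation(
  vessel = "numeric",
  total = "numeric",
  bucket = "factor",
  lesions = "data.frame"
))

setValidity("CacScores", function(object) {
  if (!identical(names(object@vessel), VESSELS))
    return("vessel scores must be named LCA, LAD, LCX, RCA")
  if (any(object@vessel < 0)) return("Agatston scores must be >= 0")
  if (abs(object@total - sum(object@vessel)) > 1e-9 * max(1, object@total))
    return("total must equal the sum of the vessel scores")
  if (!identical(levels(object@bucket), BUCKETS))
    return("bucket levels must be I..V")
  if (!identical(as.character(object@bucket), as.character(cacBucket(object@total))))
    return("bucket inconsistent with total score")
  TRUE
})

CacScores <- function(vessel, lesions = emptyLesionTable()) {
  vessel <- vessel[VESSELS]
  names(vessel) <- VESSELS
  total <- sum(vessel)
  new("CacScores", vessel = vessel, total = total,
      bucket = cacBucket(total), lesions = lesions)
}

#' PhantomGroundTruth: generator-side reference for a synthetic exam
#'
#' @slot labelVolume integer array (slice, H, W): 0 background, 1-4 the vessels
#'   LCA, LAD, LCX, RCA, 5 non-coronary calcium (aortic wall/cusps, annulus).
#' @slot scores [CacScores-class] computed analytically by the generator from
#'   the clean (pre-noise) lesion pixels.
#' @slot manifest data.frame: slice, vessel, nPixels, areaMm2, maxHu, weight,
#'   agatston per inserted lesion, with a `pixels` list-column.
#' @slot cleanVolume [CTVolume-class] noise-free HU volume (the reference
#'   standard is exact; noise is added only to the emitted exam volume).
#' @export
setClass("PhantomGroundTruth", representation(
  labelVolume = "array",
  scores = "CacScores",
  manifest = "data.frame",
  cleanVolume = "CTVolume"
))

#' CacSegModel: the two-head slice-wise segmentation model
#'
#' Encoder-decoder network mapping one preprocessed slice to a 5-channel
#' per-pixel output; channel 1 passes through a logistic function (calcium
#' head), channels 2-5 through a per-pixel softmax (vessel head).
#'
#' @slot config list, architecture configuration (see [modelConfig()]).
#' @slot params named list of numeric arrays (weights and biases).
#' @slot paramGroup named character, "new" or "pretrained" per parameter,
#'   controlling the learning-rate group during training.
#' @export
setClass("CacSegModel", representation(
  config = "list",
  params = "list",
  paramGroup = "character"
))

# ---- accessors -------------------------------------------------------------

#' @describeIn CTVolume number of axial slices
#' @param object a CTVolume
#' @export
setGeneric("nSlices", function(object) standardGeneric("nSlices"))
#' @export
setMethod("nSlices", "CTVolume", function(object) dim(object@voxels)[1])
#' @export
setMethod("nSlices", "ProbabilityVolume", function(object) dim(object@probs)[1])

#' Hounsfield-unit voxel array of a CTVolume
#' @param object a CTVolume
#' @export
setGeneric("huValues", function(object) standardGeneric("huValues"))
#' @export
setMethod("huValues", "CTVolume", function(object) object@voxels)

#' Pixel spacing (mm/pixel, row and col) of a CTVolume
#' @param object a CTVolume
#' @export
setGeneric("pixelSpacing", function(object) standardGeneric("pixelSpacing"))
#' @export
setMethod("pixelSpacing", "CTVolume", function(object) object@pixelSpacing)

#' Slice spacing (mm) of a CTVolume
#' @param object a CTVolume
#' @export
setGeneric("sliceSpacing", function(object) standardGeneric("sliceSpacing"))
#' @export
setMethod("sliceSpacing", "CTVolume", function(object) object@sliceSpacing)

#' Probability array of a ProbabilityVolume
#' @param object a ProbabilityVolume
#' @export
setGeneric("probValues", function(object) standardGeneric("probValues"))
#' @export
setMethod("probValues", "ProbabilityVolume", function(object) object@probs)

#' Per-vessel Agatston scores
#' @param object a CacScores
#' @export
setGeneric("vesselScores", function(object) standardGeneric("vesselScores"))
#' @export
setMethod("vesselScores", "CacScores", function(object) object@vessel)
#' @export
setMethod("vesselScores", "PhantomGroundTruth", function(object) object@scores@vessel)

#' Total Agatston score
#' @param object a CacScores
#' @export
setGeneric("totalScore", function(object) standardGeneric("totalScore"))
#' @export
setMethod("totalScore", "CacScores", function(object) object@total)
#' @export
setMethod("totalScore", "PhantomGroundTruth", function(object) object@scores@total)

#' Risk bucket (I-V)
#' @param object a CacScores
#' @export
setGeneric("riskBucket", function(object) standardGeneric("riskBucket"))
#' @export
setMethod("riskBucket", "CacScores", function(object) object@bucket)
#' @export
setMethod("riskBucket", "PhantomGroundTruth", function(object) object@scores@bucket)

#' Lesion table of a CacScores or PhantomGroundTruth
#' @param object a CacScores or PhantomGroundTruth
#' @export
setGeneric("lesionTable", function(object) standardGeneric("lesionTable"))
#' @export
setMethod("lesionTable", "CacScores", function(object) object@lesions)
#' @export
setMethod("lesionTable", "PhantomGroundTruth", function(object) object@manifest)

#' Ground-truth label volume of a phantom
#' @param object a PhantomGroundTruth
#' @export
setGeneric("labelVolume", function(object) standardGeneric("labelVolume"))
#' @export
setMethod("labelVolume", "PhantomGroundTruth", function(object) object@labelVolume)

#' Clean (pre-noise) HU volume of a phantom
#' @param object a PhantomGroundTruth
#' @export
setGeneric("cleanVolume", function(object) standardGeneric("cleanVolume"))
#' @export
setMethod("cleanVolume", "PhantomGroundTruth", function(object) object@cleanVolume)

#' Analytic reference scores of a phantom
#' @param object a PhantomGroundTruth
#' @export
setGeneric("referenceScores", function(object) standardGeneric("referenceScores"))
#' @export
setMethod("referenceScores", "PhantomGroundTruth", function(object) object@scores)

#' Model configuration of a CacSegModel
#' @param object a CacSegModel
#' @export
setGeneric("modelConfigOf", function(object) standardGeneric("modelConfigOf"))
#' @export
setMethod("modelConfigOf", "CacSegModel", function(object) object@config)

# ---- show ------------------------------------------------------------------

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("CTVolume '%s': %d slices of %dx%d px, %.3gx%.3g mm/px, %.3g mm spacing\n",
              object@sourceId, d[1], d[2], d[3],
              object@pixelSpacing[1], object@pixelSpacing[2], object@sliceSpacing))
  cat(sprintf("  HU range [%.0f, %.0f]\n",
              if (length(object@voxels)) min(object@voxels) else NA,
              if (length(object@voxels)) max(object@voxels) else NA))
})

setMethod("show", "ProbabilityVolume", function(object) {
  d <- dim(object@probs)
  cat(sprintf("ProbabilityVolume: %d slices of %dx%d px, channels %s\n",
              d[1], d[2], d[3], paste(PROB_CHANNELS, collapse = ", ")))
})

setMethod("show", "CacScores", function(object) {
  cat("CacScores (Agatston)\n")
  for (v in VESSELS) cat(sprintf("  %-4s %8.2f\n", v, object@vessel[[v]]))
  cat(sprintf("  total %7.2f  bucket %s  (%d lesions)\n",
              object@total, as.character(object@bucket), nrow(object@lesions)))
})

setMethod("show", "PhantomGroundTruth", function(object) {
  cat("PhantomGroundTruth\n")
  cat(sprintf("  %d lesions, analytic total %.2f (bucket %s)\n",
              nrow(object@manifest), object@scores@total,
              as.character(object@scores@bucket)))
})

setMethod("show", "CacSegModel", function(object) {
  cfg <- object@config
  np <- sum(vapply(object@params, length, integer(1)))
  cat(sprintf("CacSegModel: input %dx%d, encoder channels [%s], decoder [%s], SE %s\n",
              cfg$inputSize, cfg$inputSize,
              paste(cfg$encoderChannels, collapse = ","),
              paste(cfg$decoderChannels, collapse = ","),
              if (isTRUE(cfg$useSE)) "on" else "off"))
  cat(sprintf("  %d parameters (%d pretrained-group)\n",
              np, sum(object@paramGroup == "pretrained")))
})

#' An empty lesion table with the canonical columns
#' @return Zero-row data.frame with the lesion-table layout.
#' @export
emptyLesionTable <- function() {
  data.frame(slice = integer(0), vessel = character(0), nPixels = integer(0),
             grossAreaMm2 = numeric(0), areaMm2 = numeric(0), maxHu = numeric(0),
             weight = numeric(0), agatston = numeric(0),
             pixels = I(list()), stringsAsFactors = FALSE)
}
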