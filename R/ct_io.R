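#' Preprocessing configuration for model input
#'
#' HU values are clipped to `[clipLo, clipHi]` and mapped affinely to
#' `[-1, 1]` by subtracting the clip-range midpoint (`centerShift`) and
#' dividing by its half-width (`scale`); slices are then resampled to
#' `targetSize` with pixel spacing rescaled by the same factor so physical
#' areas are preserved downstream. The map is deterministic and
#' image-independent (no per-image statistics) and monotone in HU.
#'
#' @param clipLo lower HU clip (default -800).
#' @param clipHi upper HU clip (default 1200).
#' @param centerShift HU offset subtracted (default 200, the clip midpoint).
#' @param scale divisor (default 1000, the clip half-width).
#' @param targetSize model input size in pixels (default 512).
#' @return A list of class `cac_preprocess_config`.
#' @export
preprocessConfig <- function(clipLo = -800, clipHi = 1200, centerShift = 200,
                             scale = 1000, targetSize = 512) {
  stopifnot(clipLo < clipHi, scale > 0, targetSize >= 4)
  structure(list(clipLo = clipLo, clipHi = clipHi, centerShift = centerShift,
                 scale = scale, targetSize = targetSize),
            class = "cac_preprocess_config")
}

#' Preprocess one axial slice for the segmentation model
#'
#' @param slice numeric matrix of HU values.
#' @param cfg a [preprocessConfig()].
#' @param pixelSpacing mm/pixel of the input slice (row, col); a scalar is
#'   recycled.
#' @return List: `image` (targetSize x targetSize, values in `[-1, 1]`) and
#'   `pixelSpacing` (rescaled mm/pixel so total physical extent is unchanged).
#' @examples
#' pp <- preprocessSlice(matrix(200, 8, 8), preprocessConfig(targetSize = 16), 1)
#' range(pp$image)  # 200 HU is the clip midpoint -> 0
#' @export
preprocessSlice <- function(slice, cfg = preprocessConfig(), pixelSpacing = c(1, 1)) {
  stopifnot(is.matrix(slice), all(is.finite(slice)))
  if (length(pixelSpacing) == 1) pixelSpacing <- rep(pixelSpacing, 2)
  x <- pmin(pmax(slice, cfg$clipLo), cfg$clipHi)
  x <- (x - cfg$centerShift) / cfg$scale
  d <- dim(x)
  if (d[1] != cfg$targetSize || d[2] != cfg$targetSize) {
    newSpacing <- pixelSpacing * d / cfg$targetSize
    x <- resampleImage(x, cfg$targetSize, "bilinear")
  } else {
    newSpacing <- pixelSpacing
  }
  list(image = x, pixelSpacing = newSpacing)
}

# bilinear ("bilinear") or nearest-neighbour ("none") square resampling
resampleImage <- function(m, targetSize, filter = c("bilinear", "none")) {
  filter <- match.arg(filter)
  unclass(EBImage::resize(m, w = targetSize, h = targetSize, filter = filter))
}

#' Resample a categorical label image
#'
#' Nearest-neighbour only: labels must stay categorical.
#' @param labels integer matrix.
#' @param targetSize output pixels per side.
#' @return Integer matrix targetSize x targetSize.
#' @export
resampleLabels <- function(labels, targetSize) {
  out <- resampleImage(labels + 0, targetSize, "none")
  matrix(as.integer(round(out)), targetSize, targetSize)
}

#' Read a CT volume from disk
#'
#' Reads a NIfTI volume (RNifti), reordering to (slice, row, col) and taking
#' pixel/slice spacing from the header `pixdim`. A JSON sidecar written by
#' [writeCTVolume()] overrides header spacing when present. DICOM series are
#' not supported by this build; convert to NIfTI first.
#'
#' @param path path to a `.nii`/`.nii.gz` file.
#' @return A [CTVolume-class].
#' @export
readCTVolume <- function(path) {
  if (dir.exists(path) || grepl("\\.dcm$", path, ignore.case = TRUE))
    stop("DICOM series input is not supported; supply a NIfTI volume ",
         "(.nii/.nii.gz) with HU voxel values")
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) != 3) stop("expected a 3-D NIfTI volume")
  pd <- RNifti::pixdim(img)  # (x=col, y=row, z=slice)
  vox <- aperm(a, c(3, 2, 1)) # -> (slice, row, col)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  ps <- c(pd[2], pd[1]); ss <- pd[3]
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!is.null(meta$pixelSpacing)) ps <- as.numeric(meta$pixelSpacing)
    if (!is.null(meta$sliceSpacing)) ss <- as.numeric(meta$sliceSpacing)
  }
  CTVolume(vox, ps, ss, sourceId = basename(path))
}

#' Write a CT volume as NIfTI (+ JSON spacing sidecar)
#'
#' @param volume a [CTVolume-class].
#' @param path output `.nii`/`.nii.gz` path.
#' @return Invisibly, `path`.
#' @export
writeCTVolume <- function(volume, path) {
  stopifnot(is(volume, "CTVolume"))
  a <- aperm(huValues(volume), c(3, 2, 1))  # (col, row, slice) for NIfTI x,y,z
  ps <- pixelSpacing(volume)
  img <- RNifti::asNifti(a, pixdim = c(ps[2], ps[1], sliceSpacing(volume)))
  RNifti::writeNifti(img, path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(pixelSpacing = ps,
                            sliceSpacing = sliceSpacing(volume),
                            sourceId = volume@sourceId),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write an integer label volume as NIfTI
#'
#' @param labels integer array (slice, row, col).
#' @param pixelSpacing,sliceSpacing geometry in mm.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeLabelVolume <- function(labels, pixelSpacing, sliceSpacing, path) {
  a <- aperm(labels, c(3, 2, 1))
  img <- RNifti::asNifti(a, pixdim = c(pixelSpacing[2], pixelSpacing[1],
                                       sliceSpacing), datatype = "int16")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read an integer label volume from NIfTI
#'
#' @param path NIfTI path.
#' @return Integer array (slice, row, col).
#' @export
readLabelVolume <- function(path) {
  a <- as.array(RNifti::readNifti(path))
  storage.mode(a) <- "integer"
  aperm(a, c(3, 2, 1))
}
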