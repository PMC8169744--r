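#' Phantom specification
#'
#' Describes a synthetic chest-CT exam: axial geometry, four disjoint coronary
#' vessel territories carrying hyperdense (>130 HU) calcified lesions, plus
#' non-coronary distractor calcifications (aortic wall, aortic-root cusps,
#' mitral annulus) that must contribute nothing to any vessel score.
#'
#' Territories are four fixed quadrant-offset tubes running through the stack;
#' lesions are filled discs placed entirely inside their territory and never
#' straddle two territories. Each lesion carries a single clean HU value, so
#' the generator-side Agatston score is analytic and noise-free.
#'
#' @param nSlices number of axial slices (default 24, 5 mm apart, ~12 cm of
#'   cardiac coverage).
#' @param imageSize pixels per side (default 512).
#' @param pixelSpacing mm/pixel (default 0.5; 0.25 mm2 pixel area).
#' @param sliceSpacing mm (default 5, the routine axial reconstruction).
#' @param nLesionsPerVessel named integer vector (LCA, LAD, LCX, RCA).
#' @param lesionHuRange clean lesion attenuation interval, inside (130, 4000].
#' @param lesionRadiusRange disc radius interval in pixels.
#' @param nDistractors number of non-coronary cusp/annulus calcifications;
#'   0 disables all non-coronary calcium including the aortic wall ring.
#' @param distractorHuRange attenuation of distractor calcifications.
#' @param backgroundHu mean soft-tissue background (default 40).
#' @param noiseSd HU noise added to the emitted volume (default 12; the
#'   reference standard stays noise-free).
#' @param degradation "none" or "non_gated"; the latter applies
#'   [degradeToNonGated()] with `degradationParams` to the emitted volume.
#' @param degradationParams see [nonGatedParams()].
#' @param lesionPlan optional data.frame(vessel, radius, hu) fixing each
#'   lesion's size and attenuation (positions remain random); overrides
#'   `nLesionsPerVessel`, `lesionHuRange` and `lesionRadiusRange`.
#' @param seed integer RNG seed; generation is deterministic given the spec.
#' @return A list of class `cac_phantom_spec`.
#' @export
phantomSpec <- function(nSlices = 24, imageSize = 512, pixelSpacing = 0.5,
                        sliceSpacing = 5,
                        nLesionsPerVessel = c(LCA = 2, LAD = 3, LCX = 2, RCA = 3),
                        lesionHuRange = c(160, 800),
                        lesionRadiusRange = c(1.2, 2.5),
                        nDistractors = 3, distractorHuRange = c(200, 900),
                        backgroundHu = 40, noiseSd = 12,
                        degradation = c("none", "non_gated"),
                        degradationParams = nonGatedParams(),
                        lesionPlan = NULL, seed = 1L) {
  degradation <- match.arg(degradation)
  stopifnot(nSlices >= 1, imageSize >= 32, pixelSpacing > 0, sliceSpacing > 0,
            lesionHuRange[1] > 130, lesionHuRange[2] <= 4000,
            lesionHuRange[1] <= lesionHuRange[2],
            lesionRadiusRange[1] >= 1, noiseSd >= 0)
  if (is.null(names(nLesionsPerVessel))) names(nLesionsPerVessel) <- VESSELS
  stopifnot(setequal(names(nLesionsPerVessel), VESSELS),
            all(nLesionsPerVessel >= 0))
  if (!is.null(lesionPlan))
    stopifnot(all(c("vessel", "radius", "hu") %in% names(lesionPlan)),
              all(lesionPlan$vessel %in% VESSELS),
              all(lesionPlan$hu > 130), all(lesionPlan$hu <= 4000))
  structure(list(nSlices = nSlices, imageSize = imageSize,
                 pixelSpacing = pixelSpacing, sliceSpacing = sliceSpacing,
                 nLesionsPerVessel = nLesionsPerVessel[VESSELS],
                 lesionHuRange = lesionHuRange,
                 lesionRadiusRange = lesionRadiusRange,
                 nDistractors = nDistractors,
                 distractorHuRange = distractorHuRange,
                 backgroundHu = backgroundHu, noiseSd = noiseSd,
                 degradation = degradation,
                 degradationParams = degradationParams,
                 lesionPlan = lesionPlan, seed = as.integer(seed)),
            class = "cac_phantom_spec")
}

# fixed quadrant-offset territory geometry: centres at size/4 offsets from the
# image centre, radius size/8; the central aorta region (radius size/6) is
# disjoint from all four territories by construction.
territoryGeometry <- function(imageSize) {
  c0 <- (imageSize + 1) / 2
  off <- imageSize / 4
  centers <- rbind(LCA = c(c0 - off, c0 - off),
                   LAD = c(c0 - off, c0 + off),
                   LCX = c(c0 + off, c0 - off),
                   RCA = c(c0 + off, c0 + off))
  list(centers = centers, radius = imageSize / 8,
       aortaCenter = c(c0, c0), aortaRadius = imageSize / 6)
}

discPixels <- function(center, radius, imageSize) {
  r <- ceiling(radius)
  ci <- round(center[1]); cj <- round(center[2])
  ii <- max(1, ci - r):min(imageSize, ci + r)
  jj <- max(1, cj - r):min(imageSize, cj + r)
  g <- expand.grid(row = ii, col = jj)
  keep <- (g$row - ci)^2 + (g$col - cj)^2 <= radius^2
  as.matrix(g[keep, , drop = FALSE])
}

# generator-side density weight, written independently of module scoring
.phantomWeight <- function(hu) {
  if (hu >= 400) 4 else if (hu >= 300) 3 else if (hu >= 200) 2 else 1
}

#' Generate a synthetic CT exam with known calcium burden
#'
#' Places disc lesions in the four vessel territories and distractor
#' calcifications outside them, records a per-lesion manifest with the
#' analytic Agatston contribution (area of the clean >130 HU pixels times the
#' density weight of the clean peak HU), adds Gaussian HU noise to the emitted
#' volume, and optionally degrades it to a non-gated appearance.
#'
#' @param spec a [phantomSpec()].
#' @return List with elements `volume` ([CTVolume-class], the emitted noisy
#'   exam) and `groundTruth` ([PhantomGroundTruth-class]).
#' @examples
#' ph <- generatePhantom(phantomSpec(nSlices = 4, imageSize = 64, seed = 7,
#'   nLesionsPerVessel = c(LCA = 1, LAD = 1, LCX = 0, RCA = 0)))
#' totalScore(ph$groundTruth)
#' @export
generatePhantom <- function(spec) {
  stopifnot(inherits(spec, "cac_phantom_spec"))
  withSeed(spec$seed, {
    n <- spec$imageSize
    geo <- territoryGeometry(n)
    clean <- array(spec$backgroundHu, dim = c(spec$nSlices, n, n))
    labels <- array(0L, dim = c(spec$nSlices, n, n))

    plan <- spec$lesionPlan
    if (is.null(plan)) {
      plan <- do.call(rbind, lapply(VESSELS, function(v) {
        k <- spec$nLesionsPerVessel[[v]]
        if (k == 0) return(NULL)
        data.frame(vessel = v,
                   radius = runif(k, spec$lesionRadiusRange[1],
                                  spec$lesionRadiusRange[2]),
                   hu = runif(k, spec$lesionHuRange[1], spec$lesionHuRange[2]),
                   stringsAsFactors = FALSE)
      }))
      if (is.null(plan))
        plan <- data.frame(vessel = character(0), radius = numeric(0),
                           hu = numeric(0))
    }

    placed <- list()  # per slice+vessel: list of (center, radius)
    manifest <- list()
    for (r in seq_len(nrow(plan))) {
      v <- plan$vessel[r]; rad <- plan$radius[r]; hu <- plan$hu[r]
      ctr <- geo$centers[v, ]
      maxOff <- geo$radius - rad - 1
      if (maxOff <= 0)
        stop("territory too small to host a lesion of radius ", rad)
      ok <- FALSE
      for (att in seq_len(400)) {
        s <- sample.int(spec$nSlices, 1)
        ang <- runif(1, 0, 2 * pi); rr <- sqrt(runif(1)) * maxOff
        cen <- ctr + rr * c(cos(ang), sin(ang))
        key <- paste(s, v)
        prev <- placed[[key]]
        clash <- FALSE
        if (!is.null(prev)) {
          for (p in prev) {
            if (sqrt(sum((p$cen - cen)^2)) < p$rad + rad + 2) { clash <- TRUE; break }
          }
        }
        if (!clash) {
          placed[[key]] <- c(prev, list(list(cen = cen, rad = rad)))
          px <- discPixels(cen, rad, n)
          clean[cbind(s, px)] <- hu
          labels[cbind(s, px)] <- match(v, VESSELS)
          areaMm2 <- nrow(px) * spec$pixelSpacing^2
          w <- .phantomWeight(hu)
          m <- data.frame(slice = s, vessel = v, nPixels = nrow(px),
                          areaMm2 = areaMm2, maxHu = hu, weight = w,
                          agatston = areaMm2 * w, stringsAsFactors = FALSE)
          m$pixels <- I(list(px))
          manifest[[length(manifest) + 1L]] <- m
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop("lesion placement failed: territory ", v,
             " cannot host the requested lesion count")
    }
    manifest <- if (length(manifest)) do.call(rbind, manifest) else
      emptyLesionTable()[, c("slice", "vessel", "nPixels", "areaMm2",
                             "maxHu", "weight", "agatston", "pixels")]

    # distractors: aortic wall ring (every slice) + cusp/annulus discs;
    # nDistractors = 0 disables all non-coronary calcium
    if (spec$nDistractors > 0) {
      for (s in seq_len(spec$nSlices)) {
        ring <- ringPixels(geo$aortaCenter, geo$aortaRadius, 1.5, n)
        hu <- runif(1, spec$distractorHuRange[1], spec$distractorHuRange[2])
        clean[cbind(s, ring)] <- hu
        labels[cbind(s, ring)] <- 5L
      }
      for (k in seq_len(spec$nDistractors)) {
        s <- sample.int(spec$nSlices, 1)
        ang <- runif(1, 0, 2 * pi)
        cen <- geo$aortaCenter + (geo$aortaRadius * 0.55) * c(cos(ang), sin(ang))
        px <- discPixels(cen, runif(1, 1.2, 2.5), n)
        hu <- runif(1, spec$distractorHuRange[1], spec$distractorHuRange[2])
        sel <- labels[cbind(s, px)] == 0L
        px <- px[sel, , drop = FALSE]
        if (nrow(px) == 0) next
        clean[cbind(s, px)] <- hu
        labels[cbind(s, px)] <- 5L
      }
    }

    vessel <- setNames(numeric(4), VESSELS)
    if (nrow(manifest)) {
      agg <- tapply(manifest$agatston, factor(manifest$vessel, levels = VESSELS), sum)
      agg[is.na(agg)] <- 0
      vessel[VESSELS] <- agg[VESSELS]
    }
    scores <- CacScores(vessel)

    cleanVol <- CTVolume(clean, spec$pixelSpacing, spec$sliceSpacing,
                         sourceId = sprintf("phantom-%d", spec$seed))
    noisy <- clean + array(rnorm(length(clean), 0, spec$noiseSd), dim = dim(clean))
    vol <- CTVolume(noisy, spec$pixelSpacing, spec$sliceSpacing,
                    sourceId = sprintf("phantom-%d", spec$seed))
    if (spec$degradation == "non_gated")
      vol <- degradeToNonGated(vol, spec$degradationParams)

    gt <- new("PhantomGroundTruth", labelVolume = labels, scores = scores,
              manifest = manifest, cleanVolume = cleanVol)
    list(volume = vol, groundTruth = gt)
  })
}

ringPixels <- function(center, radius, thickness, imageSize) {
  r <- ceiling(radius + thickness)
  ii <- max(1, round(center[1]) - r):min(imageSize, round(center[1]) + r)
  jj <- max(1, round(center[2]) - r):min(imageSize, round(center[2]) + r)
  g <- expand.grid(row = ii, col = jj)
  d <- sqrt((g$row - center[1])^2 + (g$col - center[2])^2)
  keep <- d >= radius - thickness & d <= radius
  as.matrix(g[keep, , drop = FALSE])
}

#' Non-gated degradation parameters
#'
#' Emulates the acquisition differences of routine non-gated chest CT against
#' gated coronary CT: cardiac-motion blur along one in-plane axis, partial
#' mixing of adjacent 5 mm slices (thicker effective collimation), and higher
#' image noise.
#'
#' @param blurSigma Gaussian sigma of the motion blur in pixels (default 2).
#' @param extraNoiseSd additional HU noise (default 10).
#' @param sliceMix weight given to each neighbouring slice in a 3-slice
#'   average, in `[0, 1/3)` (default 0.2).
#' @param axis in-plane motion axis, "row" or "col".
#' @param seed RNG seed for the added noise.
#' @return A list of class `cac_nongated_params`.
#' @export
nonGatedParams <- function(blurSigma = 2, extraNoiseSd = 10, sliceMix = 0.2,
                           axis = c("col", "row"), seed = 1L) {
  axis <- match.arg(axis)
  stopifnot(is.finite(blurSigma), blurSigma >= 0, extraNoiseSd >= 0,
            sliceMix >= 0, sliceMix < 1 / 3)
  structure(list(blurSigma = blurSigma, extraNoiseSd = extraNoiseSd,
                 sliceMix = sliceMix, axis = axis, seed = as.integer(seed)),
            class = "cac_nongated_params")
}

gauss1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

# 1-D convolution along matrix rows or cols with replicate padding
blur1d <- function(m, kernel, along = c("col", "row")) {
  along <- match.arg(along)
  if (along == "row") return(t(blur1d(t(m), kernel, "col")))
  r <- (length(kernel) - 1L) / 2L
  n <- ncol(m)
  padded <- cbind(m[, rep(1L, r), drop = FALSE], m, m[, rep(n, r), drop = FALSE])
  out <- matrix(0, nrow(m), n)
  for (k in seq_along(kernel))
    out <- out + kernel[k] * padded[, k:(k + n - 1), drop = FALSE]
  out
}

#' Degrade a gated volume to a non-gated appearance
#'
#' Applies in-plane motion blur, adjacent-slice mixing and extra HU noise.
#' The paired gated ground truth is deliberately left untouched: gated scores
#' remain the reference standard for the degraded exam. With all parameters at
#' zero the input is returned unchanged.
#'
#' @param volume a [CTVolume-class].
#' @param params a [nonGatedParams()].
#' @return A degraded [CTVolume-class] with identical geometry.
#' @export
degradeToNonGated <- function(volume, params = nonGatedParams()) {
  stopifnot(is(volume, "CTVolume"), inherits(params, "cac_nongated_params"))
  if (params$blurSigma == 0 && params$extraNoiseSd == 0 && params$sliceMix == 0)
    return(volume)
  v <- huValues(volume)
  nS <- dim(v)[1]
  out <- v
  if (params$blurSigma > 0) {
    k <- gauss1d(params$blurSigma)
    for (s in seq_len(nS))
      out[s, , ] <- blur1d(matrix(out[s, , ], dim(v)[2], dim(v)[3]), k,
                           along = params$axis)
  }
  if (params$sliceMix > 0 && nS > 1) {
    w <- params$sliceMix
    mixed <- out
    for (s in seq_len(nS)) {
      lo <- max(1, s - 1); hi <- min(nS, s + 1)
      mixed[s, , ] <- (1 - 2 * w) * out[s, , ] + w * out[lo, , ] + w * out[hi, , ]
    }
    out <- mixed
  }
  if (params$extraNoiseSd > 0) {
    out <- withSeed(params$seed,
                    out + array(rnorm(length(out), 0, params$extraNoiseSd),
                                dim = dim(out)))
  }
  CTVolume(out, pixelSpacing(volume), sliceSpacing(volume),
           sourceId = paste0(volume@sourceId, "-nongated"))
}

#' Phantom specification targeting one risk bucket
#'
#' Builds a lesion plan whose analytic total Agatston score is guaranteed to
#' fall in the requested bucket: lesions of bucket-appropriate disc radius and
#' attenuation are added one at a time until the running analytic total passes
#' a random target drawn safely inside the bucket; the maximal single-lesion
#' overshoot keeps the total inside the bucket's upper bound.
#'
#' @param bucket "I".."V".
#' @param seed RNG seed.
#' @param nSlices,imageSize,pixelSpacing geometry passed to [phantomSpec()].
#' @param ... further arguments to [phantomSpec()].
#' @return A [phantomSpec()] whose generated phantom lands in `bucket`.
#' @export
phantomSpecForBucket <- function(bucket, seed = 1L, nSlices = 8,
                                 imageSize = 128, pixelSpacing = 0.5, ...) {
  bucket <- match.arg(as.character(bucket), BUCKETS)
  pxArea <- pixelSpacing^2
  plan <- withSeed(seed + 7L, {
    if (bucket == "I") {
      data.frame(vessel = character(0), radius = numeric(0), hu = numeric(0))
    } else if (bucket == "II") {
      # one small low-density lesion: 5 px at r=1.2, weight 1 -> score 5*pxArea
      data.frame(vessel = sample(VESSELS, 1), radius = 1.2,
                 hu = runif(1, 150, 195), stringsAsFactors = FALSE)
    } else {
      cfgs <- list(
        III = list(radius = 1.5, nPix = 9, huLo = 150, huHi = 1000,
                   tLo = c(15, 80)),
        IV = list(radius = 2.0, nPix = 13, huLo = 150, huHi = 1000,
                  tLo = c(120, 340)),
        V = list(radius = 2.5, nPix = 21, huLo = 300, huHi = 1000,
                 tLo = c(420, 560)))
      cf <- cfgs[[bucket]]
      target <- runif(1, cf$tLo[1], cf$tLo[2])
      rows <- list(); tot <- 0; vi <- sample.int(4, 1)
      while (tot < target) {
        hu <- runif(1, cf$huLo, cf$huHi)
        tot <- tot + cf$nPix * pxArea * .phantomWeight(hu)
        rows[[length(rows) + 1L]] <- data.frame(
          vessel = VESSELS[(vi + length(rows)) %% 4 + 1], radius = cf$radius,
          hu = hu, stringsAsFactors = FALSE)
      }
      do.call(rbind, rows)
    }
  })
  phantomSpec(nSlices = nSlices, imageSize = imageSize,
              pixelSpacing = pixelSpacing, lesionPlan = plan, seed = seed, ...)
}

#' Generate a stratified cohort of paired phantoms
#'
#' @param nExams number of exams (>= 1).
#' @param buckets target bucket per exam; default cycles I-V so every bucket
#'   is represented whenever `nExams >= 5`, with per-bucket counts matching the
#'   requested stratification exactly.
#' @param seed master seed; per-exam seeds are derived from it.
#' @param ... geometry arguments passed to [phantomSpecForBucket()].
#' @return List of per-exam lists (volume, groundTruth, spec).
#' @export
makePhantomCohort <- function(nExams, buckets = NULL, seed = 1L, ...) {
  stopifnot(nExams >= 1)
  if (is.null(buckets)) buckets <- rep(BUCKETS, length.out = nExams)
  stopifnot(length(buckets) == nExams, all(as.character(buckets) %in% BUCKETS))
  seeds <- withSeed(seed, sample.int(.Machine$integer.max - 10L, nExams))
  lapply(seq_len(nExams), function(i) {
    spec <- phantomSpecForBucket(buckets[i], seed = seeds[i], ...)
    ph <- generatePhantom(spec)
    if (as.character(riskBucket(ph$groundTruth)) != as.character(buckets[i]))
      stop("internal error: generated phantom missed its target bucket")
    c(ph, list(spec = spec))
  })
}

#' Write a phantom to disk (NIfTI volume + labels + JSON manifest)
#'
#' @param phantom list from [generatePhantom()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writePhantom <- function(phantom, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pImg <- file.path(dir, "image.nii.gz")
  pLab <- file.path(dir, "labels.nii.gz")
  pMan <- file.path(dir, "manifest.json")
  writeCTVolume(phantom$volume, pImg)
  writeLabelVolume(labelVolume(phantom$groundTruth),
                   pixelSpacing(phantom$volume),
                   sliceSpacing(phantom$volume), pLab)
  man <- lesionTable(phantom$groundTruth)
  jsonlite::write_json(
    list(vessel = as.list(vesselScores(phantom$groundTruth)),
         total = totalScore(phantom$groundTruth),
         bucket = as.character(riskBucket(phantom$groundTruth)),
         lesions = man[, setdiff(names(man), "pixels")]),
    pMan, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(c(pImg, pLab, pMan))
}
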