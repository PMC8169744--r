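#' Training configuration
#'
#' Mirrors the published recipe: Adam (beta1 0.9, beta2 0.999), learning rate
#' 1e-3 for randomly initialised weights and 1e-4 for pretrained weights,
#' linear warmup for 5k iterations followed by cosine annealing over 300k
#' iterations, the pretrained group's schedule delayed by 10k iterations,
#' L2 regularisation 1e-4 on all learnable parameters, and mini-batches of 64
#' slices containing calcified lesions. `scaleFactor` shrinks every iteration
#' count (warmup, anneal, delay) by the same multiplier for desk-scale runs.
#'
#' @param batchSize slices per mini-batch (default 64).
#' @param lrNew base learning rate of the randomly initialised group.
#' @param lrPretrained base learning rate of the pretrained group.
#' @param adamBeta1,adamBeta2 Adam moment decay rates.
#' @param warmupIters linear warmup length (default 5000).
#' @param annealIters cosine annealing length (default 300000).
#' @param pretrainedDelayIters schedule delay of the pretrained group.
#' @param weightDecay L2 coefficient applied to all learnable parameters.
#' @param diceSmooth additive smoothing constant of the Dice loss.
#' @param scaleFactor multiplier applied to warmup/anneal/delay counts.
#' @param seed RNG seed for sampling.
#' @return A list of class `cac_training_config`.
#' @export
trainingConfig <- function(batchSize = 64, lrNew = 1e-3, lrPretrained = 1e-4,
                           adamBeta1 = 0.9, adamBeta2 = 0.999,
                           warmupIters = 5000, annealIters = 300000,
                           pretrainedDelayIters = 10000, weightDecay = 1e-4,
                           diceSmooth = 1, scaleFactor = 1, seed = 1L) {
  stopifnot(batchSize >= 1, lrNew > 0, lrPretrained > 0,
            warmupIters >= 1, annealIters >= 1, warmupIters < annealIters,
            pretrainedDelayIters >= 0, weightDecay >= 0, diceSmooth > 0,
            scaleFactor > 0)
  structure(list(batchSize = as.integer(batchSize), lrNew = lrNew,
                 lrPretrained = lrPretrained, adamBeta1 = adamBeta1,
                 adamBeta2 = adamBeta2,
                 warmupIters = max(1L, as.integer(round(warmupIters * scaleFactor))),
                 annealIters = max(2L, as.integer(round(annealIters * scaleFactor))),
                 pretrainedDelayIters = as.integer(round(pretrainedDelayIters * scaleFactor)),
                 weightDecay = weightDecay, diceSmooth = diceSmooth,
                 scaleFactor = scaleFactor, seed = as.integer(seed)),
            class = "cac_training_config")
}

#' Warmup + cosine-annealing learning-rate schedule
#'
#' Linear ramp 0 -> `baseLr` over `warmupIters`, then half-cosine decay
#' `baseLr` -> 0 over `annealIters`, zero afterwards. The pretrained parameter
#' group evaluates the same function at `iteration - pretrainedDelayIters`,
#' clamped at 0 — an exact time shift of the main schedule.
#'
#' @param iteration iteration counter (>= 0), vectorised.
#' @param baseLr base learning rate of the group.
#' @param cfg a [trainingConfig()] (already scaled).
#' @param pretrained evaluate the delayed pretrained-group schedule.
#' @return Learning rate(s).
#' @examples
#' cfg <- trainingConfig()
#' lrSchedule(c(0, 5000, 305000), 1e-3, cfg)
#' @export
lrSchedule <- function(iteration, baseLr, cfg, pretrained = FALSE) {
  stopifnot(all(iteration >= 0))
  it <- if (pretrained) pmax(0, iteration - cfg$pretrainedDelayIters) else iteration
  w <- cfg$warmupIters; a <- cfg$annealIters
  ifelse(it < w, baseLr * it / w,
         ifelse(it <= w + a, baseLr * (1 + cospi((it - w) / a)) / 2, 0))
}

#' Build a training dataset from phantoms
#'
#' Flattens a phantom cohort into per-slice training samples: the raw HU
#' slice, its preprocessed model input, the binary calcium mask (vessel
#' labels 1-4; non-coronary calcium is background for the calcium head) and
#' the vessel label map.
#'
#' @param cohort list from [makePhantomCohort()] (or a single
#'   [generatePhantom()] result wrapped in a list).
#' @param ppCfg a [preprocessConfig()] matching the intended model.
#' @return List of class `cac_training_set`: samples plus geometry.
#' @export
makeTrainingSlices <- function(cohort, ppCfg = preprocessConfig(targetSize = 64)) {
  samples <- list()
  for (ex in cohort) {
    v <- huValues(ex$volume)
    lab <- labelVolume(ex$groundTruth)
    ps <- pixelSpacing(ex$volume)
    for (s in seq_len(dim(v)[1])) {
      sliceHu <- matrix(v[s, , ], dim(v)[2], dim(v)[3])
      labS <- matrix(lab[s, , ], dim(v)[2], dim(v)[3])
      pp <- preprocessSlice(sliceHu, ppCfg, ps)
      if (!identical(dim(labS), dim(pp$image)))
        labS <- resampleLabels(labS, ppCfg$targetSize)
      vesselMap <- ifelse(labS >= 1 & labS <= 4, labS, 0L)
      samples[[length(samples) + 1L]] <- list(
        x = pp$image, hu = sliceHu, huSpacing = ps,
        calcMask = (vesselMap > 0) + 0, vesselMap = vesselMap)
    }
  }
  structure(list(samples = samples), class = "cac_training_set")
}

#' Initialise the eligible slice pool
#'
#' Training starts from slices containing calcified lesions only; the pool is
#' later grown by [expandHardNegatives()] and never shrinks.
#'
#' @param dataset a [makeTrainingSlices()] result.
#' @param seed sampling seed.
#' @return Pool state list: `pool` (sample indices), `order`, `pos`, `epoch`.
#' @export
newSamplerPool <- function(dataset, seed = 1L) {
  stopifnot(inherits(dataset, "cac_training_set"))
  pool <- which(vapply(dataset$samples, function(s) any(s$calcMask > 0), logical(1)))
  if (!length(pool)) stop("dataset has no lesion-bearing slice")
  list(pool = pool, order = integer(0), pos = 0L, epoch = 0L,
       seed = as.integer(seed))
}

#' Sample one mini-batch of slice indices
#'
#' Epochs are permutations of the current eligible pool; the sequence is fully
#' reproducible from the pool state. The sampler never emits a slice outside
#' the pool.
#'
#' @param dataset a [makeTrainingSlices()] result.
#' @param cfg a [trainingConfig()] (uses `batchSize`).
#' @param state pool state from [newSamplerPool()].
#' @return List: `indices` (batch of sample indices), updated `state`, and
#'   `epochEnded` (TRUE when this batch crossed an epoch boundary).
#' @export
sampleMinibatch <- function(dataset, cfg, state) {
  n <- cfg$batchSize
  idx <- integer(0)
  epochEnded <- FALSE
  while (length(idx) < n) {
    if (state$pos >= length(state$order)) {
      state$epoch <- state$epoch + 1L
      state$order <- withSeed(state$seed + state$epoch,
                              sample(state$pool, length(state$pool)))
      state$pos <- 0L
      if (state$epoch > 1L) epochEnded <- TRUE
    }
    take <- min(n - length(idx), length(state$order) - state$pos)
    idx <- c(idx, state$order[state$pos + seq_len(take)])
    state$pos <- state$pos + take
  }
  list(indices = idx, state = state, epochEnded = epochEnded)
}

#' Composite segmentation loss
#'
#' Dice loss (with additive smoothing) on the calcium head plus cross-entropy
#' on the vessel head, the latter evaluated only on pixels inside the
#' ground-truth calcium mask — vessel identity is undefined elsewhere.
#'
#' @param probs H x W x 5 probability array from [netForward()].
#' @param calcMask H x W binary ground-truth calcium mask.
#' @param vesselMap H x W integer vessel labels (0 outside calcium, 1-4 =
#'   LCA, LAD, LCX, RCA).
#' @param smooth Dice smoothing constant (default 1); guarantees a finite
#'   loss on all-background slices.
#' @return List: `loss`, `dice`, `ce`.
#' @export
compositeLoss <- function(probs, calcMask, vesselMap, smooth = 1) {
  p <- probs[, , 1]
  stopifnot(identical(dim(p), dim(calcMask)), identical(dim(p), dim(vesselMap)))
  num <- 2 * sum(p * calcMask) + smooth
  den <- sum(p) + sum(calcMask) + smooth
  dice <- 1 - num / den
  idx <- which(vesselMap > 0)
  ce <- if (length(idx)) {
    pv <- vapply(1:4, function(ch) probs[, , ch + 1][idx], numeric(length(idx)))
    pv <- matrix(pv, nrow = length(idx))
    -mean(log(pv[cbind(seq_along(idx), vesselMap[idx])]))
  } else 0
  list(loss = dice + ce, dice = dice, ce = ce)
}

# gradient of the composite loss wrt the 5-channel logits
lossGradient <- function(probs, logits, calcMask, vesselMap, smooth = 1) {
  d <- dim(probs)
  dlog <- array(0, dim = d)
  p <- probs[, , 1]
  num <- 2 * sum(p * calcMask) + smooth
  den <- sum(p) + sum(calcMask) + smooth
  dLdp <- -(2 * calcMask * den - num) / den^2
  dlog[, , 1] <- dLdp * p * (1 - p)
  idx <- which(vesselMap > 0)
  if (length(idx)) {
    n <- length(idx)
    for (ch in 1:4) {
      pc <- probs[, , ch + 1]
      gch <- array(0, dim = d[1:2])
      gch[idx] <- (pc[idx] - (vesselMap[idx] == ch)) / n
      dlog[, , ch + 1] <- gch
    }
  }
  dlog
}

#' Grow the eligible pool with hard negatives
#'
#' After an epoch, calcium-free slices on which the current model predicts at
#' least one lesion (after the full second-stage thresholding: p_calc > 0.5,
#' connected components, optional minimum area) are added to the eligible
#' pool. The pool never shrinks and additions are idempotent.
#'
#' @param model a [CacSegModel-class].
#' @param dataset a [makeTrainingSlices()] result.
#' @param state pool state from [newSamplerPool()].
#' @param scoringCfg a [scoringConfig()] defining "predicted lesion".
#' @return Updated pool state.
#' @export
expandHardNegatives <- function(model, dataset, state,
                                scoringCfg = scoringConfig()) {
  negatives <- setdiff(seq_along(dataset$samples), state$pool)
  added <- integer(0)
  for (i in negatives) {
    smp <- dataset$samples[[i]]
    if (any(smp$calcMask > 0)) next  # only calcium-free slices are negatives
    out <- netForward(model, smp$x)
    probs <- clampProbs(out$probs)
    hu <- smp$hu
    if (!identical(dim(probs)[1:2], dim(hu))) {
      back <- array(0, dim = c(dim(hu), 5))
      for (ch in 1:5)
        back[, , ch] <- unclass(EBImage::resize(probs[, , ch], w = nrow(hu),
                                                h = ncol(hu), filter = "bilinear"))
      probs <- clampProbs(back)
    }
    pv <- ProbabilityVolume(array(probs, dim = c(1, dim(probs))))
    vol <- CTVolume(array(hu, dim = c(1, dim(hu))), smp$huSpacing, 5)
    mask <- binarizeCalcium(pv, scoringCfg)
    les <- extractLesions(mask, vol, scoringCfg)
    if (nrow(les) >= 1) added <- c(added, i)
  }
  state$pool <- sort(union(state$pool, added))
  state
}

#' Train the segmentation model
#'
#' Assembles the full recipe: lesion-slice sampling, composite Dice +
#' cross-entropy loss, Adam with per-group warmup/cosine learning rates, L2
#' regularisation, and optional hard-negative pool expansion at epoch
#' boundaries. Deterministic for a fixed seed. Aborts with a diagnostic if the
#' loss becomes non-finite.
#'
#' @param model a [CacSegModel-class].
#' @param dataset a [makeTrainingSlices()] result.
#' @param cfg a [trainingConfig()].
#' @param nIters iterations to run; default `warmupIters + annealIters`
#'   (after scaling). Zero returns the model unchanged.
#' @param hardNegatives expand the pool with misclassified calcium-free
#'   slices at every epoch end.
#' @param checkpointDir optional directory for periodic checkpoints.
#' @param checkpointEvery checkpoint cadence in iterations.
#' @return List: `model` (trained), `trace` (data.frame with iteration,
#'   per-group learning rates and loss components), `pool` (final pool state).
#' @export
trainModel <- function(model, dataset, cfg = trainingConfig(),
                       nIters = NULL, hardNegatives = TRUE,
                       checkpointDir = NULL, checkpointEvery = 1000L) {
  stopifnot(is(model, "CacSegModel"), inherits(dataset, "cac_training_set"))
  if (is.null(nIters)) nIters <- cfg$warmupIters + cfg$annealIters
  state <- newSamplerPool(dataset, seed = cfg$seed)
  if (nIters == 0)
    return(list(model = model, trace = data.frame(), pool = state))
  params <- model@params
  m1 <- lapply(params, function(p) p * 0)
  m2 <- m1
  grp <- model@paramGroup
  trace <- vector("list", nIters)
  for (it in seq_len(nIters)) {
    mb <- sampleMinibatch(dataset, cfg, state)
    state <- mb$state
    gAcc <- NULL
    lossSum <- diceSum <- ceSum <- 0
    for (i in mb$indices) {
      smp <- dataset$samples[[i]]
      fw <- netForward(model, smp$x, cache = TRUE)
      L <- compositeLoss(fw$probs, smp$calcMask, smp$vesselMap, cfg$diceSmooth)
      dlog <- lossGradient(fw$probs, fw$logits, smp$calcMask, smp$vesselMap,
                           cfg$diceSmooth)
      g <- netBackward(model, fw$cache, dlog)
      if (is.null(gAcc)) gAcc <- g else
        for (nm in names(g)) gAcc[[nm]] <- gAcc[[nm]] + g[[nm]]
      lossSum <- lossSum + L$loss; diceSum <- diceSum + L$dice; ceSum <- ceSum + L$ce
    }
    nb <- length(mb$indices)
    if (!is.finite(lossSum))
      stop(sprintf("training diverged at iteration %d (non-finite loss)", it))
    lrN <- lrSchedule(it - 1L, cfg$lrNew, cfg)
    lrP <- lrSchedule(it - 1L, cfg$lrPretrained, cfg, pretrained = TRUE)
    for (nm in names(params)) {
      gr <- gAcc[[nm]] / nb + cfg$weightDecay * params[[nm]]
      m1[[nm]] <- cfg$adamBeta1 * m1[[nm]] + (1 - cfg$adamBeta1) * gr
      m2[[nm]] <- cfg$adamBeta2 * m2[[nm]] + (1 - cfg$adamBeta2) * gr^2
      mh <- m1[[nm]] / (1 - cfg$adamBeta1^it)
      vh <- m2[[nm]] / (1 - cfg$adamBeta2^it)
      lr <- if (grp[[nm]] == "pretrained") lrP else lrN
      params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + 1e-8)
    }
    model@params <- params
    trace[[it]] <- data.frame(iteration = it, lrNew = lrN, lrPretrained = lrP,
                              loss = lossSum / nb, dice = diceSum / nb,
                              ce = ceSum / nb)
    if (mb$epochEnded && hardNegatives)
      state <- expandHardNegatives(model, dataset, state)
    if (!is.null(checkpointDir) && it %% checkpointEvery == 0) {
      if (!dir.exists(checkpointDir)) dir.create(checkpointDir, recursive = TRUE)
      saveModel(model, file.path(checkpointDir, sprintf("iter%06d.rds", it)))
    }
  }
  list(model = model, trace = do.call(rbind, trace), pool = state)
}

#' Dice overlap of predicted calcium against a ground-truth mask
#'
#' Predicts each sample slice, thresholds p_calc at 0.5 and computes the Dice
#' coefficient of the pooled binary masks.
#'
#' @param model a [CacSegModel-class].
#' @param dataset a [makeTrainingSlices()] result.
#' @return Dice coefficient in `[0, 1]`.
#' @export
trainingDice <- function(model, dataset) {
  inter <- szP <- szG <- 0
  for (smp in dataset$samples) {
    out <- netForward(model, smp$x)
    pred <- out$probs[, , 1] > 0.5
    inter <- inter + sum(pred & smp$calcMask > 0)
    szP <- szP + sum(pred); szG <- szG + sum(smp$calcMask > 0)
  }
  if (szP + szG == 0) return(1)
  2 * inter / (szP + szG)
}
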