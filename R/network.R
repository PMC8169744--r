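#' Segmentation model configuration
#'
#' Encoder-decoder architecture for slice-wise calcium segmentation. Every
#' trunk convolution is followed by instance normalisation (per-slice,
#' per-channel, with learnable scale and shift) and ReLU. The
#' encoder is a stack of four downsampling convolutional stages (3x3 stride-2
#' convolution, 3x3 convolution, optional squeeze-excitation channel gating)
#' reaching 1/16 resolution; skip connections are taken at three levels — the
#' encoder feature maps at 1/2, 1/4 and 1/8 resolution — so the deepest
#' decoder block is the one without a skip. The decoder is a stack of 4
#' blocks, each performing 2x up-sampling with a 4x4 transposed convolution
#' sandwiched between two 3x3 convolutions. A 1x1
#' projection yields 5 channels: channel 1 passes through a logistic function
#' (calcium head), channels 2-5 through a per-pixel softmax (vessel head) —
#' both heads share the entire trunk and split only at the projection.
#'
#' The default widths follow the halve-per-block rule (256-128-64-32). The
#' full-scale published encoders (50-layer SE-ResNeXt with grouped
#' convolutions) are beyond what this package trains on a CPU; the reduced
#' encoder keeps the two-head output contract at any width.
#'
#' @param inputSize model input resolution (must be divisible by 16).
#' @param encoderChannels widths of the four encoder stages.
#' @param decoderChannels widths of the four decoder blocks.
#' @param useSE include squeeze-excitation gating in encoder stages.
#' @param seReduction SE bottleneck reduction ratio (default 4).
#' @param nVesselClasses number of artery classes (fixed at 4).
#' @param initSeed RNG seed for weight initialisation.
#' @return A list of class `cac_model_config`.
#' @export
modelConfig <- function(inputSize = 512,
                        encoderChannels = c(64, 128, 256, 512),
                        decoderChannels = c(256, 128, 64, 32),
                        useSE = TRUE, seReduction = 4,
                        nVesselClasses = 4, initSeed = 1L) {
  stopifnot(inputSize %% 16 == 0, length(encoderChannels) == 4,
            length(decoderChannels) == 4, all(encoderChannels >= 1),
            all(decoderChannels >= 1), nVesselClasses == 4)
  structure(list(inputSize = inputSize,
                 encoderChannels = as.integer(encoderChannels),
                 decoderChannels = as.integer(decoderChannels),
                 useSE = isTRUE(useSE), seReduction = seReduction,
                 nVesselClasses = 4L, initSeed = as.integer(initSeed)),
            class = "cac_model_config")
}

#' A desk-scale model configuration
#'
#' Small widths and a 64x64 input for CPU training and tests; the output
#' contract (5 channels, vessel probabilities summing to 1) is identical to
#' the full configuration.
#' @param inputSize input resolution (default 64).
#' @param initSeed RNG seed.
#' @return A [modelConfig()].
#' @export
reducedModelConfig <- function(inputSize = 64, initSeed = 1L) {
  modelConfig(inputSize = inputSize, encoderChannels = c(8, 16, 24, 32),
              decoderChannels = c(24, 16, 12, 8), initSeed = initSeed)
}

heInit <- function(dims, fanIn) {
  array(rnorm(prod(dims), 0, sqrt(2 / fanIn)), dim = dims)
}

#' Build the two-head segmentation model
#'
#' @param cfg a [modelConfig()].
#' @param encoderWeights optional named list of encoder parameter arrays
#'   (externally supplied, e.g. from pretraining); loaded parameters form the
#'   "pretrained" learning-rate group, everything else the "new" group.
#' @return A [CacSegModel-class].
#' @export
buildModel <- function(cfg = modelConfig(), encoderWeights = NULL) {
  stopifnot(inherits(cfg, "cac_model_config"))
  ec <- cfg$encoderChannels; dc <- cfg$decoderChannels
  params <- list()
  # every trunk convolution is followed by instance normalisation (per-slice,
  # per-channel) with learnable scale `_g` and shift `_b`, then ReLU; the
  # convolutions themselves are bias-free since the normalisation removes
  # any mean. The 1x1 head is a plain biased projection.
  addConv <- function(name, dims, fanIn) {
    params[[paste0(name, "_w")]] <<- heInit(dims, fanIn)
    params[[paste0(name, "_g")]] <<- rep(1, dims[4])
    params[[paste0(name, "_b")]] <<- numeric(dims[4])
  }
  withSeed(cfg$initSeed, {
    cin <- 1L
    for (k in 1:4) {
      addConv(sprintf("e%d_c1", k), c(3, 3, cin, ec[k]), 9 * cin)
      addConv(sprintf("e%d_c2", k), c(3, 3, ec[k], ec[k]), 9 * ec[k])
      if (cfg$useSE) {
        cr <- max(1L, ec[k] %/% cfg$seReduction)
        params[[sprintf("e%d_se_w1", k)]] <- matrix(rnorm(cr * ec[k], 0, sqrt(2 / ec[k])), cr, ec[k])
        params[[sprintf("e%d_se_b1", k)]] <- numeric(cr)
        params[[sprintf("e%d_se_w2", k)]] <- matrix(rnorm(ec[k] * cr, 0, sqrt(2 / cr)), ec[k], cr)
        params[[sprintf("e%d_se_b2", k)]] <- numeric(ec[k])
      }
      cin <- ec[k]
    }
    addConv("bn", c(3, 3, ec[4], ec[4]), 9 * ec[4])
    inCh <- c(ec[4], dc[1] + ec[3], dc[2] + ec[2], dc[3] + ec[1])
    for (k in 1:4) {
      addConv(sprintf("d%d_a", k), c(3, 3, inCh[k], dc[k]), 9 * inCh[k])
      addConv(sprintf("d%d_t", k), c(4, 4, dc[k], dc[k]), 4 * dc[k])
      addConv(sprintf("d%d_b", k), c(3, 3, dc[k], dc[k]), 9 * dc[k])
    }
    params[["head_w"]] <- heInit(c(1, 1, dc[4], 5), dc[4]) * 0.1
    params[["head_b"]] <- numeric(5)
  })
  group <- setNames(rep("new", length(params)), names(params))
  if (!is.null(encoderWeights)) {
    encNames <- grep("^e[1-4]_", names(params), value = TRUE)
    for (nm in names(encoderWeights)) {
      if (!nm %in% encNames)
        stop("encoderWeights contains non-encoder parameter: ", nm)
      if (!identical(dim1(params[[nm]]), dim1(encoderWeights[[nm]])))
        stop("shape mismatch for pretrained parameter ", nm)
      params[[nm]] <- encoderWeights[[nm]]
      group[[nm]] <- "pretrained"
    }
  }
  new("CacSegModel", config = unclass(cfg), params = params, paramGroup = group)
}

dim1 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

relu <- function(x) { x[x < 0] <- 0; x }

seForward <- function(x, w1, b1, w2, b2) {
  d <- dim(x)
  s <- colMeans(matrix(x, d[1] * d[2], d[3]))
  zr <- relu(as.numeric(w1 %*% s + b1))
  u <- as.numeric(w2 %*% zr + b2)
  g <- 1 / (1 + exp(-u))
  y <- x * rep(g, each = d[1] * d[2])
  list(y = y, s = s, zr = zr, g = g, x = x)
}

seBackward <- function(dy, cache, w1, w2) {
  d <- dim(cache$x)
  hw <- d[1] * d[2]
  dyM <- matrix(dy, hw, d[3]); xM <- matrix(cache$x, hw, d[3])
  dg <- colSums(dyM * xM)
  dx <- dy * rep(cache$g, each = hw)
  du <- dg * cache$g * (1 - cache$g)
  dW2 <- outer(du, cache$zr)
  db2 <- du
  dzr <- as.numeric(t(w2) %*% du)
  dz <- dzr * (cache$zr > 0)
  dW1 <- outer(dz, cache$s)
  db1 <- dz
  ds <- as.numeric(t(w1) %*% dz)
  dx <- dx + array(rep(ds / hw, each = hw), dim = d)
  list(dx = dx, dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2)
}

# conv (or 4x4/stride-2 transposed conv) -> instance norm -> scale/shift -> ReLU
# instance norm: per-channel standardisation over the slice's spatial extent
layerFwd <- function(x, w, g, b, stride, pad, type = c("conv", "tconv")) {
  type <- match.arg(type)
  z <- if (type == "conv") {
    .conv2d_fwd(x, w, numeric(dim(w)[4]), stride, pad)
  } else {
    d <- dim(x)
    .conv2d_bwd_input(x, w, 2L, 1L, 2L * d[1], 2L * d[2])
  }
  d <- dim(z); hw <- d[1] * d[2]
  zm <- matrix(z, hw, d[3])
  mu <- colMeans(zm)
  va <- colMeans(zm * zm) - mu * mu
  invstd <- 1 / sqrt(pmax(va, 0) + 1e-5)
  xhat <- (zm - rep(mu, each = hw)) * rep(invstd, each = hw)
  pre <- xhat * rep(g, each = hw) + rep(b, each = hw)
  y <- array(pmax(pre, 0), d)
  list(y = y, cache = list(x = x, xhat = xhat, invstd = invstd, pre = pre,
                           dims = d, type = type, stride = stride, pad = pad))
}

layerBwd <- function(dy, cache, w, g) {
  d <- cache$dims; hw <- d[1] * d[2]
  dym <- matrix(dy, hw, d[3]) * (cache$pre > 0)
  dg <- colSums(dym * cache$xhat)
  db <- colSums(dym)
  dxhat <- dym * rep(g, each = hw)
  s1 <- colSums(dxhat) / hw
  s2 <- colSums(dxhat * cache$xhat) / hw
  dzm <- rep(cache$invstd, each = hw) *
    (dxhat - rep(s1, each = hw) - cache$xhat * rep(s2, each = hw))
  dz <- array(dzm, d)
  x <- cache$x
  if (cache$type == "conv") {
    dw <- .conv2d_bwd_weights(x, dz, dim(w)[1], dim(w)[2], cache$stride, cache$pad)
    dx <- .conv2d_bwd_input(dz, w, cache$stride, cache$pad, dim(x)[1], dim(x)[2])
  } else {
    dw <- .conv2d_bwd_weights(dz, x, 4L, 4L, 2L, 1L)
    dx <- .conv2d_fwd(dz, w, numeric(dim(x)[3]), 2L, 1L)
  }
  list(dx = dx, dw = dw, dg = dg, db = db)
}

#' Forward pass of the segmentation model on one preprocessed slice
#'
#' @param model a [CacSegModel-class].
#' @param x preprocessed input: matrix inputSize x inputSize (values in
#'   `[-1, 1]`).
#' @param cache keep intermediate activations for backpropagation.
#' @return List with `probs` (H x W x 5: calcium sigmoid + vessel softmax),
#'   `logits`, and (if requested) `cache`.
#' @export
netForward <- function(model, x, cache = FALSE) {
  p <- model@params; cfg <- model@config
  if (!is.matrix(x) || nrow(x) != cfg$inputSize || ncol(x) != cfg$inputSize)
    stop("input must be a ", cfg$inputSize, "x", cfg$inputSize, " matrix")
  a <- array(x, dim = c(dim(x), 1L))
  C <- list(a0 = a)
  lf <- function(nm, x, stride, pad, type = "conv") {
    out <- layerFwd(x, p[[paste0(nm, "_w")]], p[[paste0(nm, "_g")]],
                    p[[paste0(nm, "_b")]], stride, pad, type)
    C[[paste0("L_", nm)]] <<- out$cache
    out$y
  }
  for (k in 1:4) {
    h1 <- lf(sprintf("e%d_c1", k), a, 2L, 1L)
    h2 <- lf(sprintf("e%d_c2", k), h1, 1L, 1L)
    if (cfg$useSE) {
      se <- seForward(h2, p[[sprintf("e%d_se_w1", k)]], p[[sprintf("e%d_se_b1", k)]],
                      p[[sprintf("e%d_se_w2", k)]], p[[sprintf("e%d_se_b2", k)]])
      a <- se$y
      C[[sprintf("se%d", k)]] <- se
    } else a <- h2
    C[[sprintf("a%d", k)]] <- a
  }
  d <- lf("bn", a, 1L, 1L)
  skips <- list(NULL, C$a3, C$a2, C$a1)
  for (k in 1:4) {
    z <- if (is.null(skips[[k]])) d else {
      dz <- dim(d)
      arr <- array(0, dim = c(dz[1], dz[2], dz[3] + dim(skips[[k]])[3]))
      arr[, , seq_len(dz[3])] <- d
      arr[, , dz[3] + seq_len(dim(skips[[k]])[3])] <- skips[[k]]
      arr
    }
    C[[sprintf("z%d", k)]] <- z
    za <- lf(sprintf("d%d_a", k), z, 1L, 1L)
    zt <- lf(sprintf("d%d_t", k), za, 2L, 1L, type = "tconv")
    d <- lf(sprintf("d%d_b", k), zt, 1L, 1L)
    C[[sprintf("d%d", k)]] <- d
  }
  logits <- .conv2d_fwd(d, p$head_w, p$head_b, 1L, 0L)
  probs <- headProbs(logits)
  out <- list(probs = probs, logits = logits)
  if (cache) out$cache <- C
  out
}

# sigmoid calcium head + stable softmax vessel head
headProbs <- function(logits) {
  d <- dim(logits)
  probs <- array(0, dim = d)
  probs[, , 1] <- 1 / (1 + exp(-logits[, , 1]))
  v <- logits[, , 2:5, drop = FALSE]
  mx <- pmax(v[, , 1], v[, , 2], v[, , 3], v[, , 4])
  e <- exp(v - as.numeric(mx))
  tot <- e[, , 1] + e[, , 2] + e[, , 3] + e[, , 4]
  for (ch in 1:4) probs[, , ch + 1] <- e[, , ch] / tot
  probs
}

# backward pass; dlogits has the same shape as logits
netBackward <- function(model, cache, dlogits) {
  p <- model@params; cfg <- model@config
  g <- list()
  csum <- function(a) colSums(matrix(a, dim(a)[1] * dim(a)[2], dim(a)[3]))
  lb <- function(nm, dy) {
    out <- layerBwd(dy, cache[[paste0("L_", nm)]], p[[paste0(nm, "_w")]],
                    p[[paste0(nm, "_g")]])
    g[[paste0(nm, "_w")]] <<- out$dw
    g[[paste0(nm, "_g")]] <<- out$dg
    g[[paste0(nm, "_b")]] <<- out$db
    out$dx
  }
  dd <- .conv2d_bwd_input(dlogits, p$head_w, 1L, 0L,
                          dim(cache$d4)[1], dim(cache$d4)[2])
  g$head_w <- .conv2d_bwd_weights(cache$d4, dlogits, 1L, 1L, 1L, 0L)
  g$head_b <- csum(dlogits)
  daSkip <- list()  # gradient accumulators for encoder skip activations
  for (k in 4:1) {
    dzt <- lb(sprintf("d%d_b", k), dd)
    dza <- lb(sprintf("d%d_t", k), dzt)
    dz <- lb(sprintf("d%d_a", k), dza)
    skipName <- c("", "a3", "a2", "a1")[k]
    if (nzchar(skipName)) {
      mainCh <- dim(dz)[3] - dim(cache[[skipName]])[3]
      dd <- dz[, , seq_len(mainCh), drop = FALSE]
      dsk <- dz[, , mainCh + seq_len(dim(cache[[skipName]])[3]), drop = FALSE]
      daSkip[[skipName]] <- if (is.null(daSkip[[skipName]])) dsk else
        daSkip[[skipName]] + dsk
    } else dd <- dz
  }
  # dd now holds the gradient at the bottleneck output
  da <- lb("bn", dd)
  for (k in 4:1) {
    skipName <- sprintf("a%d", k)
    if (!is.null(daSkip[[skipName]])) da <- da + daSkip[[skipName]]
    if (cfg$useSE) {
      seb <- seBackward(da, cache[[sprintf("se%d", k)]],
                        p[[sprintf("e%d_se_w1", k)]], p[[sprintf("e%d_se_w2", k)]])
      g[[sprintf("e%d_se_w1", k)]] <- seb$dW1
      g[[sprintf("e%d_se_b1", k)]] <- seb$db1
      g[[sprintf("e%d_se_w2", k)]] <- seb$dW2
      g[[sprintf("e%d_se_b2", k)]] <- seb$db2
      da <- seb$dx
    }
    dh1 <- lb(sprintf("e%d_c2", k), da)
    da <- lb(sprintf("e%d_c1", k), dh1)
  }
  g
}

#' Predict a probability volume for a CT exam
#'
#' Slices are preprocessed and processed independently in order (the model
#' holds no inter-slice state); probabilities are resampled back to the
#' original slice resolution when preprocessing resized, with the vessel
#' channels renormalised to sum to 1.
#'
#' @param model a [CacSegModel-class].
#' @param volume a [CTVolume-class].
#' @param ppCfg a [preprocessConfig()]; its `targetSize` must equal the model
#'   input size.
#' @return A [ProbabilityVolume-class] aligned to `volume`.
#' @export
predictVolume <- function(model, volume, ppCfg = NULL) {
  stopifnot(is(model, "CacSegModel"), is(volume, "CTVolume"))
  cfg <- model@config
  if (is.null(ppCfg)) ppCfg <- preprocessConfig(targetSize = cfg$inputSize)
  if (ppCfg$targetSize != cfg$inputSize)
    stop("preprocess targetSize must match the model input size")
  v <- huValues(volume)
  nS <- dim(v)[1]; H <- dim(v)[2]; W <- dim(v)[3]
  probs <- array(0, dim = c(nS, H, W, 5))
  if (nS == 0) return(ProbabilityVolume(probs))
  for (s in seq_len(nS)) {
    pp <- preprocessSlice(matrix(v[s, , ], H, W), ppCfg, pixelSpacing(volume))
    out <- netForward(model, pp$image)
    ps <- out$probs
    if (dim(ps)[1] != H || dim(ps)[2] != W) {
      back <- array(0, dim = c(H, W, 5))
      for (ch in 1:5)
        back[, , ch] <- unclass(EBImage::resize(ps[, , ch], w = H, h = W,
                                                filter = "bilinear"))
      ps <- back
    }
    probs[s, , , ] <- clampProbs(ps)
  }
  ProbabilityVolume(probs)
}

# keep probabilities strictly inside (0,1) and vessel channels summing to 1
clampProbs <- function(ps, eps = 1e-6) {
  ps[, , 1] <- pmin(pmax(ps[, , 1], eps), 1 - eps)
  tot <- ps[, , 2] + ps[, , 3] + ps[, , 4] + ps[, , 5]
  for (ch in 2:5) ps[, , ch] <- (1 - 4 * eps) * ps[, , ch] / tot + eps
  ps
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the full [modelConfig()] so a model can be rebuilt
#' without external information.
#' @param model a [CacSegModel-class].
#' @param path checkpoint file path.
#' @return `saveModel`: invisibly `path`; `loadModel`: a [CacSegModel-class].
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "CacSegModel"))
  saveRDS(list(config = model@config, params = model@params,
               paramGroup = model@paramGroup, format = "cacseg-v1"), path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "cacseg-v1")) stop("unrecognised checkpoint format")
  new("CacSegModel", config = obj$config, params = obj$params,
      paramGroup = obj$paramGroup)
}
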