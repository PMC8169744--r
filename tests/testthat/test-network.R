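test_that("the model maps an input slice to a 5-channel output of the same size", {
  cfg <- modelConfig(inputSize = 512, encoderChannels = c(2, 2, 2, 2),
                     decoderChannels = c(2, 2, 2, 2), useSE = FALSE)
  m <- buildModel(cfg)
  x <- matrix(runif(512 * 512, -1, 1), 512, 512)
  out <- netForward(m, x)
  expect_identical(dim(out$probs), c(512L, 512L, 5L))
  # reduced configuration keeps the same contract
  m2 <- buildModel(reducedModelConfig(inputSize = 32))
  out2 <- netForward(m2, matrix(runif(1024, -1, 1), 32, 32))
  expect_identical(dim(out2$probs), c(32L, 32L, 5L))
})

test_that("output invariants hold for arbitrary (untrained) weights", {
  set.seed(20)
  for (seed in c(1, 99)) {
    m <- buildModel(reducedModelConfig(inputSize = 32, initSeed = seed))
    x <- matrix(runif(1024, -1, 1), 32, 32)
    p <- netForward(m, x)$probs
    expect_true(all(p > 0 & p < 1))
    vs <- p[, , 2] + p[, , 3] + p[, , 4] + p[, , 5]
    expect_lt(max(abs(vs - 1)), 1e-6)
  }
})

test_that("construction rejects invalid configurations and inputs", {
  expect_error(modelConfig(inputSize = 100), "16")
  expect_error(modelConfig(encoderChannels = c(8, 8, 8)), "length")
  m <- buildModel(reducedModelConfig(inputSize = 32))
  expect_error(netForward(m, matrix(0, 16, 16)), "32")
  # pretrained weights must match encoder shapes
  expect_error(buildModel(reducedModelConfig(inputSize = 32),
                          encoderWeights = list(head_w = array(0, c(1, 1, 8, 5)))),
               "non-encoder")
  expect_error(buildModel(reducedModelConfig(inputSize = 32),
                          encoderWeights = list(e1_c1_w = array(0, c(3, 3, 2, 8)))),
               "mismatch")
})

test_that("loading encoder weights marks the pretrained parameter group", {
  donor <- buildModel(reducedModelConfig(inputSize = 32, initSeed = 50))
  enc <- donor@params[grep("^e[1-4]_", names(donor@params))]
  m <- buildModel(reducedModelConfig(inputSize = 32, initSeed = 1),
                  encoderWeights = enc)
  expect_true(all(m@paramGroup[names(enc)] == "pretrained"))
  expect_true(all(m@paramGroup[setdiff(names(m@paramGroup), names(enc))] == "new"))
  expect_identical(m@params[["e2_c2_w"]], donor@params[["e2_c2_w"]])
})

test_that("volume prediction is slice-independent and order-equivariant", {
  m <- buildModel(reducedModelConfig(inputSize = 32, initSeed = 3))
  ph <- tinyPhantom(seed = 8, nSlices = 3, imageSize = 32)
  ppCfg <- preprocessConfig(targetSize = 32)
  pv <- predictVolume(m, ph$volume, ppCfg)
  expect_identical(dim(probValues(pv)), c(3L, 32L, 32L, 5L))
  # per-slice oracle loop equals the whole-volume path
  v <- huValues(ph$volume)
  for (s in 1:3) {
    one <- CTVolume(v[s, , , drop = FALSE], pixelSpacing(ph$volume), 5)
    pvs <- predictVolume(m, one, ppCfg)
    expect_equal(probValues(pvs)[1, , , ], probValues(pv)[s, , , ])
  }
  # permuting slices permutes the output identically
  perm <- c(3, 1, 2)
  pvPerm <- predictVolume(m, CTVolume(v[perm, , ], pixelSpacing(ph$volume), 5),
                          ppCfg)
  expect_equal(probValues(pvPerm), probValues(pv)[perm, , , , drop = FALSE])
})

test_that("an empty volume predicts an empty probability volume", {
  m <- buildModel(reducedModelConfig(inputSize = 32))
  empty <- CTVolume(array(0, c(0, 32, 32)), 0.5, 5)
  pv <- predictVolume(m, empty, preprocessConfig(targetSize = 32))
  expect_equal(nSlices(pv), 0)
})

test_that("prediction on a resized volume returns original-resolution probabilities", {
  m <- buildModel(reducedModelConfig(inputSize = 32, initSeed = 3))
  ph <- tinyPhantom(seed = 8, nSlices = 2, imageSize = 48)
  pv <- predictVolume(m, ph$volume, preprocessConfig(targetSize = 32))
  p <- probValues(pv)
  expect_identical(dim(p), c(2L, 48L, 48L, 5L))
  expect_true(all(p > 0 & p < 1))
  vs <- p[, , , 2] + p[, , , 3] + p[, , , 4] + p[, , , 5]
  expect_lt(max(abs(vs - 1)), 1e-6)
})

test_that("convolution backward primitives satisfy the exact adjoint identities", {
  # the conv operators are linear, so <conv(x), dy> = <x, conv^T(dy)> must
  # hold to machine precision; this pins both backward primitives to the
  # forward implementation without any finite-difference approximation
  set.seed(31)
  cases <- list(list(H = 9, W = 11, Cin = 3, Cout = 2, k = 3, s = 1, p = 1),
                list(H = 12, W = 12, Cin = 2, Cout = 4, k = 3, s = 2, p = 1),
                list(H = 8, W = 8, Cin = 3, Cout = 3, k = 4, s = 2, p = 1),
                list(H = 7, W = 7, Cin = 2, Cout = 5, k = 1, s = 1, p = 0))
  for (cs in cases) {
    x <- array(rnorm(cs$H * cs$W * cs$Cin), c(cs$H, cs$W, cs$Cin))
    w <- array(rnorm(cs$k^2 * cs$Cin * cs$Cout), c(cs$k, cs$k, cs$Cin, cs$Cout))
    y <- cacscore:::.conv2d_fwd(x, w, numeric(cs$Cout), cs$s, cs$p)
    dy <- array(rnorm(length(y)), dim = dim(y))
    dx <- cacscore:::.conv2d_bwd_input(dy, w, cs$s, cs$p, cs$H, cs$W)
    dw <- cacscore:::.conv2d_bwd_weights(x, dy, cs$k, cs$k, cs$s, cs$p)
    expect_equal(sum(y * dy), sum(x * dx), tolerance = 1e-10)
    expect_equal(sum(y * dy), sum(w * dw), tolerance = 1e-10)
  }
})

test_that("backpropagation matches finite-difference gradients through the whole model", {
  cfg <- modelConfig(inputSize = 32, encoderChannels = c(2, 3, 3, 4),
                     decoderChannels = c(3, 3, 2, 2), initSeed = 5)
  m <- buildModel(cfg)
  # jitter every parameter so no ReLU pre-activation sits exactly at its
  # kink (zero biases put entire channels there, which biases the numeric
  # difference quotient); isolated near-kink units can still contribute a
  # small O(h) artifact, hence the median/max two-level criterion
  set.seed(33)
  for (nm in names(m@params))
    m@params[[nm]] <- m@params[[nm]] + rnorm(length(m@params[[nm]]), 0, 0.05)
  set.seed(2)
  x <- matrix(runif(1024, -1, 1), 32, 32)
  calcMask <- matrix(rbinom(1024, 1, 0.2), 32, 32)
  vesselMap <- calcMask * sample(1:4, 1024, TRUE)
  fw <- netForward(m, x, cache = TRUE)
  dlog <- cacscore:::lossGradient(fw$probs, fw$logits, calcMask, vesselMap)
  g <- cacscore:::netBackward(m, fw$cache, dlog)
  expect_setequal(names(g), names(m@params))
  set.seed(9)
  h <- 1e-5
  errs <- c()
  for (nm in sample(names(m@params), 16)) {
    p <- m@params[[nm]]
    i <- sample(length(p), 1)
    lossAt <- function(delta) {
      m2 <- m
      m2@params[[nm]][i] <- p[i] + delta
      o <- netForward(m2, x)
      compositeLoss(o$probs, calcMask, vesselMap)$loss
    }
    num <- (lossAt(h) - lossAt(-h)) / (2 * h)
    ana <- g[[nm]][i]
    errs <- c(errs, abs(num - ana) / max(1e-6, abs(num) + abs(ana)))
  }
  expect_lt(median(errs), 1e-3)
  expect_lt(max(errs), 0.05)
})

test_that("model checkpoints round-trip with embedded configuration", {
  m <- buildModel(reducedModelConfig(inputSize = 32, initSeed = 77))
  path <- file.path(tempdir(), "model.rds")
  saveModel(m, path)
  back <- loadModel(path)
  expect_identical(back@params, m@params)
  expect_identical(back@config, m@config)
  x <- matrix(runif(1024, -1, 1), 32, 32)
  expect_identical(netForward(back, x)$probs, netForward(m, x)$probs)
})
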