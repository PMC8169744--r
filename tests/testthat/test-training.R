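test_that("learning-rate schedule matches its closed form at the landmarks", {
  cfg <- trainingConfig()   # warmup 5k, anneal 300k, delay 10k
  expect_identical(lrSchedule(0, 1e-3, cfg), 0)
  expect_identical(lrSchedule(cfg$warmupIters, 1e-3, cfg), 1e-3)
  expect_lt(abs(lrSchedule(cfg$warmupIters + cfg$annealIters, 1e-3, cfg)), 1e-12)
  expect_identical(lrSchedule(cfg$warmupIters + cfg$annealIters + 1, 1e-3, cfg), 0)
  # halfway through annealing the rate is exactly half the base
  expect_equal(lrSchedule(cfg$warmupIters + cfg$annealIters / 2, 1e-3, cfg),
               5e-4, tolerance = 1e-15)
})

test_that("schedule is continuous at the warmup end and monotone on each side", {
  cfg <- trainingConfig(warmupIters = 100, annealIters = 1000)
  eps <- lrSchedule(99, 1, cfg) - lrSchedule(100, 1, cfg)
  expect_lt(abs(eps + 0.01), 1e-12)       # linear ramp slope 1/100
  ramp <- lrSchedule(0:100, 1, cfg)
  expect_true(all(diff(ramp) > 0))
  decay <- lrSchedule(100:1100, 1, cfg)
  expect_true(all(diff(decay) < 0))
})

test_that("pretrained group schedule is an exact time shift", {
  cfg <- trainingConfig(warmupIters = 50, annealIters = 500,
                        pretrainedDelayIters = 100)
  its <- seq(0, 800, by = 7)
  shifted <- lrSchedule(pmax(0, its - 100), 1e-4, cfg)
  expect_identical(lrSchedule(its, 1e-4, cfg, pretrained = TRUE), shifted)
  expect_identical(lrSchedule(c(0, 50, 100), 1e-4, cfg, pretrained = TRUE),
                   c(0, 0, 0))
  # scaling shrinks all counts together
  cfgS <- trainingConfig(scaleFactor = 1 / 1000)
  expect_equal(cfgS$warmupIters, 5)
  expect_equal(cfgS$annealIters, 300)
  expect_equal(cfgS$pretrainedDelayIters, 10)
})

test_that("the sampler emits only lesion-bearing slices before any expansion", {
  ph <- tinyPhantom(seed = 14, nSlices = 8, imageSize = 32,
                    nLesions = c(LCA = 2, LAD = 2, LCX = 0, RCA = 0))
  ds <- makeTrainingSlices(list(ph), preprocessConfig(targetSize = 32))
  hasCalc <- vapply(ds$samples, function(s) any(s$calcMask > 0), logical(1))
  expect_true(any(!hasCalc))  # the phantom has some calcium-free slices
  st <- newSamplerPool(ds, seed = 5)
  expect_identical(st$pool, which(hasCalc))
  cfg <- trainingConfig(batchSize = 3, seed = 5)
  seen <- integer(0)
  for (i in 1:100) {
    mb <- sampleMinibatch(ds, cfg, st)
    st <- mb$state
    seen <- union(seen, mb$indices)
    expect_true(all(mb$indices %in% which(hasCalc)))
  }
  expect_setequal(seen, which(hasCalc))
})

test_that("an epoch over a pool of exactly batch-size slices is a permutation", {
  ph <- tinyPhantom(seed = 15, nSlices = 6, imageSize = 32,
                    nLesions = c(LCA = 3, LAD = 3, LCX = 3, RCA = 3))
  ds <- makeTrainingSlices(list(ph), preprocessConfig(targetSize = 32))
  st <- newSamplerPool(ds, seed = 1)
  cfg <- trainingConfig(batchSize = length(st$pool), seed = 1)
  mb <- sampleMinibatch(ds, cfg, st)
  expect_setequal(mb$indices, st$pool)
  # fixed seed reproduces the identical batch sequence
  st2 <- newSamplerPool(ds, seed = 1)
  mb2 <- sampleMinibatch(ds, cfg, st2)
  expect_identical(mb2$indices, mb$indices)
})

test_that("composite loss matches hand-computed Dice and cross-entropy", {
  # 3-pixel toy mask, hand arithmetic with smoothing constant 1
  probs <- array(0.001, dim = c(4, 4, 5))
  probs[, , 2:5] <- 0.25
  mask <- matrix(0, 4, 4); vmap <- matrix(0L, 4, 4)
  mask[1, 1] <- mask[2, 2] <- mask[3, 3] <- 1
  vmap[1, 1] <- 1L; vmap[2, 2] <- 2L; vmap[3, 3] <- 2L
  probs[1, 1, 1] <- 0.9; probs[2, 2, 1] <- 0.8; probs[3, 3, 1] <- 0.7
  pSum <- 0.9 + 0.8 + 0.7 + 13 * 0.001
  diceHand <- 1 - (2 * (0.9 + 0.8 + 0.7) + 1) / (pSum + 3 + 1)
  ceHand <- -mean(log(c(0.25, 0.25, 0.25)))
  L <- compositeLoss(probs, mask, vmap, smooth = 1)
  expect_equal(L$dice, diceHand, tolerance = 1e-9)
  expect_equal(L$ce, ceHand, tolerance = 1e-9)
  expect_equal(L$loss, diceHand + ceHand, tolerance = 1e-9)
  # perfect binary prediction: Dice loss within smoothing-induced epsilon
  probsP <- probs
  probsP[, , 1] <- mask * 0.999999 + (1 - mask) * 1e-9
  LP <- compositeLoss(probsP, mask, vmap, smooth = 1)
  expect_lt(LP$dice, 1e-6)
  # all-background slice: finite loss through smoothing
  L0 <- compositeLoss(probs, matrix(0, 4, 4), matrix(0L, 4, 4), smooth = 1)
  expect_true(is.finite(L0$loss))
  expect_equal(L0$ce, 0)
})

test_that("hard-negative expansion equals a brute-force re-scan and is idempotent", {
  ph <- tinyPhantom(seed = 16, nSlices = 8, imageSize = 32,
                    nLesions = c(LCA = 1, LAD = 1, LCX = 0, RCA = 0))
  ds <- makeTrainingSlices(list(ph), preprocessConfig(targetSize = 32))
  st <- newSamplerPool(ds, seed = 1)
  poolBefore <- st$pool
  # an untrained model with this seed fires on some calcium-free slices
  m <- buildModel(reducedModelConfig(inputSize = 32, initSeed = 23))
  st2 <- expandHardNegatives(m, ds, st)
  expect_true(all(poolBefore %in% st2$pool))    # monotone growth
  # brute-force recomputation of the misclassified negative set
  negatives <- setdiff(seq_along(ds$samples), poolBefore)
  fired <- integer(0)
  for (i in negatives) {
    smp <- ds$samples[[i]]
    if (any(smp$calcMask > 0)) next
    pr <- netForward(m, smp$x)$probs
    mask <- pr[, , 1] > 0.5
    if (any(mask)) {
      # any predicted component counts as a predicted lesion
      fired <- c(fired, i)
    }
  }
  expect_identical(st2$pool, sort(union(poolBefore, fired)))
  # idempotent: a second expansion with the same model adds nothing new
  st3 <- expandHardNegatives(m, ds, st2)
  expect_identical(st3$pool, st2$pool)
  # a model predicting nothing leaves the pool unchanged
  mQuiet <- m
  mQuiet@params$head_b[1] <- -50
  st4 <- expandHardNegatives(mQuiet, ds, st)
  expect_identical(st4$pool, st$pool)
})

test_that("zero training iterations return the model unchanged; traces have one row per iteration", {
  ph <- tinyPhantom(seed = 18, nSlices = 2, imageSize = 32)
  ds <- makeTrainingSlices(list(ph), preprocessConfig(targetSize = 32))
  m <- buildModel(reducedModelConfig(inputSize = 32, initSeed = 2))
  r0 <- trainModel(m, ds, trainingConfig(batchSize = 2, seed = 1), nIters = 0)
  expect_identical(r0$model@params, m@params)
  r3 <- trainModel(m, ds, trainingConfig(batchSize = 2, scaleFactor = 1e-4,
                                         seed = 1),
                   nIters = 3, hardNegatives = FALSE)
  expect_equal(nrow(r3$trace), 3)
  expect_true(all(is.finite(r3$trace$loss)))
  expect_false(identical(r3$model@params, m@params))
  # deterministic for a fixed seed
  r3b <- trainModel(m, ds, trainingConfig(batchSize = 2, scaleFactor = 1e-4,
                                          seed = 1),
                    nIters = 3, hardNegatives = FALSE)
  expect_identical(r3b$model@params, r3$model@params)
  expect_identical(r3b$trace, r3$trace)
})
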