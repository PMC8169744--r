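# Independent brute-force oracles used to validate the scoring pipeline.
# Deliberately written without reference to the package internals: pure-R
# flood fill, table-lookup weights, single-pass per-pixel accumulation.

# pure-R 8-connected labeling by breadth-first flood fill
floodLabel8 <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nxt <- 0L
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(i, j)); lab[i, j] <- nxt
    while (length(queue)) {
      q <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        ni <- q[1] + di; nj <- q[2] + dj
        if (ni < 1 || ni > H || nj < 1 || nj > W) next
        if (mask[ni, nj] && lab[ni, nj] == 0L) {
          lab[ni, nj] <- nxt
          queue[[length(queue) + 1]] <- c(ni, nj)
        }
      }
    }
  }
  lab
}

oracleWeight <- function(hu) {
  if (hu < 200) 1 else if (hu < 300) 2 else if (hu < 400) 3 else 4
}

# naive single-pass re-implementation of the whole second stage; also keeps
# the individual lesion scores so equivalence can be asserted bit-exactly
# per lesion (vessel totals can differ in the last ulp by summation order)
naiveScoreOracle <- function(probs, hu, pixelSpacing) {
  vessels <- c("LCA", "LAD", "LCX", "RCA")
  out <- setNames(numeric(4), vessels)
  lesionScores <- numeric(0)
  pxArea <- prod(rep(pixelSpacing, length.out = 2))
  for (s in seq_len(dim(probs)[1])) {
    mask <- matrix(probs[s, , , 1] > 0.5, dim(probs)[2], dim(probs)[3])
    if (!any(mask)) next
    lab <- floodLabel8(mask)
    huS <- matrix(hu[s, , ], dim(hu)[2], dim(hu)[3])
    for (k in seq_len(max(lab))) {
      px <- which(lab == k, arr.ind = TRUE)
      vals <- huS[px]
      area <- sum(vals > 130) * pxArea
      if (area == 0) next
      mx <- max(vals)
      votes <- integer(4); mass <- numeric(4)
      for (r in seq_len(nrow(px))) {
        pv <- sapply(1:4, function(ch) probs[s, px[r, 1], px[r, 2], ch + 1])
        votes[which.max(pv)] <- votes[which.max(pv)] + 1L
        mass <- mass + pv
      }
      top <- which(votes == max(votes))
      if (length(top) > 1) top <- top[which.max(mass[top])]
      v <- vessels[min(top)]
      sc <- area * oracleWeight(mx)
      out[v] <- out[v] + sc
      lesionScores <- c(lesionScores, sc)
    }
  }
  attr(out, "lesionScores") <- sort(lesionScores)
  out
}

# random but contract-valid probability volume with attached HU volume
randomScoredVolume <- function(ns = 2, sz = 24, pCalcFrac = 0.15,
                               pixelSpacing = 0.5) {
  p <- array(0, dim = c(ns, sz, sz, 5))
  p[, , , 1] <- ifelse(runif(ns * sz * sz) < pCalcFrac,
                       runif(ns * sz * sz, 0.6, 0.99),
                       runif(ns * sz * sz, 0.01, 0.45))
  raw <- array(runif(ns * sz * sz * 4, 0.05, 1), dim = c(ns, sz, sz, 4))
  tot <- raw[, , , 1] + raw[, , , 2] + raw[, , , 3] + raw[, , , 4]
  for (ch in 1:4) p[, , , ch + 1] <- raw[, , , ch] / tot * (1 - 4e-6) + 1e-6
  hu <- array(runif(ns * sz * sz, -100, 600), dim = c(ns, sz, sz))
  list(probs = ProbabilityVolume(p),
       volume = CTVolume(hu, pixelSpacing, 5),
       rawProbs = p, rawHu = hu)
}

# asymptotic two-sample Kolmogorov p, independent closed form
kolmogorovP <- function(D, n, m) {
  lambda <- sqrt(n * m / (n + m)) * D
  k <- 1:100
  min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))))
}

# a small phantom shared across tests
tinyPhantom <- function(seed = 3, nSlices = 4, imageSize = 64,
                        nLesions = c(LCA = 1, LAD = 1, LCX = 1, RCA = 1), ...) {
  generatePhantom(phantomSpec(nSlices = nSlices, imageSize = imageSize,
                              nLesionsPerVessel = nLesions, seed = seed, ...))
}
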