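#' Bland-Altman agreement analysis
#'
#' Bias is the mean difference (predicted minus reference); the 95% limits of
#' agreement are bias +/- 1.96 SD of the differences, with a normal 95% CI on
#' the bias itself.
#'
#' @param reference,predicted paired score vectors (equal length, >= 2 pairs).
#' @return List: `bias`, `loa` (lower, upper), `biasCI`, `differences`,
#'   `means`.
#' @examples
#' blandAltman(c(0, 10, 20), c(2, 10, 24))$bias
#' @export
blandAltman <- function(reference, predicted) {
  stopifnot(length(reference) == length(predicted), length(reference) >= 2)
  d <- predicted - reference
  bias <- mean(d)
  s <- sd(d)
  half <- 1.96 * s
  list(bias = bias,
       loa = c(lower = bias - half, upper = bias + half),
       biasCI = c(lower = bias - 1.96 * s / sqrt(length(d)),
                  upper = bias + 1.96 * s / sqrt(length(d))),
       differences = d, means = (predicted + reference) / 2)
}

#' Cohen's kappa for bucketed score agreement
#'
#' Unweighted kappa over the categories present in either vector, with the
#' conventional interpretation bands: < 0 poor, 0-0.20 slight, 0.21-0.40
#' fair, 0.41-0.60 moderate, 0.61-0.80 substantial, 0.81-1.00 almost perfect.
#'
#' @param reference,predicted paired category vectors (factors or character).
#' @return List: `kappa`, `band`, `po` (observed agreement), `pe` (chance
#'   agreement), `table` (confusion counts, reference in rows).
#' @export
cohenKappa <- function(reference, predicted) {
  stopifnot(length(reference) == length(predicted), length(reference) >= 1)
  lev <- union(levels(factor(reference)), levels(factor(predicted)))
  r <- factor(as.character(reference), levels = lev)
  p <- factor(as.character(predicted), levels = lev)
  tab <- table(r, p)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  kappa <- if (pe == 1) 1 else (po - pe) / (1 - pe)
  list(kappa = kappa, band = kappaBand(kappa), po = po, pe = pe, table = tab)
}

#' Interpretation band of a kappa coefficient
#' @param kappa kappa value(s).
#' @return Character band label(s).
#' @examples
#' kappaBand(0.89)
#' @export
kappaBand <- function(kappa) {
  vapply(kappa, function(k) {
    if (k < 0) "poor"
    else if (k <= 0.20) "slight"
    else if (k <= 0.40) "fair"
    else if (k <= 0.60) "moderate"
    else if (k <= 0.80) "substantial"
    else "almost perfect"
  }, character(1))
}

#' Two-sample Kolmogorov-Smirnov test on score distributions
#'
#' @param scoresA,scoresB nonempty score samples.
#' @return List: `D` statistic and asymptotic `p` value.
#' @export
ksTestScores <- function(scoresA, scoresB) {
  stopifnot(length(scoresA) >= 1, length(scoresB) >= 1)
  kt <- suppressWarnings(ks.test(scoresA, scoresB, exact = FALSE))
  list(D = unname(kt$statistic), p = unname(kt$p.value))
}

#' Diagnostic performance at a CAC cutoff
#'
#' Positivity is score >= cutoff on both sides (pass buckets through
#' [bucketAtCutoff()] first for classifiers that emit buckets). Sensitivity,
#' specificity, PPV and NPV are reported in percent with 95% CIs clipped to
#' `[0, 100]`; F1 is the harmonic mean of sensitivity and PPV (as a
#' proportion). Metrics with empty denominators are flagged undefined (NA).
#'
#' @param reference,predicted paired total scores, or paired logical
#'   positivity calls (in which case `cutoff` is only descriptive).
#' @param cutoff one of 1, 10, 100, 400.
#' @param ciMethod "wald" (normal approximation, clipped) or "wilson".
#' @return One-row data.frame: cutoff, confusion counts, metrics (%) with CI
#'   bounds, and F1.
#' @export
diagnosticMetrics <- function(reference, predicted, cutoff,
                              ciMethod = c("wald", "wilson")) {
  ciMethod <- match.arg(ciMethod)
  stopifnot(length(reference) == length(predicted))
  refPos <- if (is.logical(reference)) reference else binaryAtCutoff(reference, cutoff)
  prdPos <- if (is.logical(predicted)) predicted else binaryAtCutoff(predicted, cutoff)
  tp <- sum(refPos & prdPos); fn <- sum(refPos & !prdPos)
  fp <- sum(!refPos & prdPos); tn <- sum(!refPos & !prdPos)
  prop <- function(num, den) if (den == 0) NA_real_ else num / den
  ci <- function(p, n) {
    if (is.na(p) || n == 0) return(c(NA_real_, NA_real_))
    if (ciMethod == "wald") {
      half <- 1.96 * sqrt(p * (1 - p) / n)
      c(max(0, p - half), min(1, p + half)) * 100
    } else {
      z <- 1.96; z2 <- z^2
      ctr <- (p + z2 / (2 * n)) / (1 + z2 / n)
      half <- z * sqrt(p * (1 - p) / n + z2 / (4 * n^2)) / (1 + z2 / n)
      c(ctr - half, ctr + half) * 100
    }
  }
  sens <- prop(tp, tp + fn); spec <- prop(tn, tn + fp)
  ppv <- prop(tp, tp + fp); npv <- prop(tn, tn + fn)
  f1 <- if (is.na(sens) || is.na(ppv) || sens + ppv == 0) NA_real_ else
    2 * sens * ppv / (sens + ppv)
  sensCI <- ci(sens, tp + fn); specCI <- ci(spec, tn + fp)
  ppvCI <- ci(ppv, tp + fp); npvCI <- ci(npv, tn + fn)
  data.frame(cutoff = cutoff, tp = tp, fp = fp, fn = fn, tn = tn,
             sensitivity = sens * 100, sens_lo = sensCI[1], sens_hi = sensCI[2],
             specificity = spec * 100, spec_lo = specCI[1], spec_hi = specCI[2],
             ppv = ppv * 100, ppv_lo = ppvCI[1], ppv_hi = ppvCI[2],
             npv = npv * 100, npv_lo = npvCI[1], npv_hi = npvCI[2],
             f1 = f1)
}

#' Diagnostic performance table over the standard cutoffs
#'
#' @param reference,predicted paired total scores.
#' @param cutoffs CAC cutoffs (default 1, 10, 100, 400).
#' @param ciMethod see [diagnosticMetrics()].
#' @return data.frame, one row per cutoff.
#' @export
diagnosticTable <- function(reference, predicted,
                            cutoffs = c(1, 10, 100, 400),
                            ciMethod = c("wald", "wilson")) {
  ciMethod <- match.arg(ciMethod)
  do.call(rbind, lapply(cutoffs, function(co)
    diagnosticMetrics(reference, predicted, co, ciMethod)))
}

#' 5x5 bucket confusion matrix
#'
#' Rows are the reference (ground truth) buckets, columns the predictions;
#' counts sum to the number of pairs.
#'
#' @param reference,predicted paired bucket vectors (I-V).
#' @return 5x5 integer table.
#' @export
confusionMatrixBuckets <- function(reference, predicted) {
  r <- factor(as.character(reference), levels = BUCKETS)
  p <- factor(as.character(predicted), levels = BUCKETS)
  if (anyNA(r) || anyNA(p)) stop("buckets must be I..V")
  table(reference = r, predicted = p)
}

#' Write an evaluation report (JSON and/or CSV, Table-style layout)
#'
#' @param reference,predicted paired total scores.
#' @param jsonPath,csvPath optional output paths.
#' @param cutoffs CAC cutoffs.
#' @return Invisibly, the report list.
#' @export
writeEvaluationReport <- function(reference, predicted, jsonPath = NULL,
                                  csvPath = NULL, cutoffs = c(1, 10, 100, 400)) {
  ba <- blandAltman(reference, predicted)
  kp <- cohenKappa(cacBucket(reference), cacBucket(predicted))
  tab <- diagnosticTable(reference, predicted, cutoffs)
  rep <- list(bias = ba$bias, loa = as.list(ba$loa),
              kappa = kp$kappa, kappaBand = kp$band,
              ks = ksTestScores(reference, predicted),
              metrics = tab)
  if (!is.null(jsonPath))
    jsonlite::write_json(rep, jsonPath, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  if (!is.null(csvPath)) utils::write.csv(tab, csvPath, row.names = FALSE)
  invisible(rep)
}

#' Bland-Altman plot
#'
#' @param ba a [blandAltman()] result.
#' @param ... passed to [plot()].
#' @return Invisibly NULL.
#' @export
plotBlandAltman <- function(ba, ...) {
  plot(ba$means, ba$differences, xlab = "Mean of methods",
       ylab = "Difference (predicted - reference)", pch = 19, ...)
  graphics::abline(h = ba$bias, lty = 1)
  graphics::abline(h = ba$loa, lty = 2)
  invisible(NULL)
}

#' Confusion-matrix heatmap for bucket agreement
#'
#' @param tab a 5x5 table from [confusionMatrixBuckets()].
#' @return Invisibly NULL.
#' @export
plotConfusionMatrix <- function(tab) {
  m <- t(apply(unclass(tab), 2, rev))
  graphics::image(seq_len(5), seq_len(5), m, axes = FALSE,
                  xlab = "Predicted", ylab = "Reference",
                  col = grDevices::hcl.colors(25, "Blues 3", rev = TRUE))
  graphics::axis(1, at = 1:5, labels = colnames(tab))
  graphics::axis(2, at = 1:5, labels = rev(rownames(tab)))
  for (i in 1:5) for (j in 1:5)
    graphics::text(j, 6 - i, unclass(tab)[i, j])
  invisible(NULL)
}
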