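# cacscore

Automated, vessel-specific coronary artery calcium (CAC) scoring for gated
coronary CT and routine non-gated chest CT, in R.

CAC burden, expressed as the Agatston score, is one of the strongest
non-invasive predictors of coronary events, and a total score ≥ 100 is the
contemporary threshold for initiating statin therapy. Dedicated gated CAC
exams are scored manually in 3D labs, while the millions of routine chest
CTs that visibly show coronary calcification usually go unquantified. This
package is for imaging scientists and methodologists who want a complete,
testable implementation of an end-to-end automated scoring pipeline:

1. **Segmentation** — a slice-wise encoder–decoder network emits, per pixel,
   a calcium probability and a vessel probability vector
   (p_calc, p_LCA, p_LAD, p_LCX, p_RCA) with p_LCA + p_LAD + p_LCX + p_RCA = 1.
   The two heads share one trunk and split at the final 1×1 projection.
2. **Scoring** — pixels with p_calc > 0.5 are merged into 8-connected
   in-slice lesions; each lesion is attributed to the artery winning the
   per-pixel argmax plurality vote; its Agatston contribution is
   area(mm², pixels > 130 HU) × weight(peak HU), with the standard density
   weights 1–4 for peaks in 130–200, 200–300, 300–400 and ≥ 400 HU.
   Slice-wise scores sum to per-vessel scores (LCA/LM, LAD, LCX, RCA), the
   exam total, and risk bucket I–V (0, 1–10, 11–100, 101–400, > 400).
3. **Non-gated post-processing** — per-slice 4-component lesion summaries,
   concatenated over the 5 highest-area slices into a 20-component feature
   vector, classified into buckets I–V by gradient-boosted trees trained
   against paired gated reference scores.
4. **Evaluation** — Bland–Altman bias and limits of agreement, unweighted
   Cohen's kappa with interpretation bands, two-sample Kolmogorov–Smirnov,
   and sensitivity/specificity/PPV/NPV/F1 at the clinical cutoffs
   1, 10, 100 and 400.

A synthetic CT phantom generator with *analytically known* per-vessel scores
(disjoint quadrant vessel territories, disc lesions, aortic-ring and valve
distractors, a gated→non-gated degradation model) makes every stage testable
without any clinical data: scoring the clean ground-truth masks must
reproduce the generator's analytic scores exactly.

## A worked example

```r
library(cacscore)

ph <- generatePhantom(phantomSpec(nSlices = 6, imageSize = 96, seed = 7,
  nLesionsPerVessel = c(LCA = 1, LAD = 2, LCX = 1, RCA = 2)))
ph$groundTruth
#> PhantomGroundTruth
#>   6 lesions, analytic total 50.00 (bucket III)

sc <- scoreVolume(probabilityFromLabels(ph$groundTruth),
                  cleanVolume(ph$groundTruth))
sc
#> CacScores (Agatston)
#>   LCA     21.00
#>   LAD      8.75
#>   LCX      9.00
#>   RCA     11.25
#>   total   50.00  bucket III  (6 lesions)

identical(vesselScores(sc), vesselScores(ph$groundTruth))
#> [1] TRUE

head(lesionTable(sc)[, c("slice", "vessel", "areaMm2", "maxHu", "weight", "agatston")])
#>   slice vessel areaMm2    maxHu weight agatston
#> 1     2    LCX    2.25 782.1200      4     9.00
#> 2     3    RCA    2.25 308.1453      3     6.75
#> 3     3    LAD    1.25 315.9996      3     3.75
#> 4     3    LAD    1.25 666.8867      4     5.00
#> 5     6    LCA    5.25 414.5571      4    21.00
#> 6     6    RCA    2.25 269.9188      2     4.50
```

The six inserted lesions are recovered with their exact areas, density
weights and per-vessel sums; the total of 50.0 falls in risk bucket III
(11–100). The same `scoreVolume()` call accepts the probability output of a
trained segmentation model (`predictVolume()`) in place of the ground-truth
masks.

Training at desk scale (a reduced model overfitting a handful of phantom
slices) and the non-gated bucket classifier are demonstrated in the methods
vignette (`vignettes/cac-scoring-methods.Rmd`), which also documents every
numerical convention — strict thresholds, tie-breaks, padding rules — and
the design decisions behind the reduced network.

## Scope

The package ships no trained clinical weights and makes no clinical
performance claims; phantom experiments validate the arithmetic, the
training mechanism and the pipeline wiring. Volumes are read and written as
NIfTI (+ JSON spacing sidecar); DICOM series must be converted upstream.
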