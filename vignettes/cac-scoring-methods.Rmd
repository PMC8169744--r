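---
title: "Automated coronary calcium scoring: models, scoring rules and synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated coronary calcium scoring: models, scoring rules and synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cacscore)
```

## The problem

Coronary artery calcium (CAC) is quantified on CT with the Agatston score:
every in-slice calcified lesion contributes its area (mm^2 of pixels above
130 HU) multiplied by a density weight derived from the lesion's peak
attenuation (130--200 HU &rarr; 1, 200--300 &rarr; 2, 300--400 &rarr; 3,
&ge; 400 &rarr; 4), summed over slices. Clinical reporting uses both the
per-artery scores (LCA/left main, LAD, LCX, RCA) and risk buckets I--V for
totals of 0, 1--10, 11--100, 101--400 and > 400; a total &ge; 100 is the
contemporary statin-initiation threshold.

`cacscore` implements a fully automatic two-stage pipeline:

1. a slice-wise convolutional segmentation model emits, for every pixel, a
   calcium probability `p_calc` and a four-way vessel probability vector
   that sums to one;
2. a deterministic scoring stage thresholds `p_calc > 0.5`, merges calcium
   pixels into 8-connected in-slice lesions, attributes each lesion to the
   artery winning the per-pixel argmax plurality vote, and accumulates
   vessel-specific Agatston scores, the exam total and its bucket.

For non-gated chest CT (no ECG synchronisation; motion, thicker effective
slices, more noise) a third stage summarises each slice's predicted lesions
into a 4-vector (predicted area, peak HU in the predicted region, area
weighted by per-lesion peak HU, lesion count), concatenates the summaries of
the 5 slices with the highest predicted area (zero-padded, descending-area
order) and classifies the resulting 20-component vector into buckets I--V
with gradient-boosted trees, trained against buckets from paired gated
exams — gated scores remain the reference standard throughout.

## Scoring-stage conventions

All thresholds are strict as stated: `p_calc > 0.5` and attenuation
`> 130` HU. Connected components are strictly two-dimensional per slice with
8-connectivity; identical masks on adjacent slices are two lesions, never
one. A lesion's area counts only its pixels above 130 HU while its peak HU
is taken over all component pixels; a component with no pixel above 130 HU
scores exactly zero. Areas are real-valued (pixel area in mm^2 times count),
so fractional scores are representable. Vessel-vote ties are broken first by
the larger summed probability mass over the lesion, then by the fixed order
LCA < LAD < LCX < RCA — deterministic by construction.

Two conventions are configurable because the field's literature leaves them
open. The density weight defaults to the standard 4-bin mapping; a literal
`area x peak HU` variant is available (`scoringConfig(weightMode =
"literal")`) but produces values orders of magnitude above the clinical
0--400 scale that the buckets assume. No minimum lesion area is applied by
default; the conventional &ge; 1 mm^2 filter is available via
`minLesionAreaMm2`.

Scoring always runs on the original-resolution HU volume, never on the
preprocessed model input: preprocessing clips at 1200 HU, which would
corrupt weight assignment for dense lesions.

The cutoff/bucket correspondence used for classifiers whose output is a
bucket is: cutoff 1 &harr; bucket &ge; II, 10 &harr; &ge; III, 100 &harr;
&ge; IV, 400 &harr; V. The conventions disagree only at the exact boundary
scores (a score of exactly 10, 100 or 400 is positive at its cutoff but
sits at the top of the lower bucket, and fractional scores below 1 occupy
bucket II while being negative at cutoff 1); both calls are exposed
(`binaryAtCutoff()`, `bucketAtCutoff()`) and the equivalence away from the
boundaries is tested.

## Preprocessing

Model input slices are clipped to [-800, 1200] HU and mapped affinely to
[-1, 1] by subtracting 200 (the clip midpoint) and dividing by 1000. The
zero-centering constant is a package decision: a fixed, image-independent
affine map keeps preprocessing deterministic and monotone, where a per-image
mean subtraction would couple the model input to slice content. Resampling
to the model input size uses bilinear interpolation for HU images and
nearest-neighbour for label volumes (labels must stay categorical), with
pixel spacing rescaled by the same factor so physical areas are preserved.

I/O is NIfTI (via RNifti) with a JSON spacing sidecar; no R DICOM reader is
available to this package, so DICOM series must be converted upstream and
`readCTVolume()` says so explicitly.

## The segmentation model

The full-scale architecture this package emulates is a 50-layer
squeeze-excitation encoder with a 4-block decoder. What `cacscore` builds is
a configurable reduced form that preserves the published output contract
exactly — one preprocessed slice in, a 5-channel per-pixel field out, the
calcium channel through a logistic function and the four vessel channels
through a per-pixel softmax, so the vessel probabilities sum to one for any
weights:

* encoder: four downsampling stages (3x3 stride-2 convolution, 3x3
  convolution, optional squeeze-excitation channel gating with reduction
  ratio 4), reaching 1/16 resolution; grouped-convolution cardinality is not
  implemented at desk scale;
* decoder: four blocks, each a 3x3 convolution, a 4x4 stride-2 transposed
  convolution and another 3x3 convolution (2x upsampling per block);
* skip connections at three levels. The encoder stages that feed them are
  not dictated by the architecture's description, and the choice matters:
  with the three skips at 1/4, 1/8 and 1/16 the two full-resolution decoder
  blocks receive no fine-grained features and small (2--4 px) lesions
  could not be localised in desk-scale experiments. The package therefore
  takes the skips from the 1/2, 1/4 and 1/8 encoder maps, leaving the
  deepest decoder block as the single unskipped one;
* both heads share the entire trunk and split only at the final 1x1
  projection, reflecting the shared-anatomy motivation (the same features
  that find calcium must recognise the aorta and valves to suppress them);
* every trunk convolution is followed by instance normalisation (per-slice,
  per-channel standardisation with learnable scale and shift) and ReLU.
  The full-scale encoder is batch-normalised throughout; without any
  normalisation the desk-scale network exhibited multi-hundred-iteration
  loss plateaus and saturation traps. Instance normalisation is the
  batch-size-independent analogue appropriate for slice-wise training.

There is no explicit background/non-coronary class: pixels the model should
ignore are represented only through low `p_calc`, keeping the output vector
at exactly five components.

The forward and backward passes are implemented in the package (R with
C++ convolution primitives); the backward pass is verified in the test
suite both by exact adjoint identities on the linear convolution operators
and by finite-difference checks through the whole model.

## Training procedure

Training follows the published recipe at configurable scale: Adam
(β₁ = 0.9, β₂ = 0.999), learning rate 1e-3 for randomly initialised and
1e-4 for pretrained parameters, linear warmup over 5k iterations followed by
cosine annealing over 300k, the pretrained group's schedule delayed by 10k
iterations (an exact time shift, clamped at zero), L2 regularisation 1e-4 on
all parameters, and mini-batches of 64 slices containing calcified lesions.
`scaleFactor` multiplies all three iteration counts for desk-scale runs.

The loss is Dice (with an additive smoothing constant of 1, so
all-background slices remain finite) on the calcium head plus cross-entropy
on the vessel head. The vessel term is evaluated only on ground-truth
calcium pixels: vessel identity is undefined elsewhere, and the softmax
output constraint would otherwise force a meaningless label on every
background pixel.

Hard-negative mining follows the published schedule: training starts from
lesion-bearing slices only, and after every epoch calcium-free slices on
which the model predicts at least one lesion — "predicts" meaning the full
second-stage thresholding, the quantity that actually corrupts a score —
are added to the eligible pool. The pool grows monotonically and additions
are idempotent.

### Desk-scale problem sizes

The test suite trains a reduced model (channels 8/16/24/32, 32x32 input) on
five distractor-free phantom slices for 1500 iterations with the schedule
scaled by 1/100, reaching a training Dice above 0.9 in a few minutes on one
CPU. Those slices deliberately exclude the aortic-ring and valve
distractors: the smoke test certifies the optimisation mechanism (loss,
gradients, schedule, sampler), whereas learning to *suppress* non-coronary
calcium is a representation task that a five-slice overfit cannot and
should not certify. Evaluation cohorts are 60 phantoms of 96x96 x 5--6
slices, stratified over buckets I--V.

## The phantom generator

Every stage is testable without clinical data through a synthetic CT
phantom with analytically known ground truth. Geometry: square axial slices
(default 512x512 at 0.5 mm/pixel, 5 mm slice spacing — the routine axial
reconstruction; tests use smaller images), soft-tissue background at 40 HU.
The four coronary territories are fixed quadrant-offset tubes through the
stack (radius imageSize/8) — deliberately not anatomically realistic, so
ground truth is unambiguous and placement verifiable; lesions are filled
discs placed entirely inside one territory, never straddling two, each
carrying a single clean attenuation drawn from (130, 4000]. Non-coronary
distractors — an aortic-wall ring and cusp/annulus discs near the image
centre, geometrically disjoint from all territories — are labeled as a
separate class and must contribute zero to every vessel score.

The generator computes each lesion's Agatston contribution analytically
from the clean pixels with its own independently written weight code, so
scoring the clean ground-truth masks must reproduce the analytic scores
*exactly* — the package's strongest oracle, exercised over 200 random
volumes against a naive per-pixel re-implementation and over stratified
50-phantom cohorts. Gaussian HU noise (default SD 12, a typical soft-kernel
reconstruction noise level) is added only to the emitted volume; the
reference standard stays noise-free.

Bucket-stratified cohorts are built by adding lesions one at a time until
the running analytic total passes a target drawn safely inside the bucket;
the maximal single-lesion overshoot keeps the total inside the bucket's
upper bound, so membership is guaranteed, not retried.

The non-gated degradation applies in-plane Gaussian motion blur along one
axis, partial mixing of adjacent slices (thicker effective collimation) and
extra noise. Blur with a non-negative normalised kernel cannot raise a
lesion's regional maximum, which the tests exploit. The paired gated ground
truth is left untouched, mirroring the use of gated scores as the non-gated
reference standard.

What the phantom does *not* emulate: real anatomy and vessel curvature,
contrast enhancement, beam hardening and scanner-specific physics, and
lesions with internal density gradients (each phantom lesion is a constant-
HU disc). Passing phantom tests therefore demonstrates the correctness of
the scoring arithmetic, the training mechanism and the pipeline wiring —
not clinical segmentation performance.

## Risk-bucket classification for non-gated exams

The gradient-boosted classifier uses 200 trees of depth 3 with learning
rate 0.1 (unspecified in the source method; config-exposed), single-threaded
for determinism. Exams with fewer than five lesion-bearing slices are
zero-padded; the peak intensity of an empty predicted region is defined as
0, and peak intensities are floored at 0 so summary components stay
non-negative.

One calibration of expectations: the 20 summary components do not encode
the bin-exact Agatston arithmetic (they carry raw peak HU, not the binned
weight, and only the top five slices). An exam generated essentially on a
bucket boundary is therefore not perfectly decodable by a classifier
trained on *other* exams; cross-validated recovery on clean-mask features
reaches a kappa of about 0.96 with the residual errors confined to
boundary exams, and exact recovery holds for the classifier evaluated on
the noise-free features it was fitted to.

## Agreement statistics

Bland-Altman bias is the mean difference (predicted minus reference) with
1.96 SD limits of agreement; Cohen's kappa is unweighted over buckets with
the conventional interpretation bands (0.81--1.00 "almost perfect", etc.);
the two-sample Kolmogorov-Smirnov test reports the asymptotic p-value.
Confidence intervals for the diagnostic metrics default to the Wald normal
approximation clipped to [0, 100] — matching the symmetric, clipped
intervals conventional in this literature — with Wilson intervals available
by flag. Empty-denominator metrics (e.g. specificity with no negatives) are
reported as NA rather than an arbitrary 100%.

## A worked example

```{r example}
ph <- generatePhantom(phantomSpec(nSlices = 6, imageSize = 96, seed = 7,
  nLesionsPerVessel = c(LCA = 1, LAD = 2, LCX = 1, RCA = 2)))
ph$groundTruth

sc <- scoreVolume(probabilityFromLabels(ph$groundTruth),
                  cleanVolume(ph$groundTruth))
sc
identical(vesselScores(sc), vesselScores(ph$groundTruth))
```

## Known limitations

* The network is a reduced, CPU-trainable form; no pretrained clinical
  weights are distributed, and ImageNet pretraining is out of scope
  (externally supplied encoder weights can be loaded and are assigned the
  delayed, lower learning-rate group).
* DICOM input is not supported in-process; convert to NIfTI first.
* Phantom realism is deliberately limited (see above); clinical validation
  claims cannot be derived from this package's tests.
* Single-device training only; no mixed precision or data parallelism.
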