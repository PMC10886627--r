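---
title: "Tissue classification on stimulated Raman images: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tissue classification on stimulated Raman images: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ramanhisto)
```

## The problem

Stimulated Raman scattering (SRS) microscopy images fresh tissue without
staining by measuring vibrational energy shifts at two wavenumbers:
2845 cm^-1^, where photons scatter mainly at CH~2~ bonds abundant in
lipids (the "CH2" channel), and 2930 cm^-1^, where they scatter at CH~3~
bonds of proteins and DNA (the "CH3" channel).  A virtual-H&E rendering
of the two channels — stimulated Raman histology (SRH) — lets
pathologists read the images like conventional frozen sections.  For
intraoperative margin assessment in oral squamous cell carcinoma
surgery, an automated classifier that labels image patches as tumor or
one of five non-malignant tissue types (stroma, adipose, muscle,
squamous epithelium, glandular tissue) can shorten the feedback loop.

`ramanhisto` implements that workflow end to end: annotated two-channel
specimen images are converted to three-channel tensors, cut into
fixed-size labeled tiles under a strict coverage rule, partitioned at
the image level by an iterative Jensen–Shannon-distance procedure,
classified by a class-weighted convolutional network, and scored with a
per-class metric suite.  Because the clinical imaging data this design
derives from are not public, the package ships a synthetic specimen
generator that emulates the cohort's statistical structure, so every
stage is exercised and tested without any download.

## Image model and the three-channel tensor

An `srs_image` holds two aligned nonnegative intensity grids plus
acquisition metadata (pixel size 467 nm, scan depth 10 µm — metadata
only; no optics are modeled).  Intensities are standardized to the
`[0, 1]` scale and quantized to a 1/65535 grid, so the 16-bit TIFF
round trip is bit-exact.  The learning input adds a third plane, the
per-pixel spectral difference CH3 − CH2, which is kept *signed*:
lipid-rich adipose tissue has CH2 > CH3, and clipping at zero would
erase exactly that contrast.

Model input scaling offers three strategies.  Per-channel min–max (each
plane stretched by its own extrema) removes acquisition gain but makes
the mapping depend on what happens to be in the image — a nearly
single-class image is stretched to full range regardless of class, which
destroys the absolute-intensity signal.  A global fixed range preserves
absolute contrast but passes per-acquisition offsets through to the
classifier.  The pipeline default, `min_subtract_fixed_range`, is the
flat-fielding compromise: subtract each plane's minimum (dark-level /
offset correction, anchored in practice by unannotated background
pixels) and divide by a fixed range width.  On synthetic cohorts with
per-image intensity offsets this is the only one of the three that lets
rare classes generalize across images, which is why it is the default;
the other two remain available.

## Virtual H&E rendering

The clinical instrument's look-up table is proprietary; the package uses
a documented stand-in: Beer–Lambert two-dye mixing in optical-density
space, `rgb = exp(−(g_h · CH3 · OD_h + g_e · CH2 · OD_e))`, with the
standard hematoxylin and eosin OD triples used in stain deconvolution.
Zero signal leaves white background; CH3 (nuclei) pulls toward
hematoxylin purple monotonically; CH2 (cytoplasm, lipid) toward eosin
pink.  The mapping is deterministic and reproduces the qualitative H&E
appearance, not the vendor's exact colors.

## Annotations and tiling

Annotations are closed polygons (outer ring plus optional holes) in
0-based pixel coordinates, y down, carrying one of the six classes; they
read and write the QuPath GeoJSON dialect
(`properties.classification.name`, with `properties.name` accepted).
Because SRH renders are generated pixel-for-pixel from their SRS source,
annotation transfer between modalities is an identity on coordinates.

Tiling is a non-overlapping grid (stride = tile size, anchored at the
origin, incomplete edge tiles dropped; 250 px at full scale, 64 px in
the desk profile).  A tile is labeled with class *c* iff at least 99% of
its pixels are covered by class-*c* annotations; a tile that reaches the
threshold for two overlapping classes would carry contradictory label
information and is excluded, as is everything below threshold.

Coverage semantics are *pixel-center-in-polygon-union*: the fraction of
the tile's pixel centers inside the union of the class's polygons,
computed exactly by scanline even-odd rasterization.  An alternative —
clipping polygons against the tile rectangle and dividing areas — gives
almost but not exactly the same number, and near a 0.99 threshold
"almost" is not good enough: the two rules can disagree on whether a
tile is retained.  The package therefore uses the pixel-center rule
throughout, and the test suite checks it cell-for-cell against an
independent per-pixel point-in-polygon brute force, including identical
retained-tile sets on dozens of random specimens.

## Jensen–Shannon stratified splitting

Images (not tiles) are assigned to train/validation/test so no specimen
leaks across subsets: 80% of images form the training pool, 20% the
test set, and 10% of the pool (rounded to whole images, 6 of 64 at
cohort scale) becomes validation.  Subsets are filled one at a time
(test, validation, then training receives the remainder): draw a random
unassigned image, keep it iff the subset's Jensen–Shannon distance
(square root of the base-2 Jensen–Shannon divergence, a `[0, 1]` metric)
to the full-dataset tile distribution *strictly* decreases; the first
image of a subset is always kept, and ties reject.  The raw loop can
stall when no remaining image decreases the distance, so after 200
consecutive rejections the candidate minimizing the post-addition
distance is force-accepted, which guarantees termination while
preserving the procedure's intent; forced acceptances are flagged in the
recorded trace.  The boundary condition — every class present in every
subset — is verified at the end; on failure the procedure restarts from
a derived seed (25 restarts by default) and reports infeasibility
beyond that.  Whether the subset distributions are tile-level or
pixel-level is an open choice; tile counts are the unit of learning, so
tile-level is used.

## Classifier

The full-size profile is a VGG19-style backbone (sixteen 3×3
convolution layers in widths 64–512 with five max-pool stages) on
250×250×3 tiles; the head is two fully connected layers of 1000 and 100
neurons with dropout 0.5 between them and a 6-way softmax, trained for
100 epochs at batch size 100 with learning rate 10^-4^.  Weights are
randomly initialized (He-normal); no pretraining.  The optimizer is
unspecified in that design, so the package defaults to Adam with cosine
decay to 10% of the initial rate — the loss of a thin network otherwise
oscillates on a plateau.  Inputs are centered (x − 0.5) inside the
model for first-layer conditioning.  Class imbalance is handled by
weighting the cross-entropy with `w_c = 1/(K p_c)`, normalized so the
expected weight under the training distribution is 1 and weighted and
unweighted losses are comparable in magnitude.  Each tile is
independently flipped horizontally and/or vertically with probability
0.5 per axis each epoch.  Checkpoint selection is final-epoch weights;
validation metrics are logged for audit only.  Inference is
deterministic (dropout off), with argmax ties broken toward the lowest
class index.

The **desk profile** used by the package's own experiments replaces the
backbone with a four-block conv/pool stack (widths 8–32) on 64×64 tiles
and trains 20 epochs at learning rate 10^-3^ with batch size 16 — a few
hundred training tiles need a smaller batch to give the optimizer a
useful number of steps.  The conv engine itself (im2col convolution,
max-pooling, dense layers, dropout, Adam, the weighted loss and the flip
augmentation) is implemented in the package's C++ code; all randomness
flows from one integer seed, so runs are reproducible within a software
environment (bit-exactness across BLAS builds is not promised).

## Synthetic cohort generator

The generator emulates the *statistical shape* of the clinical cohort,
not its appearance: 80 specimen images (tagged with 8 synthetic patient
ids), each partitioned into 1–6 perturbed Voronoi regions; each region
gets a tissue class, and the target tile mixture is 0.23 tumor, 0.23
stroma, 0.07 adipose, 0.03 muscle, 0.39 squamous epithelium, 0.05
glandular.  Regions are polygons rather than pixel masks so the tiling
module's polygon-coverage path is genuinely exercised, including
partial-coverage exclusions along the thin unannotated seams left by
region shrinking and vertex jitter.

Class signatures encode the biochemistry qualitatively on the `[0, 1]`
scale: adipose is CH2-dominant (0.90, 0.25), tumor (0.20, 0.90),
squamous epithelium (0.30, 0.60) and glandular tissue (0.80, 0.85) are
CH3-dominant, stroma (0.50, 0.50) and muscle (0.60, 0.70) intermediate,
each with a distinct texture family (nuclear dots, fibrous and layered
sinusoids, striations, vacuoles, glandular rings), Gaussian speckle
(sd 0.06), and a per-image intensity offset (sd 0.04) as a crude
inter-patient gain effect.  A `separation` parameter scales all
signatures about their centroid; a linear probe's accuracy rises
monotonically with it (tested), which is the control knob the
property-based suites rely on.  `hard_mode` moves squamous epithelium
next to tumor in both intensity and texture, reproducing qualitatively
the dominant tumor-vs-epithelium confusion seen in real tissue.

Two allocation details matter for small cohorts.  Region classes follow
a golden-ratio low-discrepancy sequence over the cohort's global region
stream (inverted through the mixture CDF) rather than iid draws, so the
realized mixture tracks the target closely — with iid draws an 80-image
cohort misses the 3% muscle share too often.  And regions of rare
classes (target below 0.08) are re-laid-out until they contain at least
two full tiles, so rare classes survive tiling in enough images for the
three-subset boundary condition to be satisfiable.  Both mechanisms are
deterministic given the cohort seed and the image index.

### What the generator does not emulate

No instrument noise model, no line-scan stitching artifacts, no
photorealistic histology, no within-region morphological gradients, and
inter-patient variance beyond the scalar intensity offset.  Passing
tests on this data shows the pipeline's mechanics are correct and that
the classifier can recover well-separated classes under the study's
imbalance and split procedure; it does not certify performance on real
SRS images.

## Problem sizes and numerical choices

The desk profile uses 384 px images (a 6×6 complete-tile grid at 64 px,
comparable to the 4×4 grid of 1000 px images at 250 px), giving roughly
a thousand labeled tiles per 80-image cohort — large enough that the 3%
muscle class lands ~20–60 tiles spread over several images, small
enough that a full generate→train→evaluate run takes about a minute on
one CPU.  The full-size VGG19 profile is available but compute-heavy;
tests instantiate it and check its output contract without training it.
Distribution sums are validated to 10^-9^; `0·log 0` terms in the
divergence are 0; zero-denominator precision/recall is reported as 0
with a warning rather than NaN; metric tables round to two decimals
(rates to whole percents) in rendered reports while full precision is
kept in the JSON alongside.

One reporting caveat inherited from the reference metric table shipped
in `inst/extdata/`: a few printed F1 cells (e.g. stroma) are not the
two-decimal rounding of the harmonic mean of their *printed, rounded*
precision/recall — a pre-rounding artifact.  The recomputation in
`recompute_reference_summary()` flags such cells instead of forcing
them.

## Known limitations

The CNN engine is single-threaded and CPU-oriented; at the full 250-px
VGG19 scale it is far slower than a GPU framework and is not intended
for real training runs.  The splitting procedure is greedy and
randomized, not an optimal partitioner, matching its specification.
GeoJSON support covers Polygon/MultiPolygon FeatureCollections, not
whole-slide pyramids or annotation editing.
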