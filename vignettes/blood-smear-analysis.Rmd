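---
title: "Classifying red blood cell morphology from stained smear images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying red blood cell morphology from stained smear images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemosmear)
```

## The problem

Anemia subtyping starts from two per-cell judgements on a peripheral blood
smear: the *size* of each red blood cell (RBC) — microcytic below the normal
6.2–8.2 µm diameter band, normocytic within it, macrocytic above it — and its
*chromicity*, the hemoglobin content read from the stain density and from the
central pallor, the lighter disk at the cell centre where the biconcave cell
is thinnest. Hypochromic cells are pale with an enlarged pallor; hyperchromic
cells are densely stained with essentially none. Manual scoring of these
classes is slow and error-prone; `hemosmear` automates it as a pipeline of
classical image analysis and machine learning:

1. **Preprocess**: green channel → balance contrast enhancement (BCET) →
   median smoothing → mean-step intensity quantization.
2. **Segment**: two-step binarization; the all-cells mask comes from the
   original (smoothed) channel, a WBC-only mask from the quantized image, and
   an XOR-style removal subtracts the white cells. Connected components become
   per-cell regions with filled masks and pallor holes.
3. **Describe**: a 52-dimensional feature vector per cell — 5 shape
   descriptors, 6 RGB statistics, 6 angle-averaged gray-level co-occurrence
   (GLCM) features, 11 angle-averaged run-length (GLRLM) features, and 24
   Gabor-bank responses.
4. **Learn**: ADASYN balances the class counts, locality sensitive
   discriminant analysis (LSDA) reduces the 52 features to a small
   discriminative subspace, and a random forest + multilayer perceptron
   soft-voting ensemble classifies each cell, evaluated by stratified
   cross-validation.

No public dataset with per-cell ground truth exists for this task, so the
package ships a synthetic smear generator with pixel-exact ground truth;
every stage above is tested against it.

## The synthetic generator, and what it does (not) capture

`simulate_smear()` renders anti-aliased stained disks on a pale background:
RBCs as salmon-red disks with an optional concentric lighter pallor disk,
WBCs as large dark-purple disks, platelets as small violet specks. Class
geometry is anchored in micrometres and converted at a configurable pixel
pitch (default 0.2 µm/px):

| class | diameter (µm) | pallor/radius ratio |
|---|---|---|
| microcytic | 4.2–5.8 | by chromicity |
| normocytic | 6.2–8.2 | by chromicity |
| macrocytic | 8.6–10.6 | by chromicity |
| hypochromic | — | 0.55–0.70 |
| normochromic | — | 0.30–0.45 |
| hyperchromic | — | 0 |
| WBC | 12–16 | 0 |
| platelet | 2–3 | 0 |

The pallor ranges are simulator assumptions: no quantitative pallor-to-cell
ratio per chromicity class is available in the clinical literature we model,
so we fixed plausible, non-overlapping ranges once and documented them here.
Stain colours form a ladder in the green channel (background ≈ 228,
hypochromic 150, normochromic 140, hyperchromic 130, WBC 35): hemoglobin and
Romanowsky stains absorb green most strongly, deeper staining means lower
green, and WBC nuclei are far darker than any RBC. The two margins that the
segmentation method structurally requires — RBC bodies clearly separated from
the pallor/background cluster, and WBC nuclei clearly below half the mean
image intensity — are properties of real stained smears too; fields where
they fail (over-stained, grossly under-exposed) defeat a single global
threshold no matter the implementation.

Illumination is a multiplicative linear gradient with random direction
(default ±4% peak), noise is additive Gaussian (default SD 3 gray levels).
Cells are placed by rejection sampling, largest classes first; with
`overlap_fraction = 0` an extra 4 px gap keeps tangent cells from fusing
into one component after thresholding. What the generator does *not*
emulate: real stain texture inside cells, rouleaux and heavy clumping,
out-of-focus blur, camera noise correlations, and poikilocytosis (shape
abnormalities — every simulated cell is round). Passing tests on this
material therefore demonstrate the pipeline's internal correctness and its
behaviour under the stated imaging conditions, not clinical performance.

## Preprocessing choices

BCET maps intensities through the parabola `y = a(x−b)² + c` solved in closed
form so that the output minimum, maximum and mean hit their targets exactly.
The classical target mean of 128 is kept as the default of the standalone
`bcet_enhance()`. The *pipeline*, however, uses a monotone target
(`out_mean = NULL`): on smear fields the histogram is dominated by bright
background, the input mean sits far above mid-range, and forcing the output
mean to 128 places the parabola's vertex inside the input range — the mapping
folds, everything below the background collapses to 0, and the quantized
image can no longer isolate the WBCs. With the monotone target the mean is
placed where a linear stretch would put it, the vertex stays outside the
input range, and ordering of intensities is preserved (a property the test
suite asserts on a background-heavy histogram).

Quantization snaps every pixel to the nearest multiple of the image mean
`Fg` (ties round half away from zero — the definition leaves the tie rule
open, so we fixed and tested one). Background and RBCs land on the same
level; only WBC nuclei fall to level 0, which is what the WBC mask
thresholds. Median smoothing defaults to the smallest standard window, 3×3,
with replicate padding.

## Segmentation

The all-cells mask is the Otsu threshold of the *original* (smoothed,
un-enhanced) green channel, foreground = darker class; the WBC mask is the
Otsu threshold of the quantized enhanced image. The low-level
`remove_wbc_xor()` defaults to the plain pixelwise XOR of the two masks. The
pipeline default dilates the WBC mask by 2 px and removes it with AND-NOT
instead: the two binarizations cut the anti-aliased WBC rim at different
intensities, so plain XOR necessarily leaves a ring one to two pixels wide
(2–5% of the WBC's pixels) around every removed cell; the dilated AND-NOT
mode — exposed precisely for this — eliminates it. Both modes are available
and tested.

Components are labelled 8-connected (4-connected labelling with a
diagonal-merge pass), holes are closed 4-connectedly, components smaller
than the area of a disk of half the smallest microcyte radius are dropped
(this is the implicit platelet filter), frame-touching components are
dropped by default, and components larger than 1.8× the median area are
flagged `clump = TRUE` but never split — concavity and texture features are
the mitigation for clumps, not watershed surgery.

## Feature semantics and numerical choices

*Geometry.* Area and all outline measures use the hole-filled mask so the
pallor cannot corrupt them. The perimeter estimator traces the crack
boundary (the polygon of pixel edges around the component, crossing diagonal
pinches so one loop covers an 8-connected component) and Gaussian-smooths it
(σ = 1.25 px) before measuring: raw crack length overestimates smooth
outlines by up to 27%, raw pixel-centre chain length by ~5%, while the
smoothed crack polygon is within ~1–2% for both digital disks and digital
rectangles — verified against closed forms (disk circularity ≈ 1, square
circularity = π/4). Rectangularity uses the rotating-calipers minimum-area
rectangle over the boundary-pixel corners, so it is orientation-free.
Concavity is the pallor reading: hole area over filled area (a convex-hull
denominator is selectable, since the defining symbol admits both readings;
the two differ by <3% on round cells). Convexity is hull perimeter over cell
perimeter. Single-pixel regions are returned as `degenerate` and excluded
from training.

*Colour.* Population (divide-by-N) means and variances per channel over mask
pixels.

*GLCM/GLRLM.* Intensities are min–max binned into 8 levels over the cell
mask (half-open bins, closed top bin, edge values to the lower bin — each
rule fixed and tested). GLCMs use unit-distance offsets at 0°, 45°, 90°,
135°, symmetrized, normalized; features are max probability, correlation
(reported 0 and flagged when a marginal SD vanishes), contrast, energy,
homogeneity, entropy (base 2, `0·log 0 := 0`). GLRLMs count maximal
equal-level runs along the same four directions — 45°-family directions are
the only diagonal lattice directions at unit distance, so a stray mention of
30°/60° scanning elsewhere in the method's lineage is not implementable and
the 0/45/90/135 set is used throughout — truncated at the mask boundary;
the eleven run statistics index gray levels from 1 so low-gray emphases are
defined at the darkest level. `RP` is defined as total runs over masked
pixels. Both builders are verified against brute-force pair/run enumerators
on hundreds of random masked images.

*Gabor.* Twelve complex kernels (wavelengths 3, 6, 9, 12 px/cycle ×
orientations 30°, 60°, 90°), each a complex exponential under an isotropic
Gaussian envelope with σ = 0.56 × wavelength (one-octave bandwidth; the
bandwidth parameters have no published values, so the standard convention is
fixed here), truncated at 3σ, envelope-weighted-DC-subtracted so constant
regions respond with exactly zero. The explicitly listed wavelengths
supersede the geometric frequency ladder, which remains available as an
alternative bank mode (`fmax`, `k`, `M`). Crops are reflect-padded,
convolution is FFT-based with kernel-FFT caching, and statistics are
restricted to mask pixels: mean squared energy `mean(|r|²)` then mean
amplitude `mean(|r|)`, wavelength-major order, 24 values. Responses are
complex magnitudes, so "amplitude" is well defined and θ and θ+180° are
indistinguishable, as expected.

The feature vector is the frozen concatenation (5 + 6 + 6 + 11 + 24 = 52)
whose column names `feature_names()` returns; the CSV header is the format
contract.

## Resampling and reduction

ADASYN balances every minority class up to the majority count. Generation
budgets per minority point are proportional to the fraction of foreign
points among its k = 5 nearest neighbours, so synthesis concentrates near
class boundaries; rows are convex interpolations toward same-class
neighbours. Two deliberate choices: budgets are apportioned exactly (floor +
largest remainder), so balance is exact rather than approximate; and when a
minority class is so separated that every boundary weight is zero, the
budget falls back to uniform — otherwise the method would refuse to balance
precisely the easiest data. Originals are never modified, synthetic rows are
flagged, and the whole step is deterministic under its seed.

LSDA builds a k-nearest-neighbour graph, splits the edges by label agreement
into within-class and between-class sets, and solves the generalized
eigenproblem that maximizes local between-class separation (between-graph
Laplacian, weight α = 0.5) plus within-class affinity against the
within-class degree constraint, ridge-regularized (1e-3 relative). The
default output dimension is C−1 for C classes. Eigenvector signs are fixed
(largest-magnitude component positive) for reproducibility. Feature columns
are standardized (fit on training data only) before both ADASYN and LSDA:
areas in the thousands and probabilities in [0,1] share a distance metric
only after scaling.

A caveat worth stating: when classes are widely separated *and* the training
set is small (a few dozen rows per class), the between-class edge set is
nearly empty and the LSDA criterion degenerates towards an unsupervised
locality projection; at the package's default experiment scale (hundreds of
cells) this does not occur, but users reducing with LSDA on very small
tables should inspect `lsda_fit()$eigenvalues`.

## Classifier and evaluation

The ensemble averages the class-probability vectors of a 200-tree random
forest and a single-hidden-layer (64 unit) softmax perceptron with weight
decay 1e-3 (the perceptron here has no validation-based early stopping;
decay plus the iteration cap plays that role) — equal-weight soft voting,
with hard voting available. Evaluation is stratified k-fold (default 5)
cross-validation in which standardization, ADASYN and LSDA are fit inside
each training fold only; the report asserts that every test row is an
original (never synthetic) cell. Metrics are one-vs-rest per class:
precision TP/(TP+FP), recall TP/(TP+FN), F1, accuracy, macro-averaged over
classes (classes with undefined metrics are excluded from the macro mean and
listed). Note the precision definition: the false-discovery-rate form that
sometimes appears in print is a typo — TP/(TP+FP) is the quantity consistent
with high reported precision values, and is what this package computes.

## Default experiment scale

The package's reference experiment — what `run_pipeline()` does with
defaults and what `scripts/acceptance.R` re-runs — simulates 60 fields of
256×256 px, each with 2 cells of each of five classes (microcytic
hypochromic, normocytic hypochromic, macrocytic hypochromic, microcytic
hyperchromic, normocytic normochromic) plus one WBC (the removal stage needs
WBCs present), segments ~600 cells, and cross-validates with 5 folds. These
sizes were chosen as the smallest at which the fold-level training sets
(~480 cells) are comfortably larger than the regime where graph-based LSDA
degenerates, while a full run stays in the minutes range on one CPU.

## Known limitations

* Overlapping-cell splitting is out of scope by design; clumps are flagged,
  not divided.
* The XOR removal assumes WBC nuclei are the darkest structures and that at
  most a modest fraction of the field is WBC; fields with no dark nuclei at
  all make the quantized mask threshold arbitrary (the pipeline guards the
  degenerate all-equal case but not adversarial intermediate ones).
* Feature values on real smears will differ systematically from synthetic
  ones (stain texture, focus); a model trained on simulated cells should not
  be applied to clinical images without retraining.
* BCET with a fixed mid-gray target mean is unreliable on background-heavy
  fields (see above); the monotone target is the supported pipeline setting.
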