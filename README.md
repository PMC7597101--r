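# hemosmear

Automated red-blood-cell (RBC) morphology typing from stained blood-smear
images, for people building hematology image-analysis pipelines: given a
light-microscopy field, the package segments the red cells, measures each
one, and classifies it by **size** (microcytic / normocytic / macrocytic,
relative to the normal 6.2–8.2 µm diameter band) and **chromicity**
(hypochromic / normochromic / hyperchromic, read from stain density and the
central pallor). These are the judgements behind anemia subtyping — e.g.
microcytic hypochromic cells are the signature of iron deficiency and
thalassemia.

## Method

The pipeline is classical image analysis plus shallow machine learning:

1. **Preprocessing** — green channel of the RGB field; balance contrast
   enhancement (BCET), the parabolic mapping `y = a(x−b)² + c` fixing output
   min/max/mean in closed form; 3×3 median smoothing; quantization with the
   mean intensity as step, `Q(x,y) = Fg · round(g(x,y)/Fg)`,
   `Fg = mean(g)`.
2. **Segmentation** — two-step binarization: Otsu on the original channel
   (all cells) and Otsu on the quantized image (only the much darker WBC
   nuclei survive at level 0), then XOR-style removal of the WBC mask;
   8-connected components, hole filling, area filtering.
3. **Features** — 52 per cell:
   area, circularity `4πA/P²`, rectangularity `A/A_rect`,
   concavity `A_hole/A_cell` (the central-pallor fraction), convexity
   `P_hull/P_cell`; RGB means and variances; six co-occurrence (GLCM)
   features and eleven run-length (GLRLM) features, each averaged over the
   0°/45°/90°/135° scan directions at 8 gray levels; and a 12-filter Gabor
   bank (wavelengths 3, 6, 9, 12 px × orientations 30°, 60°, 90°) summarized
   by mean squared energy and mean amplitude.
4. **Learning** — ADASYN oversampling to balance classes, locality sensitive
   discriminant analysis (LSDA) down to C−1 dimensions, and an equal-weight
   soft-voting ensemble of a 200-tree random forest and a 64-unit
   perceptron, evaluated by stratified 5-fold cross-validation (per-class
   one-vs-rest precision/recall/F1/accuracy, macro-averaged).

Because no public per-cell-annotated dataset exists, the package includes a
synthetic smear generator (`simulate_smear()`) with pixel-exact ground
truth: class-dependent cell diameters anchored in micrometres, pallor size
encoding chromicity, darker-stained WBCs, platelets, illumination gradient
and pixel noise. All tests and the reference experiment run on it. See the
vignette (`vignettes/blood-smear-analysis.Rmd`) for every modelling choice.

## Worked example

```r
library(hemosmear)

cfg <- pipeline_config(n_images = 60, seed = 42)
report <- run_pipeline(cfg)
print(report)
```

Output from this run:

```
Blood-smear pipeline report: 60 images, 600 cells used / 600 segmented
timings: features 88.5s, cross-validation 3.7s
Classification report (600 cells)
                        precision recall    f1 support
macrocytic_hypochromic      0.992  0.983 0.987     120
microcytic_hyperchromic     1.000  1.000 1.000     120
microcytic_hypochromic      0.992  0.983 0.987     120
normocytic_hypochromic      0.967  0.983 0.975     120
normocytic_normochromic     1.000  1.000 1.000     120
macro: precision 0.990 | recall 0.990 | F1 0.990
overall accuracy 0.990
```

Reading this: 60 simulated fields produced 600 segmented red cells, every
one matched to its ground-truth class; under 5-fold cross-validation (with
ADASYN and LSDA fit inside each training fold) the ensemble recovers the
five morphology classes with ~99% macro precision/recall, the residual
confusions lying between adjacent size classes of the same chromicity.

Single stages are equally usable on their own:

```r
sim <- simulate_smear(smear_config(counts_per_class = c(normocytic_normochromic = 5, wbc = 1), seed = 7))
seg <- segment_smear(sim$image)
length(seg$regions)          # 5 — the WBC was removed, platelet-free field
compute_geometry(seg$regions[[1]])
```

A thin CLI over the same functions lives at `inst/cli/hemosmear.R`
(`simulate`, `preprocess`, `segment`, `pipeline` subcommands).

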