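# bsiquant

Automated quantification of metastatic tumour burden on whole-body planar
bone scintigrams, for researchers who need an end-to-end, fully reproducible
reference implementation of the bone scan index (BSI) pipeline and of the
statistics used to compare scoring systems.

A ⁹⁹ᵐTc-MDP bone scan is read here in four stages:

1. **Atlas segmentation** — a sex-specific skeletal atlas is fitted to the
   anterior/posterior image pair by multi-scale non-rigid registration
   (global affine by normalized cross-correlation, then demons-style
   refinement), labelling every skeletal pixel with its anatomical region.
2. **Hot-spot detection** — pixels exceeding `k ×` a robust local background
   (median of same-region skeletal pixels in a 40 px disc; default
   `k = 1.5`) form 8-connected candidate lesions, equally detectable in
   faint ribs and bright lumbar spine.
3. **Classification** — per-region, sex-specific neural networks (single
   hidden layer, logistic output) score each hot spot's metastasis
   probability from size, shape, intensity and localization features. The
   patient-level **ANN value** is the maximum probability.
4. **BSI** — every hot spot with probability ≥ 0.5 contributes its region
   area fraction weighted by the region's skeletal mass fraction:

   BSI = Σ (hot-spot area / region area) × mass fraction(region) × 100 [%].

Since clinical images cannot be distributed, the package includes a seeded
synthetic phantom generator (procedural 2D skeleton, benign degenerative vs
metastatic lesions with view-dependent contrast, physiological kidney/bladder
activity, system-resolution blur, Poisson counting noise) with per-lesion
ground truth, and the whole pipeline is validated against it.

The statistics module reproduces the analyses used to compare software
generations: empirical ROC with the optimal cutoff maximizing
sensitivity − (1 − specificity), paired AUC comparison (DeLong), proportion
tests, and net reclassification improvement (NRI) over the standard ANN
(0.25/0.50/0.75) and BSI (0.1/1/5) risk bins, with

net gain = (moved up − moved down) / stratum size,
total NRI = net gain(events) − net gain(non-events).

## Worked example

```r
library(bsiquant)

# train hot-spot classifiers on 60 seeded phantoms
training <- build_training_set(n_phantoms = 60, seed = 7)
registry <- train_classifiers(training, seed = 7)

# analyse a new phantom end to end (registration -> detection -> BSI)
ph  <- generate_phantom(phantom_config(sex = "male", n_metastases = 3,
                                       n_benign = 2, seed = 123))
res <- run_pipeline(ph$pair, registry)
res
#> patient_result: ANN value 1, BSI 0.66% (4 of 5 hot spots metastatic)
glance(res)
#> # A tibble: 1 x 5
#>   ann_value   bsi n_hotspots n_metastatic flags
#>       <dbl> <dbl>      <int>        <int> <chr>
#> 1     1.000 0.657          5            4 ""
sum(ph$truth$involvement_pct[ph$truth$class == "metastatic"])  # ground truth
#> [1] 0.623954
```

The ANN value 1.0 says some hot spot is confidently metastatic; the BSI says
the metastatic hot spots cover ~0.66% of skeletal mass, close to the
phantom's true 0.62%. The benign joint lesions were detected but classified
non-metastatic, so they do not enter the BSI.

NRI from published 4×4 reclassification counts (bundled example tables):

```r
tabs <- read_reclassification_table(
  system.file("extdata", "reclass_ann_example.csv", package = "bsiquant"),
  scheme = "ANN")
total_nri(tabs$event, tabs$nonevent)
#> NRI (ANN): net gain events +3.6% (p = 0.38), non-events -26.0% (p = 1.8e-09)
#> total NRI 29.6% (p = 5.3e-07)
```

A command-line interface wraps the same functions
(`bsiquant phantom|segment|detect|train|score|bsi|stats|pipeline`); see
`exec/bsiquant`.

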