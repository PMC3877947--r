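---
title: "Automated bone scan index quantification: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated bone scan index quantification: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsiquant)
```

## The problem

Whole-body planar bone scintigraphy with ⁹⁹ᵐTc-MDP is the workhorse survey
for skeletal metastases in prostate, breast and other cancers. Visual reading
is reader-dependent, so automated pipelines quantify the scan instead: fit a
skeletal atlas to the patient's anterior and posterior images, detect focal
uptake ("hot spots") with a locally adaptive threshold, classify each hot
spot as metastatic or benign with per-region neural networks, and summarize
the patient with two numbers — the **ANN value** (probability of abnormality,
in \[0, 1\]) and the **bone scan index** (BSI), the percentage of total
skeletal mass involved by lesions classified as metastatic:

$$\mathrm{BSI} = \sum_{h \,:\, p_h \ge \tau} \frac{a_h}{A_{r(h)}}\; w_{r(h)} \times 100,$$

where $a_h$ is the hot spot's pixel area, $A_{r(h)}$ the pixel area of its
anatomical region in the quantified view, $w_r$ the region's skeletal mass
fraction ($\sum_r w_r = 1$), $p_h$ the classifier's metastasis probability
and $\tau$ the decision cutoff (default 0.5).

`bsiquant` implements this pipeline end to end, together with the statistics
used to compare scoring systems across software generations: empirical ROC
with a Youden-style optimal cutoff, paired AUC comparison (DeLong), and net
reclassification improvement (NRI) over ordered risk categories. Because no
patient images can ship with the package, a seeded synthetic phantom
generator stands in for acquisitions, with per-lesion ground truth.

## The phantom generator

The generator draws a procedural 2D skeleton (ellipses and capsules for
skull, cervical/thoracic/lumbar spine, sternum, clavicles, scapulae, ribs,
humeri, pelvis, femora — 16 regions) on the fixed 256 × 1024 acquisition
matrix, one intensity and one label map per view. Per-region uptake factors
and anterior/posterior view emphases live in a packaged CSV
(`inst/extdata/uptake_factors.csv`); women get a narrower shoulder girdle, a
wider pelvis and the higher skull uptake that is a known confounder in female
patients. Kidneys and bladder are rendered as non-skeletal tracer pools so
that detectors must respect the skeletal mask. Pixel spacing defaults to
2.2 mm (a ~1.8 m body on 1024 rows with margin); the source acquisition
protocol fixes the matrix size but not the spacing, so this is the package's
own choice.

Lesions are isotropic Gaussian *multiplicative* bumps on the local uptake:

* **Metastases** land at random skeletal sites (regions sampled
  proportionally to area), with full width at half maximum set per region
  (5 px in ribs up to 14 px in the pelvis) and amplitude drawn from
  3–5 × local uptake by default.
* **Benign degenerative lesions** are restricted to 18 joint and
  vertebral-margin candidate sites (shoulders, elbows, knees, sacroiliac
  joints, vertebral margins), smaller (FWHM 5 px) and weaker (1.6–2.8 ×) —
  the arthritis/deformity pattern a classifier must learn to dismiss.

Lesion contrast is view-dependent: the excess is weighted by the fourth root
of the region's anterior/posterior emphasis ratio (geometric mean 1), a
simple depth proxy — a sternum lesion shows more strongly toward the anterior
camera, a vertebral one toward the posterior. This matters: the two views are
co-registered projections, and the midline chest is the one place where the
same lesion surfaces under different labels (sternum anteriorly, thoracic
spine posteriorly). The view-dependent contrast lets the BSI stage resolve
that ambiguity from the data.

**Ground truth.** Each lesion's true extent is the contour where uptake
exceeds the local normal level by ≥ 50% (multiplicative factor 1.5), per
view; amplitudes must therefore exceed 1.5 so the contour exists. Its true
involvement applies the same primary-view policy the pipeline uses (below).
Truth masks, regions, classes and involvements ship with every phantom.

Acquisition is modelled as a Gaussian system-resolution blur (σ = 2 px,
~10 mm FWHM) followed by independent Poisson counts scaled to an expected
10⁶ counts per view — typical delayed-phase statistics. Physically accurate
photon transport, scatter and collimator modelling are out of scope, so
passing tests demonstrate the pipeline's behaviour under idealized planar
geometry with realistic counting noise, not performance on clinical images:
real scans add patient-to-patient anatomical variability, attenuation
asymmetries, injection-quality variation and camera nonuniformities that the
phantom does not emulate.

## Atlas and registration

`load_atlas()` renders the sex-specific reference (stature 1.0) and attaches
the per-region mass fractions (`inst/extdata/mass_fractions.csv`): an
approximate adult reference-skeleton table (skull 0.12, spine 0.21 split over
segments, pelvis 0.11, femora 0.15, …) renormalized at load over the rendered
regions. The source analysis defines involvement as a percentage of the total
skeleton but never prints its weight table, so this editable CSV is the
package's stand-in.

`register_atlas()` fits the atlas to a patient scan per view:

1. **Photometric normalization** — images are compared as z-scored
   `log1p` intensities, so count levels and template units cancel.
2. **Global affine** — translation, per-axis scale and rotation about the
   image centre, fitted by Nelder–Mead on the normalized cross-correlation at
   1/4 scale (a 1/8-scale grid seeds the search). 100 iterations suffice
   because the phantom's stature transform *is* a similarity map.
3. **Photometric matching** — the warped reference is linearly regressed onto
   the patient image before residuals are taken; without this, body-size
   changes shift the z-score contrast and the demons stage chases intensity
   offsets instead of geometry.
4. **Demons refinement** — 20 iterations of a Thirion-style update
   $\Delta u = -r\,\nabla f / (\lVert\nabla f\rVert^2 + r^2)$ with per-step
   displacement capped at one coarse pixel and Gaussian smoothing
   (σ = 1.5 coarse px) of the field each iteration.

The coarse displacement is bilinearly upsampled, labels are pulled back by
nearest neighbour, and the result carries an NCC quality score (a score
below 0.5 flags the result rather than aborting — mirroring how clinical
software degrades gracefully) plus the fraction of positive warp Jacobians
(< 99% flags folding). Registering the reference to itself stays below one
pixel median displacement; synthetic affine + smooth deformations
(translation ±6 px, scale 0.95–1.05, rotation ±2°, smooth fields up to 5 px)
are recovered with ~0.95 mean label agreement.

## Hot-spot detection

The threshold at pixel $p$ is $k$ times a robust local background: the
median of smoothed same-region skeletal pixels within a 40 px disc
(evaluated on an 8 px grid and nearest-interpolated; grid points with fewer
than 10 skeletal neighbours fall back to the whole-region median and are
flagged). Estimating background per region is what keeps sensitivity uniform
between faint ribs and bright lumbar spine; the median resists contamination
by the lesion itself. Defaults: $k = 1.5$, minimum area 4 px, presmoothing
σ = 1.5 px. All intensity criteria are ratios, so detected masks are
invariant under any positive rescaling of the image.

Two details depart from a textbook threshold-and-label detector, both driven
by failure modes visible in the phantom:

* **Local-maximum gate.** Where a dim bone abuts a bright one (medial
  clavicle against the spine), resolution blur spills intensity across the
  label boundary as a monotone ramp that can exceed the dim region's
  threshold. Ramps contain no local maximum of the smoothed image, while
  genuine focal uptake does, so components without an interior peak are
  rejected.
* **Raw-contour area.** Detection is gated on the smoothed image (noise
  control), but the reported mask is re-measured on the raw image at the same
  threshold (largest connected piece). Smoothing inflates a small lesion's
  supra-threshold contour; re-measuring on the raw image undoes that bias and
  is exact on noise-free input. With truth defined at the 50%-excess contour
  and $k = 1.5$, noise-free BSI recovery errors stay within a few percent.

Components are 8-connected; one straddling a region boundary belongs to the
region holding the majority of its pixels (ties to the larger mass
fraction). Feature vectors cover size (area, region fraction), shape
(eccentricity from the coordinate covariance, solidity against the convex
hull, perimeter²/4πA irregularity), intensity (max/mean over local
background, contrast ratio) and localization (normalized centroid inside the
region's bounding box plus a region indicator). A single-pixel hot spot takes
the degenerate values eccentricity 0, solidity 1. Cold (photopenic) lesions
are out of scope by design.

## Classification and the patient score

Each (sex, region) gets its own classifier: a single-hidden-layer network
(8 sigmoidal units, logistic output, cross-entropy loss with weight decay
10⁻³, 300 iterations), fitted with `nnet` under a fixed seed, with
per-feature standardization frozen at training time. The smallest
architecture adequate for a ~26-dimensional feature vector was preferred over
anything deeper; prediction is an explicit forward pass from stored weights,
so a trained registry serializes to plain JSON. Regions with fewer than 10
training examples per class fall back to pooled axial/appendicular
classifiers (then a whole-skeleton pool), and the fallback is logged. Male
and female registries are disjoint; querying a sex that was never trained is
an error, not a silent fallback.

The patient-level ANN value is the **maximum** hot-spot probability (zero
without hot spots): any single metastasis makes the patient abnormal. Whether
the original software aggregates this way or uses a dedicated patient-level
network is not recoverable from the source; the maximum is this package's
documented, swappable choice. Hot spots with probability ≥ 0.5 count into the
BSI — the canonical decision boundary, exposed as `metastasis_threshold`.

## View policy for the BSI

Each region is quantified from one primary view to avoid double counting the
two projections of one lesion: spine and scapulae posteriorly; skull, sternum
and clavicles anteriorly; ribs, humeri, pelvis and femora as the average of
the two views (a lesion of an averaged region seen in only one view
contributes half). Overlapping cross-view hot spots carrying *different*
region labels are first merged into one instance — preferring the hot spot
whose region's primary view matches its own view, then the larger area, then
the posterior view. The per-view region area is the involvement denominator;
whether the original system used view-specific or merged denominators is
unstated, so this is a documented convention. BSI is clamped to \[0, 100\]
with a flag (superscan-like phantoms can overrun through view averaging).

## Statistics

`roc_analysis()` builds the empirical ROC over all distinct thresholds
(positive call: score ≥ threshold); the AUC is the trapezoidal integral,
identical to the Mann–Whitney statistic with ties counted ½ (a brute-force
pair-counting oracle verifies this to 10⁻¹² in the tests). The optimal cutoff
maximizes sensitivity − (1 − specificity); rationally equal criterion values
can differ by float rounding across thresholds, so ties are detected with a
10⁻¹² tolerance and broken toward higher specificity. `compare_auc()`
implements DeLong's correlated-ROC test (the field standard where the source
reports paired AUC p-values without naming a method); its type-I error at
n = 60 is verified to sit in \[0.03, 0.07\] over 2,000 null replicates.
`compare_proportions()` uses the chi-square test with continuity correction,
switching to Fisher's exact test when any expected cell is below 5.

**Risk categories.** ANN values bin at 0.25/0.50/0.75 with left-closed
intervals (0.25 belongs to the second bin); BSI values bin at 0.1/1/5,
left-closed, top category unbounded (5.0 belongs to the fourth bin). The
published range labels "0.1 to 1" and "1 to 5" are rounded display forms of
these edges.

**NRI.** For a 4 × 4 old-method × new-method table, the net gain in
reclassification proportion is (count above diagonal − count below
diagonal) / stratum size, *in both outcome strata*, and the total NRI is
net gain(events) − net gain(non-events). This sign convention is the only
one consistent with all six published summary values the package reproduces
(+3.6%, −26.0%, 29.6% for ANN bins; −40.8%, −72.8%, 31.9% for BSI bins), and
it is locked in by regression tests against the bundled tables
(`inst/extdata/reclass_*.csv`). Per-stratum significance uses the movement
test $z = (\mathrm{up} - \mathrm{down})/\sqrt{\mathrm{up} + \mathrm{down}}$
— which reproduces the published p = 0.38 for the ANN metastasis stratum —
and the total uses the standard NRI z statistic. Exact agreement with the
unnamed software behind the published p-values is not claimed beyond these
checks.

## Validation scales and what they show

The test suite and `scripts/acceptance.R` run fixed, seeded study conditions
chosen to finish on one CPU:

* detection recovery: 20 phantoms × 5 metastases, amplitudes 3–5×,
  10⁶ counts/view — lesion-level sensitivity ≥ 0.9, ≤ 1 spurious hot spot
  per phantom (development runs: sensitivity ~0.96–1.0, ~0 spurious);
* registration recovery: 20 seeded affine + smooth deformations — mean label
  agreement ≥ 0.9;
* end-to-end discrimination: train on 300 phantoms, evaluate the ANN value
  on 100 held-out phantoms (half with ≥ 1 metastasis) — ROC AUC ≥ 0.90.
  Training phantoms use the generator's true segmentation (a standard
  supervised setup); evaluation phantoms run the full pipeline including
  registration;
* statistical calibration: 2,000 null replicates of the paired AUC test at
  n = 60.

These are synthetic surrogates: the published cohort AUCs (for example 0.934
for men under the revised training database) require the original
multi-center patient data and are deliberately not claimed. What the
surrogate shows is that the implemented chain — segmentation, adaptive
detection, per-region classification, mass-weighted aggregation — preserves
the discriminative signal it is supposed to quantify, and that the
statistical layer reproduces the published worked examples exactly.

## Numerical choices and degenerate inputs

* Phantoms are bit-reproducible from `(config, seed)`; every stochastic
  entry point takes a seed, and derived sub-seeds stay below 2³¹.
* An all-zero view is a registration *error* (degenerate image), never a
  silent identity fit; a region with zero pixel area in a view is an error
  when used as an involvement denominator (the occluded sternum in the
  posterior view is the canonical case — its primary view is anterior).
* Empty hot-spot sets are valid everywhere: ANN value 0, BSI exactly 0.
* `bin_scores()` rejects out-of-domain scores (ANN outside \[0, 1\],
  negative BSI) rather than clamping.
* Single-class cohorts, mismatched pair lengths and mixed binning schemes
  are errors; `total_nri()` with no movement returns p = 1.

## Known limitations

2D planar geometry only (no SPECT/CT or PET extensions); hot lesions only;
no longitudinal change tracking; the phantom's anatomical variability is a
similarity transform plus smooth deformation, far narrower than clinical
variation; rib counting is not enforced (ribs are paired left/right labels);
and the classifier registry shipped by `train_classifiers()` reflects the
synthetic population it was trained on — applying it to real scans would
require retraining on labelled clinical hot spots.
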