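---
title: "Density-window fat volumetrics for whole-fish micro-CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Density-window fat volumetrics for whole-fish micro-CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctfat)
```

## The measurement

Computed tomography expresses X-ray attenuation in Hounsfield units (HU), a
linear rescaling in which water is 0 and air is −1000. Adipose tissue is
mildly negative, lean tissue slightly positive, bone strongly positive.
That ordering makes fat quantifiable by *density-window segmentation*:
count the voxels whose HU lies inside an interval bracketing fat, multiply
by the voxel volume, and normalise to the whole-body volume.

`ctfat` implements this workflow for whole-body micro-CT of fish:

1. **Ex-vivo calibration.** Dissected visceral fat is scanned on its own;
   ellipsoidal regions of interest (ROIs), each required to contain
   strictly more than 400 voxels, are placed in the block and their mean HU
   values averaged (unweighted across ROIs). The grand mean — for gilthead
   seabream, −115 HU — becomes the lower bound of the in-situ fat window.
   The reported value is rounded to integer HU, matching how such
   calibration constants are presented; all downstream computation uses
   the unrounded value.
2. **Whole-body delineation.** The fish is delineated as a seeded
   6-connected isocontour inside the body window (−1000 to +2500 HU).
   Voxels belonging to the scanner bed — identified from an empty-bed
   reference scan by thresholding and one-voxel dilation — are excluded.
3. **Fat segmentation.** Voxels inside the body whose HU falls in the fat
   window (−115 to +50 HU, both ends inclusive) are labelled fat.
4. **Volumetrics.** Per specimen: total volume, fat volume (cm³) and fat
   fraction (100 × fat / total). Per cohort: mean ± sample SD (n − 1).
5. **Group comparison.** Fed versus starved cohorts are compared per
   biometric parameter with a two-sided pooled-variance Student t-test,
   significance at p < 0.05, no multiple-testing correction.

Because no public whole-fish scans exist for this protocol, every stage is
validated on *digital phantoms* with known ground truth.

## The phantom model

`make_fish_phantom()` rasterises a stylised fish: a body ellipsoid lying
along the x axis containing a dorsal swim-bladder gas lumen, a spine, an
eye, and fat depots — a subcutaneous shell plus a visceral ellipsoid (an
optional head depot is available). A homogeneous bed slab spans the grid
under the fish, separated from it by a one-voxel air gap (the tissue paper
of the scanning protocol). Voxel values are tissue mean + Gaussian noise,
then blurred with a Gaussian kernel (σ in voxels) as a partial-volume
surrogate. Ground truth is computed from the unblurred label map, so true
volumes are exact voxel counts × voxel volume.

Two constructions keep the ground truth sharp:

* **Quantile-placed surfaces.** The body surface and depot boundaries are
  placed by rank statistics of ellipsoidal radius fields, so the labelled
  body volume and fat fraction hit their targets to within one voxel
  (far inside the 0.5-percentage-point requirement). Ties created by grid
  symmetry are trimmed deterministically by radius order, and surface
  voxels attached only diagonally are pruned so the body is a single
  6-connected component — exactly what a seeded isocontour can recover.
* **Geometry is RNG-free.** Randomness enters only through voxel noise,
  so the label map is a deterministic function of the spec, and the
  matching empty-bed scan shares the bed geometry exactly.

The true body volume excludes the swim-bladder lumen: gas is
radiologically indistinguishable from background air, so no density-based
contour can claim it, and defining truth this way makes zero-noise
recovery exact rather than approximately right.

### Tissue model

Only two attenuation values in the model are measured quantities: fat
(−115 HU, the ex-vivo calibration constant) and air (−1000 HU, by
definition of the scale). All other tissue means (soft +40, bone +1500,
bed +300, eye +10 HU; SD 15 HU throughout) are package parameters chosen
to be plausible for a teleost, and are labelled as such.

The default soft-tissue mean (+40 HU) lies **inside** the fat window,
whose upper bound is +50 HU. This is deliberate: lean-tissue densities
genuinely overlap so wide a window, and the phantom should expose that
behaviour rather than hide it. Analyses that need clean tissue separation
(exact-recovery tests, the reduction-robustness reference) set soft tissue
to +80 HU.

### Cohorts and scale

`make_cohort()` draws per-fish body volume, fat fraction, weight and
length from condition-specific Gaussians — baseline control
(33.792 ± 1.164 cm³, 48.737 ± 4.917 % fat), fed (71.289 ± 0.655 cm³,
44.618 ± 1.331 %) and starved (37.101 ± 2.077 cm³, 49.172 ± 3.080 %) —
truncated to ±3 SD (cohort fish are size-graded, and bounded draws
guarantee each fish fits its grid). Per-fish seeds derive
deterministically from the cohort's base seed.

Default phantoms use a 64 × 64 × 112 voxel grid at 2 mm isotropic
spacing. This *desk scale* preserves the real fish sizes (tens of cm³,
12–16 cm long) while keeping a full 18-fish analysis under a minute on one
CPU; the scanner's native 125 µm voxels would need ~10⁹-voxel grids. All
segmentation logic is scale-free, and the body-size QC floor (33,564
voxels, defined at 0.125 mm) is rescaled by the cube of the spacing ratio.
Resolution-sensitive checks (reduction robustness) use a finer reference:
an 8 cm³ fish at 0.5 mm spacing.

## Numerical choices

* **Axis and indexing conventions.** Arrays are (z, y, x), 1-based in R;
  spacing in mm; the world origin sits at the centre of the first voxel
  and defaults to the grid centre. Voxel volume is exactly the product of
  spacings.
* **Window endpoints are inclusive** on both sides; ROI membership is by
  voxel-centre inclusion (no partial-volume weighting) — simple,
  reproducible, and how viewer software counts voxels.
* **Image reduction is block mean pooling** (spacing × factor, trailing
  partial blocks dropped): the only pooling that preserves the mean HU of
  covered regions, which window segmentation depends on.
* **Bed removal is mask exclusion, not HU subtraction.** Subtracting bed
  HU from overlapping voxels would corrupt quantitation; excluding bed
  voxels (threshold on the empty scan, dilated one voxel to cover blurred
  edges) cannot.
* **Effective body lower bound −480 HU.** The nominal body window starts
  at −1000 HU, the air value, so naive thresholding floods the
  background. Region growing needs an effective lower bound, and its
  value matters under partial volume: at the air/tissue interface the blur
  sweeps every HU between −1000 and the tissue value, so a bound near air
  (e.g. −900) annexes almost the whole transition shell — at desk scale a
  ~40 % body-volume overestimate. The default −480 HU is the midpoint
  between air and lean tissue, i.e. the half-maximum edge criterion, which
  places the contour at the geometric boundary and leaves body volume
  unbiased (≲2 % on the reference phantoms). The bound is configurable;
  the nominal window is reported in the segmentation metadata.
* **Seeding.** One master seed; stage seeds are fixed offsets of it, and
  phantom noise runs under a local RNG scope that restores the caller's
  RNG state. Re-running a configuration reproduces every output bit for
  bit.
* **Degenerate t-test inputs.** With zero pooled variance the statistic
  is 0 with p = 1 for equal means, ±Inf with p = 0 otherwise (documented
  convention; the closed form is otherwise exact, with Welch available
  behind a flag). The pooled Student test is the default because the
  source protocol reports only "Student-T test".
* **Cohort fat fraction is the mean of per-specimen percentages**, not
  the ratio of summed volumes. Normalising each fish to its own total
  volume first makes the summary size-independent — and is the only
  convention consistent with the published cohort table, where the
  printed fat percentage (48.737) differs from the ratio of the printed
  mean volumes (100 × 16.442 / 33.792 = 48.66).

## Open choices made here

* The provenance of the fat window's **upper bound (+50 HU)** is not
  derivable from the calibration; it is treated as a fixed constant of
  the protocol, configurable but never calibrated.
* Whether the original analysis weighted ROI means by voxel count is
  unknown; this package uses **unweighted ROI means** (each ROI is an
  independent probe of the same homogeneous tissue).
* The reconstruction filter is not specified by the protocol; **ramp** is
  the default, with Shepp-Logan available. The projection stage is
  parallel-beam with a 180° arc by default (sufficient for parallel
  geometry; 360° is supported). HU↔µ conversion uses
  µ = µ_water (1 + HU/1000) with µ_water = 0.019 mm⁻¹, a configurable
  constant appropriate for a ~45 kVp-class beam.

## What the phantoms do and do not show

The phantom suite demonstrates that the implementation is correct in the
senses that can be checked exactly: zero-noise phantoms are recovered
voxel-for-voxel (body count equal to truth; with lean tissue outside the
window, the fat mask equals the fat label set exactly); volumes are exact
voxel arithmetic; the projection/reconstruction loop preserves region
means to a few HU at 600 angles; the t-test matches its closed form and
holds its nominal type-I error at n = 6; and the full pipeline is
deterministic under a fixed seed.

They equally expose what the *method* — not the code — cannot do:

* **A window bound at the tissue mean halves that tissue.** The fat
  window's lower bound equals the calibrated fat mean, so under any
  symmetric voxel noise the expected capture of deep fat voxels is 50 %,
  independent of the noise scale (blur and pooling shrink the noise but
  leave the mean on the bound). In real scans this is masked by in-situ
  fat being a partial-volume mixture shifted above the pure ex-vivo
  value; in a phantom whose fat is pinned to −115 HU it produces a
  systematic underestimate of the fat fraction.
* **Lean-tissue overlap.** With soft tissue at +40 HU inside the window,
  most lean voxels are counted as fat; the overlap and the interior-fat
  loss partially cancel, and the pipeline's cohort fat-fraction estimate
  at default desk-scale conditions lands several percentage points below
  the ground-truth fraction (the acceptance script reports both
  estimated and true fractions side by side).
* **Desk-scale partial volume.** At 2 mm voxels the boundary shell is a
  much larger fraction of the body than at 125 µm, so estimate biases
  here are upper bounds on what the protocol would show at native
  resolution; fat-fraction differences between reduction factors are
  likewise resolution effects (≈1 pp on the fine reference, larger on
  coarse grids).
* The phantom is **anatomically stylised** (ellipsoids and shells, a
  single homogeneous lean compartment, no beam hardening, scatter, rings,
  or cone-beam geometry). Passing tests validate the measurement
  pipeline, not anatomical realism.

Group *comparisons* are robust to all of the above: the segmentation
biases act alike on both cohorts, and the fed/starved differences in
total and fat volume remain strongly significant through the full
pipeline.

## Problem sizes

Default analyses use 64 × 64 × 112 grids at 2 mm (single fish ≈ 0.9 M
voxels), cohorts of n = 6 per condition, 48³ calibration blocks at
0.125 mm with six 0.6 mm spherical ROIs (> 400 voxels each), 600
projection angles for reconstruction checks, and 10,000 simulated pairs
for the type-I-error calibration. These sizes were chosen so that the
complete validation suite and a full two-cohort analysis each run in well
under a minute on a single CPU while keeping every voxel-level check
exact.
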