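---
title: "Measuring cerebral torque from hemispheric surface meshes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring cerebral torque from hemispheric surface meshes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(braintorque)
```

## The measurement problem

The human brain is not mirror-symmetric: in the typical configuration the
right frontal and left occipital regions protrude beyond their
contralateral counterparts, the left occipital pole sits lower than the
right, and the inter-hemispheric fissure bends toward the right at the back
of the brain. This counter-clockwise shape asymmetry — the cerebral torque
— is quantified here from closed outer cerebral-hemisphere surfaces
(smoothed, sulci filled) as produced by standard surface-reconstruction
pipelines, in an RAS frame (+x subject right, +y anterior, +z superior)
roughly aligned to MNI axes. `braintorque` measures, per subject:

* **dimensions** — bounding-box length (y), height (z) and width (x) of
  the left hemisphere, the right hemisphere, and the whole cerebral
  surface, with length/width and height/width ratios and L−R asymmetries
  ΔL, ΔH, ΔW;
* **petalia** — L−R difference of the y coordinates of the frontal
  (anterior) and occipital (posterior) poles;
* **shift** — L−R difference of the z coordinates of the same pole
  vertices;
* **bending** — the signed angle between the x axis and the normal of a
  total-least-squares plane fitted to the medial surface in the frontal
  and occipital quarters of the brain, averaged over the hemispheres;
* the **configuration** (LF/LO, LF/RO, RF/LO, RF/RO) of each feature's
  frontal/occipital sign pair.

Cohort-level inference uses two-tailed one-sample t tests against zero
asymmetry, uncorrected 2×2 chi-squared tests for prevalence differences
between groups, and Pearson correlations, at a fixed α = 0.01 with no
multiplicity correction.

## Mid-sagittal plane estimation and alignment

Affine normalization to a template leaves residual misalignment between
the inter-hemispheric fissure and the plane x = 0, which would bias every
signed metric. The pipeline therefore re-estimates the mid-sagittal plane
(MSP) from the meshes themselves:

1. compute outward per-vertex normals (area-weighted incident-face
   average);
2. select *medial-surface* vertices: those whose normal makes an angle
   below `theta_max` (default 40°) with the midline-pointing axis — +x̂
   for the left hemisphere, −x̂ for the right;
3. restrict to the central band of the whole-brain antero-posterior range
   (middle `central_fraction`, default 0.5), where frontal/occipital
   bending deviates least from a flat midline;
4. fit a total-least-squares plane (centroid + direction of smallest
   variance from the SVD of the centred points) to the pooled selection of
   both hemispheres;
5. rotate both hemispheres about the in-plane axis `n × x̂` through the
   fitted centroid by the angle between the fitted normal and x̂, and
   translate along x so the plane contains the origin.

Steps 2–5 are iterated (default cap 5, tolerance 0.01°) because the
rotation changes the normals and hence the medial selection; in practice
small misalignments converge in one or two iterations.

A note on step 2. A simpler criterion — folding the angle through
`|n · x̂|` so one rule covers both hemispheres — also selects the *lateral*
convexity around each hemisphere's left/right extreme point, where normals
align with ±x̂ while pointing *away* from the midline. On smooth closed
surfaces those lateral caps sit ~65 mm off the midline on both sides and
can dominate the variance of the pooled cloud, in which case the
smallest-variance direction of the fit is no longer x̂ and the MSP estimate
collapses. Taking the angle to the midline-pointing axis of the labelled
hemisphere keeps the criterion purely normal-based and excludes the lateral
caps exactly. For an unlabelled (`side = "whole"`) mesh the folded
criterion remains available and is what the cube/sphere selection examples
in the tests exercise.

Rotations about the x axis itself leave the MSP invariant and are therefore
*unobservable* to any MSP-based correction: pitch/roll misalignment must be
handled by the upstream template registration. The rotation-invariance
tests accordingly perturb brains about axes in the span of ŷ and ẑ.

## Sign conventions

All asymmetries are left minus right. Negative frontal petalia means the
right frontal pole leads; negative occipital petalia means the left
occipital pole trails — so the human-typical pattern has both petalia
negative. Negative occipital shift means the left occipital pole sits
lower. For bending, the fitted plane normal is canonicalised to
x-component ≥ 0 and the angle is signed by the normal's y component such
that a midline deviating toward the subject's right at the regional
extreme is positive in *both* regions (for the occipital region a
rightward posterior edge tilts the normal anteriorly; the frontal region
uses the opposite y sign). The human-typical rightward occipital bending
is therefore positive. No published sign rule exists for bending; this one
is enforced by the mirror anti-symmetry tests, under which every signed
metric must negate exactly when the brain is mirrored across x = 0.

Configuration labels name the side expressing the feature: for petalia and
shift, frontal > 0 ⇒ LF and occipital < 0 ⇒ LO; for bending, positive
(rightward) ⇒ RF/RO. Exact zeros are resolved deterministically (RF
frontally, LO occipitally) and flagged, so prevalence denominators always
sum to the cohort size.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `theta_max` | 40 | degrees | medial-surface selection threshold |
| `central_fraction` | 0.5 | — | y-band for the MSP fit |
| `quarter_fraction` | 0.25 | — | y-band of the frontal/occipital bending regions |
| `align_tol` | 0.01 | degrees | alignment convergence tolerance |
| `align_max_iter` | 5 | — | alignment iteration cap |
| `rounding` | 2 | decimals | applied only when records are serialised |
| `scale` | 1 | — | per-subject uniform normalized→native factor |

The 40° threshold and the quarter regions follow the published procedure;
the central fraction is not specified there and 0.5 was fixed once as the
band that excludes both bending regions entirely (the quarter bands touch
it only at their boundary). The regional plane fits are unweighted; the
poles are single raw vertices (ties broken by lowest vertex index for
determinism), not interpolated extrema.

## The synthetic cohort generator

No scan data accompany the measurements, so validation rests on synthetic
brains with *known* torque. Each hemisphere is half of a superellipsoid
`|x/a|^e + |y/b|^e + |z/c|^e = 1` (defaults a, b, c = 67, 87, 59 mm,
e = 2.5) cut at the midline with a flat medial wall offset by half a 1 mm
inter-hemispheric gap, closed and watertight. The defaults reproduce adult
human whole-brain bounding-box extents (≈174 × 118 × 135 mm); the
chimpanzee regime scales all coordinates by the published length ratio
(111.1/174.9 ≈ 0.635).

`apply_torque()` composes, in order: left-hemisphere anisotropic scaling
(ΔL/ΔH/ΔW, with the lateral scaling anchored at the medial wall so the gap
is preserved); petalia as antero-posterior displacement fields split ±half
between the hemispheres and tapered by a cosine ramp over the outer 40% of
the y range (zero slope at the pole, so the pole displacement equals the
parameter; zero by mid-brain, so the MSP band is untouched); shift as the
analogous dorso-ventral fields; bending as a lateral shear of *both*
hemispheres with slope `tan(angle)` over each outer quarter (within the
fitted band the sheared wall is exactly a tilted plane, so the target
angle is recovered by construction-independent measurement); a global size
factor; a rigid tilt about ẑ; and i.i.d. Gaussian vertex noise (default SD
0.15 mm, the order of a subvoxel surface-reconstruction error at 0.6–1 mm
voxels).

Cohort regimes draw per-subject parameters independently from normal
distributions: the human regime centres petalia/shift/bending and ΔH/ΔW on
the published human cohort means; the chimpanzee and null regimes centre
everything at zero. Where the source tables print mean ± SD (the
dimensional asymmetries) those SDs are used directly; for the torque
features only means and t statistics are printed, so the implied SD
`|mean|·√n / |t|` is used. The residual rigid tilt is N(0, 1°), a plausible
leftover from affine normalization.

### Two structural identities worth knowing

**ΔL is not free.** With bounding-box length and single-vertex poles, the
length asymmetry satisfies ΔL ≡ petalia(frontal) − petalia(occipital) for
*any* brain — both sides of the identity are L−R differences of the same
extreme-y vertices. The published human means obey it (0.92 ≈ −0.67 −
(−1.58)), and the strong reported correlation between length asymmetry and
occipital petalia is partly this identity at work. Consequently the
generator cannot inject ΔL independently of petalia: the cohort sampler
draws petalia and records ΔL as the derived value, and `apply_torque()`
reports *net* ground truth whenever an explicit `dL` scaling is combined
with petalia fields.

**Bending leaks into width.** Bending is, by definition, midline tissue
crossing x = 0; the displaced medial wall extends the bent-into
hemisphere's bounding box by up to `tan(angle) ×` the quarter length
(≈ 2.7 mm at 3.6°). This is a property of bounding-box width on any bent
brain, not a generator artefact; it is why the human-regime synthetic
cohort shows a significant positive ΔW that the real cohort does not — real
lateral surfaces are irregular enough that the lateral extreme, not the
displaced wall, sets the box on both sides. `truth$dW` records only the
injected scaling offset, and ΔW is excluded from the recovery calibration.

### What the generator does and does not emulate

It emulates: left/right surface pairs with controllable petalia, shift,
bending, dimensional asymmetry, rigid midline tilt, brain size, and
measurement noise; realistic magnitudes for all of them. It does not
emulate: gyrification (irrelevant to a pipeline consuming closed outer
surfaces), realistic lateral-surface irregularity (see the ΔW note),
spatially correlated reconstruction error (noise is i.i.d.), or
species-accurate allometry beyond a uniform scale factor. Passing
recovery tests therefore demonstrate that the *pipeline* is unbiased and
well-calibrated on surfaces whose ground truth is known — they do not
certify accuracy on real cortical surfaces, whose medial walls are
interrupted by the corpus callosum and whose poles are blunter than a
superellipsoid's.

## Numerical choices

* Plane fits use the SVD of the centred point matrix; the normal's sign is
  canonicalised (x component ≥ 0, next nonzero component positive at
  x ≈ 0) to remove the eigenvector sign ambiguity. Collinear point sets
  (second singular value numerically zero) are rejected.
* Vertex normals orient by the mesh's signed volume, so inward-wound
  closed meshes are handled; degenerate faces contribute zero weight;
  isolated vertices are an error.
* Watertightness is checked (every edge shared by exactly two opposed
  half-edges) but violations only warn: reconstructed outer surfaces are
  closed, hand-built fixtures need not be.
* Alignment warns and returns the last iterate on non-convergence rather
  than failing, and records the residual angle on the object.
* Rounding to 2 decimals happens only at the CSV layer; the JSON sidecar
  and all in-memory values keep full precision.

## Problem sizes used in validation

The test suite and the acceptance script validate at sizes chosen to make
the statistics informative while keeping meshes light: mesh resolution
32–48 (≈ 1 200–2 600 vertices per hemisphere; bounding-box extents change
by < 0.5% when resolution doubles), 50-subject human-regime cohorts for
measured-vs-injected calibration (slope within [0.9, 1.1], r > 0.95 per
torque feature), 1 000 15-subject null cohorts for type-I calibration of
the t test at α = 0.01, and the full published cohort sizes (91/78) for
the analysis scripts under `analysis/`.

## Known limitations

* MSP correction cannot observe rotations about the x axis (above).
* Bounding-box dimensions are extreme-value statistics: single-vertex
  sensitivity is the price of matching the published procedure, mitigated
  only by surface smoothness.
* The 2×2 collapse behind the between-species petalia chi-squared (modal
  quadrant vs rest) is reconstructed, not stated in the source; it
  reproduces the printed statistic to 2 decimals but is not assumed
  elsewhere.
* The chimpanzee length/width ratio printed as 1.28 is 1.27 when computed
  as the ratio of the printed means — a mean-of-ratios vs ratio-of-means
  discrepancy; the package reports the computed value.
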