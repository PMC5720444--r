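---
title: "Validating black-box deformable registration with regqa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating black-box deformable registration with regqa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regqa)
```

## The problem

Commercial deformable image registration systems used in image-guided
radiation therapy are frequently *black boxes*: the deformation function
they compute cannot be inspected, exported, or evaluated at a point.  All
the user can do is store a registration and reapply it to images.  Before
such a system is trusted clinically, its behavior must be characterized —
but every standard accuracy measure (landmark error, displacement fields,
Jacobians) presumes access to the transformation.

`regqa` implements a four-component validation protocol that works
entirely through the image-in/image-out interface such systems expose:

1. **Digital phantom study** — a cylindrical water phantom with plastic
   spheres, rendered in CT, MRI and PET with modality-specific intensity
   models, and modified between "acquisitions" by known sphere
   translations or replacements.  Every scenario exports its ground truth.
2. **Relative validation** — post-registration similarity measures
   (normalized mutual information, mutual information, symmetric
   correlation ratio, correlation coefficient) computed over registered
   pairs, and a harness that ranks registration settings by mean metric.
3. **Absolute intra-modality validation** — synthetic cubic B-spline
   deformations of known magnitude applied to a baseline image, and a
   *grid-probe* estimator that measures the residual displacement error
   after registration without ever touching the system's transform.
4. **Absolute inter-modality validation** — overlap metrics (Tannimoto
   and Dice coefficients, mean surface distance) on binary masks pushed
   through the stored deformation.

## The displacement-error estimator

The central quantity is the displacement error

$$\mathrm{DE} = \sqrt{\tfrac{1}{N}\textstyle\sum_{i=0}^{N-1}\varepsilon_i^2},$$

the RMS over sampled points of the residual displacement
$\varepsilon_i$ between each point's true position and the position
produced by registration; its *axial* variant uses only the in-plane
$(x, y)$ components.  When the transform is accessible (`true_de()`,
`true_de_dense()`) this is evaluated exactly.  When it is not, the
grid-probe pipeline estimates it:

* `make_grid_image()` plants `n` unit-intensity voxels at random,
  separated voxel centers in an otherwise zero volume and records their
  exact positions;
* the known deformation is applied by `splat_forward()` — trilinear
  forward splatting, which conserves both total intensity and each
  deposit's first moment, so an intensity-weighted centroid recovers the
  mapped position exactly;
* the black-box system's stored deformation is applied to the deformed
  grid *as an image* (`system_apply()`);
* `detect_points()` labels 26-connected components above 5% of the
  maximum intensity and returns intensity-weighted centroids, and the
  matcher pairs them with the planted truth;
* the DE over matched pairs is the estimate (`approximate_de()`), with
  the matched fraction reported and low-fraction estimates flagged.

### Correspondence

Two matchers are provided.  `match_points()` is a conservative
mutual-nearest-neighbor rule with an ambiguity-ratio test (second-nearest
candidate must be 1.5 times farther) — appropriate for the post-recovery
regime where residuals are far smaller than the probe spacing, and for
characterizing how dense grids fail by merging and crossover.

`match_points_coherent()` handles the self-validation regime, where the
probe must be matched across the raw deformation and per-point
displacements can exceed the inter-point spacing.  It alternates an
entropic optimal-transport plan (Sinkhorn iterations with annealed
temperature, 60 to 1.5 mm²) between the displacement-compensated
predictions and the detections with a Gaussian kernel-ridge fit of the
displacement field implied by the plan (bandwidth annealed 45 to 14 mm,
ridge 0.02).  Two structural facts make this reliable: deformations are
spatially smooth, and splatted probes carry quantized unit mass, so a
detection of mass ≈ 2 is identifiably a merger of two probes and receives
transport capacity (and finally hard assignment) for both.  The final
assignment is a greedy capacity-respecting pairing on compensated
distances (radius 10 mm).  Annealing parameters were fixed against
synthetic fields of graded magnitude; they are not exposed as tuning
knobs in the study harnesses.

### Accuracy self-validation

`accuracy_study()` replicates the estimator's validation: for a graded
family of known transforms it plants a grid, splats it with the
transform, and runs the full detect/match pipeline against the planted
truth, tabulating the measured DE against the exact per-point aggregate.
The reference value is Eq.-style DE over the *planted points* — the
quantity the probe actually estimates; the dense whole-frame RMS is
recorded alongside (`dense_de`), and the difference between the two is
the sampling error of a 1000-point probe, not an estimator fault.  At the
study conditions (512×512×43 voxels at 0.8×0.8×7.5 mm³, twelve
boundary-zeroed random transforms spanning DE 0–9.35 mm, 1000-point
grids) the pipeline reproduces truth to a few hundredths of a millimeter
in both 3D and axial components; `scripts/acceptance.R` recomputes this
end to end.

## The synthetic deformation family

`random_transform()` draws cubic B-spline control-point coefficients
i.i.d. uniform in $[-c, c]$ on a grid covering the volume plus the cubic
support margin, and zeroes five control-point layers on every side so the
displacement vanishes identically at (and within one control spacing of)
the volume faces — anatomy pinned at the field of view, and probe points
cannot leave the frame.  `scale_transform()` scales coefficients, and by
linearity the displacement field and its DE scale exactly, which is how
the acceptance study hits prescribed DE targets without re-simulation.
The default control spacing of 32 mm matches the coarse-to-medium
refinement scales (2–5 cm) quoted for the commercial system's settings.

Two properties deserve note.  First, the zero-displacement band
concentrates the deformation in the interior, so a frame-wide RMS of
9.35 mm implies interior displacements several times larger — a harsher
correspondence regime than clinically derived fields of equal RMS, which
is why the coherent matcher exists.  Second, coefficients large relative
to the control spacing can locally fold the field; the probe pipeline
never needs to invert the map numerically (splatting is forward,
recovery is lazy-inverse), but `warp_volume()` does, and it refuses
(with an error suggesting smaller deformations) when fixed-point
inversion (tolerance 0.01 mm, 20 iterations) fails at more than 0.1% of
voxels.

A second, data-driven family comes from `reference_ffd_register()`: a
deliberately minimal SSD gradient-descent registrar over B-spline
coefficients that snapshots the transform after every iteration, so each
snapshot is a plausible deformation of graded magnitude.  Step halving
enforces a non-increasing SSD trajectory; both images are pre-smoothed
by one voxel by default because sharp-edged images otherwise lock the
optimizer at the aligned-lattice configuration (every voxel sits at an
interpolation kink); and image gradients use central differences for the
same reason.  Its single protocol role is generating transforms and a
registrar-backed test system (`ffd_system()`) — it is not a production
registration algorithm.

## Geometry and numerical conventions

* Axis-aligned geometry only; voxel-center convention with 1-based
  indices: voxel $(i,j,k)$ sits at `origin + (i-1, j-1, k-1) * spacing`,
  with $z$ the slice axis.  "Axial" DE is the in-plane $(x,y)$ RMS
  component.  Oblique NIfTI/NRRD headers are rejected rather than
  silently ignored.
* Masks are stored on disk as unsigned 8-bit 0/1; intensity volumes as
  64-bit doubles, so round trips are bit-exact.
* Polygon rasterization uses the even-odd rule at voxel centers with a
  strict interior test; self-intersecting polygons warn and proceed.
* Similarity metrics bin intensities into 64 equal-width bins over each
  image's robust (0.5th–99.5th percentile) range by default; entropies
  are in bits; NMI is the Studholme form $(H(A)+H(B))/H(A,B)$; the
  symmetric correlation ratio averages the two directed $\eta^2$ values.
  All voxels of the shared grid participate — no background masking —
  so similarity gains driven by structures away from the region of
  interest remain visible, which is exactly the failure mode relative
  validation must be able to expose.
* Surface distance uses 6-connectivity surface extraction (volume faces
  count as background) and symmetric means of voxel-center nearest
  distances in mm.  Sub-voxel surface meshing was rejected as
  unverifiable against an exhaustive oracle.

## The digital phantom

`phantom_spec()` describes a cylindrical water phantom (default outer
radius 100 mm, height 120 mm, 3 mm plastic wall, 15 mm base slab with a
12×12 grid of holes 8 mm apart, seven plastic spheres of radii
5–15 mm).  Rendering classifies materials at voxel centers, supersamples
boundary voxels 2×2×2 for partial volume, applies an isotropic Gaussian
PSF at the modality resolution (CT 0.7 mm, MRI 0.8 mm, PET 6.5 mm) and
optional Gaussian noise under a mandatory seed.  The intensity maps are
deliberately simple (CT: water 0 HU, plastic +120 HU, air −1000 HU;
T1 MRI: signal from water only; PET: activity in water only); physical
acquisition effects (beam hardening, MRI sequences, PET attenuation or
scatter) are out of scope.  Because the plastic wall is signal-free on
MRI, the apparent phantom radius is smaller on MRI than CT — the
modality-dependent bias the phantom study is designed to expose; a test
measures it via half-maximum crossings.  Cylinder and sphere dimensions
are configuration defaults chosen to fit the stated image matrices, not
measured values.

## Mock systems and what passing tests mean

`mock_system()` implements the black-box contract as a test double: it
"recovers" the exact lazy inverse of the true transform (which the study
harness passes alongside the images; real systems ignore it), optionally
composed with injected residuals per setting.  Exact-inverse mocks bound
the protocol's detection noise floor; constant-offset residuals must be
read back at their true magnitude (a (3,4,0) mm residual measures as
DE 5.0); graded translation residuals must rank strictly inversely under
mean NMI.  Graded *B-spline* residuals are used where invertibility
permits — on small test frames a rough field scaled to a whole-frame RMS
of several millimeters folds, so the injected-error suites use
translations, which warp exactly.

The synthetic studies emulate geometry, smooth deformation, merging and
crossover of probe points, modality contrast, and resampling through an
opaque pipeline.  They do not emulate real anatomy, intensity
distortions, registration-algorithm behavior, or DICOM plumbing; a
passing suite therefore validates the *measurement machinery*, not any
particular registration system, and says nothing about how a commercial
algorithm will deform real patients.

## Problem sizes

The accuracy replication runs twelve transforms on the full
512×512×43 thoracic-CT geometry with 1000-point grids (about a minute).
Unit and property tests use scaled-down frames (tens of voxels per axis)
chosen so every code path — boundary zeroing, inversion, merging,
ranking — is still exercised; the mock-recovery studies use 256×256×30
probe frames and 64×64×16 phantom renders with 20 Monte-Carlo repeats
for the ranking study.
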