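---
title: "Contour-guided deformable registration and dose accumulation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contour-guided deformable registration and dose accumulation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dosewarp)
```

## The problem

During a course of prostate radiotherapy the patient's anatomy drifts from
the planning CT: the bladder fills and empties, the rectum changes content,
the prostate shifts by millimetres.  Daily cone-beam CTs (CBCT) capture the
anatomy of each fraction but are noisy, biased in intensity, and poor in
soft-tissue contrast.  Estimating the *delivered* dose requires a dense
deformable mapping from the planning frame to each fraction: warp each
fraction's dose back onto the planning anatomy, sum, and compare the
accumulated dose-volume-histogram (DVH) indices with the plan.

`dosewarp` implements that chain: rigid bone-based positioning
initialisation, three weakly supervised convolutional registration
networks (driven by scans, organ label images, or both), a classical
multi-resolution B-spline free-form-deformation (FFD) baseline, geometric
evaluation (DSC, ASD, HD, HD95), Jacobian-determinant folding analysis,
and DVF-based dose warping, accumulation and DVH reporting.  A synthetic
pelvic phantom with analytically known diffeomorphic deformations makes
every stage testable without patient data.

## Conventions

* Volumes are 3D arrays with per-axis spacing (mm) and an origin: voxel
  `(i,j,k)` (0-based) sits at `origin + (i,j,k) * spacing`; axis order is
  (x, y, z).
* Labels use the fixed code set 0 background, 1 body, 2 rectum, 3 bladder,
  4 prostate.
* A deformation field stores per-voxel displacements in mm on the fixed
  grid, in the pull-back convention: `warped(x) = moving(x + u(x))`.
  Every producer (networks, FFD, phantom ground truth) and every consumer
  (warping, Jacobian analysis, dose accumulation) shares this convention,
  which removes the classic silent-inverse family of bugs.

## Registration networks

The three variants share one 3D U-Net body: four stride-2 encoder
convolutions (default widths 16/32/32/32), a mirror decoder with skip
connections, LeakyReLU(0.2), and a flow head that predicts the three
displacement components at half resolution, trilinearly upsampled to the
full grid.  Displacements are predicted in voxels internally and converted
to millimetres at the interface, so stored fields are
resolution-independent.  Grid dimensions must be divisible by 16; the
error message reports the padding that would fix an incompatible grid.

The variants differ only in inputs and loss:

| variant  | inputs (channels)            | loss                                   |
|----------|------------------------------|----------------------------------------|
| `sc`     | fixed + moving scans (2)     | α·NMI + λ·smooth, α=1, λ=4             |
| `msk`    | fixed + moving labels (2)    | α·L1 + λ·smooth, α=2, λ=4              |
| `sc_msk` | scans + labels (4)           | α·NMI + β·L1 + λ·smooth, α=1, β=2, λ=4 |

Design notes, in rough order of how much they matter:

* **L1 on one-hot indicators, not integer codes.**  The label *input* to
  the network is the single-channel coded image scaled by 1/4, but the L1
  dissimilarity is computed on one-hot organ indicators.  On integer codes
  a bladder-vs-rectum error (|3−2|) would cost less than a
  bladder-vs-body error (|3−1|), an entirely arbitrary ordering.
* **Smoothness normalisation.**  `smoothness_loss()` reports the sum over
  the nine direction/component pairs of the mean squared forward
  difference (so a linear field `u = c·x` scores exactly `c²`).  The
  diffusion regulariser conventionally used with these loss weights is the
  *mean* over those pairs — nine times smaller — and that is the
  normalisation `total_loss()` and the training loop apply λ to.  Mixing
  the two conventions over-regularises nine-fold and visibly caps the
  attainable organ overlap.
* **NMI estimator.**  Differentiable soft binning: each voxel splits unit
  mass linearly between two adjacent bins (triangular Parzen window), 32
  bins by default, Studholme normalisation `(H(A)+H(B))/H(A,B)` in
  [1, 2], returned negated.  A constant image has zero marginal entropy;
  the documented fallback returns the independence floor (−1) with zero
  gradient rather than NaN.
* **No diffeomorphic integration layer.**  Only the diffusion regulariser
  discourages folding; the folding that remains is *measured* (Jacobian
  determinant ≤ 0 percentage per organ) rather than prevented, which is
  the phenomenon of interest downstream.
* **Validation measure.**  "Best epoch" selection uses mean organ DSC on
  the validation pairs for the label-aware variants and the negated
  validation loss for `sc`, which has no labels at validation time.
* **Ties in label warping.**  Warped one-hot channels are re-assembled by
  argmax with ties resolved to the lowest label code, making the operator
  deterministic.

Training uses Adam, batch size one pair, and the stepped schedule
`lr_init × 0.7^floor(epoch/10)` with `lr_init = 5e-4` over 150 epochs as
the package default.  Desk-scale runs (the test suite and the acceptance
script) train for 8–15 epochs on 20 pairs of 64×64×32 voxels at reduced
widths (8/16/16/16); at that step budget — roughly fifty times fewer
updates than the default regime — the initial rate must co-scale, and
those runs use `lr_init = 2e-3` with the same schedule shape.  The
schedule itself is always verifiable at the defaults
(`lr_schedule(10)` = 3.5e-4).

The backward pass is hand-written (im2col + GEMM convolutions with cached
column matrices, exact gradients through the trilinear spatial transformer
and the soft-binned NMI) and is verified against finite differences in the
test suite; the L1 term contributes subgradients at its kinks, as usual.

## FFD baseline

The classical comparator is a cubic B-spline free-form deformation driven
by NMI: a four-level image pyramid with resolution factors 4, 4, 2, 1
(Gaussian smoothing of σ = factor/2 voxels per level), a control lattice
whose spacing follows the pyramid down to 8 mm isotropic, and an adaptive
stochastic gradient ascent: each iteration samples 2000 random voxels,
forms the soft-binned NMI gradient with respect to the control points
(chained through the trilinearly interpolated moving-image gradient), and
takes a normalised step with a decaying gain `(1 + k/50)^-0.602`,
backtracking once (half step) if the sampled NMI does not improve.
Iterations per level (200), sample count and bin count are configurable;
the reference library the configuration emulates leaves the same knobs to
its defaults.  Coarser levels carry their displacement down the pyramid
additively, and the final field is guaranteed not to degrade the
full-volume NMI relative to the unregistered pair (the best intermediate
is kept).

## The phantom

The generator emulates what the downstream machinery actually depends on,
not CBCT physics:

* **Anatomy** (world mm, grid centred on the origin): an elliptical body
  (85/75/95 mm semi-axes), bilateral iliac bone arcs (an elliptic annulus
  band, |x| ≥ 30 mm, 700 HU), a prostate ellipsoid (20/17/15 mm at
  (0, 10, −10)), a bladder sphere (radius 20 mm at (0, −25, 15)), and a
  rectum tube (radius 11 mm, length 70 mm, posterior).  Sizes are typical
  of adult male pelvis contours; organs are verified disjoint at
  generation.
* **Deformation** (planning → daily, analytic): a radial bladder
  expansion (pure scaling inside the bladder — so a filling factor `s`
  multiplies the bladder volume by `s³` — with a 20 mm Gaussian decay), a
  plateaued prostate offset, and a low-frequency sinusoidal body warp
  with seed-determined phases.  Defaults: filling 1.15, offset
  (2, −2, 1) mm, warp 2.5 mm at 120 mm wavelength — a moderately deformed
  daily pelvis.  The generator evaluates the Jacobian determinant of the
  analytic map on the grid and refuses any parameterisation that folds.
* **Daily volumes**: the forward map is inverted per voxel by fixed-point
  iteration (converges in a handful of steps at these amplitudes), and
  daily labels are evaluated analytically at the inverse-mapped voxel
  centres, so they are crisp rather than resampled.  The daily scan gets
  CBCT-like degradation: contrast compression (×0.7), intensity bias
  (+15 HU) and extra noise (25 HU), plus an optional rectal air pocket.
  Degradation touches intensities only — label geometry is exactly the
  deformed geometry, as delineated contours would be.
* **Dose**: prescription (80 Gy) inside the prostate plus a 5 mm margin,
  Gaussian falloff (σ = 6 mm) outside, computed from a Euclidean distance
  transform.  Deliberately simple; it exercises dose warping, summation
  and DVH indices, not treatment planning.
* **Cohorts** (`phantom_cohort()`) jitter the deformation per pair —
  filling in 1.05–1.25, per-axis prostate shifts in ±4 mm, warp amplitudes
  in 1–3 mm, independent phases — emulating fraction-to-fraction
  variability of one patient.

What the phantom does *not* emulate: scatter and beam hardening, sliding
interfaces, content changes without correspondence (the gas pocket is an
intensity confound only), inter-patient anatomical variability, and
planning-system dose.  Passing the phantom study therefore demonstrates
that the machinery is correct and that the qualitative method ordering
(label-aware variants ≫ intensity-only ≈ rigid at desk scale) emerges for
the right reasons — not that clinical accuracy ranges are reproduced.

## Discretisation limits

Warping binarised masks can only localise a boundary to a fraction of a
voxel: one-hot trilinear interpolation recovers a flat boundary to about a
quarter voxel on average.  On the 3 mm training grid this caps the
achievable DSC of the *ground-truth* field itself at roughly 0.91 for the
thin rectum (prostate ≈ 0.95, bladder ≈ 0.97).  At clinical-like
resolution (1.5 mm, 128×128×64) the same check gives ≥ 0.977 for all
organs, which is where the ground-truth-consistency invariant is
evaluated.  Held-out network DSC on the 3 mm grid should be read against
the same ceiling: the scaled-down label-driven network reaches ≈ 0.93
against a ≈ 0.94 ceiling.

## Geometric and dose evaluation

* Surfaces are border voxels (a mask voxel with a face-adjacent outside
  voxel; array-boundary voxels count), distances are Euclidean mm between
  voxel centres.  ASD is directed (planning → warped) as printed in the
  evaluation protocol, with a symmetric option; HD95 takes the
  95th percentile (linear interpolation) per direction, then the maximum.
  All of them are checked exactly against a brute-force double-loop
  oracle on small random masks.
* The Jacobian determinant uses central differences in mm (one-sided at
  the boundary); folding is reported as the percentage of organ voxels
  with det ≤ 0.
* DVH indices are computed from the voxel dose distribution directly
  (Dmean as the masked mean, D98% as the interpolated 2nd percentile, Vx
  exactly), with the binned cumulative curve kept for plotting; the
  organ-specific index set is D98%/V76Gy for prostate, V70Gy for bladder,
  V72Gy for rectum, Dmean for all.  Bladder/rectum *wall* masks (7/5 mm
  negative expansion) are available via `wall_mask()`; default reporting
  uses whole organs.
* Dose warping is trilinear without Jacobian weighting — interpolated
  dose, not energy/mass remapping — matching the accumulation protocol
  this package implements; that is a known limitation of the
  interpolation approach.
* Fraction doses are the planning dose rigidly carried to each fraction
  frame ("dose deformation-invariance"); CBCT dose recalculation is out
  of scope.

## Numerical choices

* Cubic B-spline *interpolation* (resampling) uses the standard recursive
  prefilter (pole √3−2, mirror boundary); linear functions are reproduced
  exactly away from the border.
* The bone-based rigid registration matches Gaussian-smoothed bone-window
  intensities (clamped to [200, 800] HU) rather than hard bone masks —
  binarisation quantises the optimum by a noticeable fraction of a voxel —
  and optimises translation first, then all six parameters, by
  Nelder-Mead from a centre-of-mass initialisation.  Recovery on the
  phantom is ≈ 0.4 mm; the spurious rotation is below 0.1°.
* Out-of-grid samples replicate the border everywhere (warping,
  resampling); deterministic seeds flow from configuration objects into
  every stochastic component (weight init, shuffling, voxel subsampling),
  and the RNG state of the caller is always restored.

## Desk-scale problem sizes

The test suite and the acceptance script run the full chain at 64×64×32
voxels, 3 mm isotropic (phantom training, FFD recovery, dose
accumulation), with one 128×128×64 (1.5 mm) phantom for the
ground-truth-consistency check; networks train on 20 pairs at widths
8/16/16/16 for 8–15 epochs.  These sizes were chosen so the whole study
is a CPU-minutes exercise while every organ remains several voxels
across.

## Known limitations

* The networks here demonstrate the method at desk scale; clinical-scale
  grids (256×256×128) would need the default widths, the default
  schedule, and far more compute than the bundled experiments use.
* The `sc` variant at desk scale barely improves on rigid alignment —
  consistent with the motivating observation that intensity-only
  registration of CT/CBCT pelvis is weak — so its numbers should be read
  as a baseline, not a failure of the implementation.
* ASD/HD95 direction conventions differ across the literature; both the
  directed (default) and symmetric forms are provided.
* Dose accumulation ignores tissue-density changes between fractions
  (interpolated dose only).
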