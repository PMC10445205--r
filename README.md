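# dosewarp

Deformable image registration and dose accumulation for CBCT-guided
pelvic radiotherapy, in R.

During a fractionated prostate treatment the anatomy of each day differs
from the planning CT — bladder filling, rectal content, prostate shifts.
`dosewarp` estimates the dense deformation between the planning CT and
each daily CBCT-like volume, evaluates it geometrically, and uses it to
warp and sum the fraction doses on the planning anatomy so that the
accumulated dose can be compared with the plan.

The package provides:

* **Three weakly supervised registration networks** sharing one 3D U-Net
  body and differing in inputs/loss: intensity-driven (`sc`,
  NMI + smoothness), contour-driven (`msk`, one-hot L1 + smoothness), and
  combined (`sc_msk`, NMI + L1 + smoothness) with loss weights
  α=1/λ=4, α=2/λ=4 and α=1/β=2/λ=4.  Networks, spatial transformer,
  losses and backpropagation are implemented in R + Rcpp (im2col + GEMM).
* **A classical FFD baseline**: multi-resolution (factors 4, 4, 2, 1)
  cubic B-spline free-form deformation, 8 mm final control spacing,
  adaptive stochastic gradient ascent on normalised mutual information.
* **Preprocessing**: bone-based rigid positioning, field-of-view
  cropping, B-spline resampling, intensity clipping to [−1024, 1575] HU
  and normalisation to [0, 1].
* **Evaluation**: Dice coefficient, average surface distance, Hausdorff
  and 95th-percentile Hausdorff distances (oracle-exact surface
  distances), and the percentage of voxels with non-positive Jacobian
  determinant (folding) per organ.
* **Dose machinery**: rigid fraction-dose mapping, pull-back dose
  warping, accumulation, cumulative DVHs and the clinical index set
  (Dmean; D98% and V76Gy for prostate, V70Gy for bladder, V72Gy for
  rectum), plus wall masks by negative expansion.
* **A synthetic pelvic phantom** with analytically known diffeomorphic
  deformations (bladder filling, prostate offset, smooth body warp),
  CBCT-like degradation and a planning-style dose, so the whole chain is
  testable without patient data.

The registration model: a network `g` maps a fixed/moving input pair to a
displacement field `u` on the fixed grid (pull-back convention,
`warped(x) = moving(x + u(x))`), trained without ground-truth fields by
minimising, e.g. for the combined variant,

```
L(Sc_f, Sc_m, Msk_f, Msk_m, u) =
    α · NMI(Sc_f, Sc_m ∘ u) + β · L1(Msk_f, Msk_m ∘ u) + λ · Smooth(u)
```

with soft-binned NMI, one-hot label L1, and a diffusion (squared spatial
gradient) regulariser.

## Worked example

Generate a phantom pair, check that its ground-truth field maps the daily
contours onto the planning contours, and report the planning DVH indices:

```r
library(dosewarp)

pair <- make_phantom(phantom_spec(seed = 1))
warped <- warp(pair$daily$labels, pair$field)
structure_metrics(pair$planning$labels, warped, pair$field)
#>   structure   dsc asd_mm hd_mm hd95_mm fold_pct
#> 1    rectum 0.934  0.734  4.24       3        0
#> 2   bladder 0.966  0.559  3.00       3        0
#> 3  prostate 0.959  0.516  3.00       3        0

dose <- make_planning_dose(pair, prescription = 80)
dvh_indices(dose, pair$planning$labels)
#>   structure Dmean_Gy D98_Gy V70_pct V72_pct V76_pct
#> 1    rectum    9.235     NA      NA   1.136      NA
#> 2   bladder    3.119     NA       0      NA      NA
#> 3  prostate   80.000     80      NA      NA     100
```

The DSC values read against a discretisation ceiling: on the 3 mm
desk-scale grid even the exact field cannot score 1.0 because binarised
contours localise boundaries only to a fraction of a voxel (the same
check at 1.5 mm gives ≥ 0.977 for every organ).  The fold percentage of
the analytic field is 0 by construction.  The dose table shows the
prescription held in the target (Dmean = D98% = 80 Gy, V76Gy = 100%) and
low bystander organ doses.

To train a contour-driven network on a phantom cohort and register a
held-out pair:

```r
cohort <- phantom_cohort(24, seed = 11)
to_pair <- function(p) list(fixed = clip_normalize(p$planning$image),
                            moving = clip_normalize(p$daily$image),
                            fixed_labels = p$planning$labels,
                            moving_labels = p$daily$labels)
fit <- train_network(
  regnet_config("msk", enc = c(8, 16, 16, 16), refine = 8,
                epochs = 15, seed = 7, lr_init = 2e-3),
  pairs = lapply(cohort[1:20], to_pair),
  val   = lapply(cohort[21:22], to_pair))

tp <- to_pair(cohort[[23]])
field <- predict_field(fit$net, tp$fixed, tp$moving,
                       tp$fixed_labels, tp$moving_labels)
mean(sapply(2:4, function(code)
  dsc(tp$fixed_labels$data == code,
      warp(tp$moving_labels, field)$data == code)))
#> ~0.93  (rigid-only alignment of the same pair: ~0.82)
```

A thin command-line interface over the same functions ships in
`inst/cli/dosewarp` (subcommands `phantom`, `preprocess`, `register`,
`ffd`, `evaluate`, `dvh`, `pipeline`).

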