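---
title: "Measuring coronal microvascular displacement: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring coronal microvascular displacement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(coronaflow)
```

## The measurement model

Two en-face OCTA slabs of the same eye, acquired months apart, differ by
the composition of two motions: a **rigid acquisition misalignment**
(rotation + translation of the whole frame, caused by head/eye placement)
and a **biological displacement** — the smooth, spatially varying
tangential shift of the vascular network itself. Only the second is of
clinical interest; it is an order of magnitude smaller than the first
(≈10–20 µm versus up to hundreds of µm), so the rigid part must be removed
before measurement, using the same flow machinery that later measures the
residual.

The displacement estimator is Farnebäck's two-frame algorithm. Each local
neighborhood of an image is approximated by a quadratic polynomial

f(x) ≈ xᵀ A x + bᵀ x + c,

fitted by weighted least squares under a Gaussian applicability of
standard deviation `sigma_app`. Because the basis normal matrix is
constant over the image, the fit reduces to six separable correlations
plus a fixed 6×6 inverse. If two images are related by a pure translation
d, their expansions satisfy A₂ = A₁ and b₂ = b₁ − 2A₁d, giving the
estimator Ā d = Δb with Ā = (A₁+A₂)/2 and Δb = −½(b₂−b₁). Solving this
per pixel is ill-posed where the image is locally 1-dimensional, so the
normal equations are aggregated over a Gaussian window (`agg_sigma`)
before the 2×2 solve; the estimate is refined `n_iter` times (resampling
the moving image's coefficients at x + d) and run coarse-to-fine over an
image pyramid to extend the capture range beyond the expansion's
neighborhood.

Alignment then iterates: sample the dense flow at the 36 × 36 grid of
block centers, solve the closed-form 2D Procrustes problem

argmin_{θ,t} Σᵢ ‖R pᵢ + t − (pᵢ + dᵢ)‖²,

apply the accumulated roto-translation to the *original* moving image
(one interpolation, never compounded), and stop when the sum of squared
grid displacements S changes by less than 3% between iterations. The
"sum of squared differences" of the convergence rule is interpreted as S —
the quantity the fitted roto-translation minimizes — not image-intensity
SSD. The residual flow after convergence is the biological displacement;
its per-node magnitude D = √(Dx²+Dy²) is converted to micrometers with
`1000 · scan_width_mm / width_px` and averaged over the whole frame and
over foveally centered circles of radius 0.5, 0.75 and 1.5 mm.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `sigma_app` | 1.5 | px | neighborhood scale of the polynomial fit; ~vessel caliber |
| `agg_sigma` | 7 | px | aggregation window; trades noise vs field smoothing |
| `n_iter` | 3 | – | refinement steps per level; converges in 2–3 for ≤5 px motion |
| `pyramid_levels` / `scale` | 3 / 0.5 | – | capture range ≈ 15–20 px at 304 px frames |
| `tol` | 0.03 | – | the 3% convergence rule of the alignment loop |
| `n_side` | 36 | – | reporting grid; fixed by the measurement convention |
| `radii_mm` | 0.5, 0.75, 1.5 | mm | central subfield, inner ring, parafovea |
| `scan_width_mm` | 3.0 | mm | physical field; µm/px is derived, never hard-coded |
| `tile_grid` / `clip_limit` | 8 / 0.01 | – | CLAHE tiling; technique named by the protocol, parameters not |

Flow parameters are deliberately conventional: the validated quantity is
warp recovery, not parameter fidelity, and all are exposed through
`pipeline_config()`. Whether the original protocol used a pyramid, or
CLAHE versus plain tiled equalization, is not stated; both are config
choices here and neither affects the ≤20 px motions exercised.

## What the synthetic data emulates — and what it does not

`generate_slab_image()` draws branching strokes (SCP), a fine capillary
mesh (DCP) or granular smoothed noise (CC) to match each plexus's texture
scale and lit-pixel density; `ground_truth_warp()` composes a rigid
misalignment (|θ| ≤ 10°, |t| ≤ 5% of the frame) with an elastic field
built from Gaussian-smoothed white noise (correlation length 15 px,
zero-mean components, rescaled to an exact mean magnitude in µm);
`apply_warp()` resamples backward through the analytically inverted map,
so the stored ground truth d(p) = φ(p) − p is exact, not interpolated.
`simulate_cohort()` draws per-eye/per-slab displacement records from the
same random-intercept structure the mixed model assumes, truncated at
zero (truncation, not folding, preserves the mean structure at the
simulated effect sizes).

The generator does **not** emulate OCTA speckle statistics, projection
artifacts, segmentation errors, drusen morphology, or flow-signal dropout.
`noise_sd` is a free knob, not a device claim. A green test therefore
establishes that the *pipeline* recovers known warps and known cohort
structure — not that the original clinical measurements are reproduced;
those depend on raw images that are not publicly available.

## Numerical choices

- **Coordinates.** x = columns rightward, y = rows downward, pixel
  (r, k) centered at (k+½, r+½); rotations are about the image center
  (any other center is absorbed into t, fixing it makes θ identifiable).
  Flow maps reference→moving: ref(p) ≈ mov(p + d(p)).
- **Boundaries.** Separable correlations reflect at edges; the polynomial
  fit is biased there, so `valid` masks exclude a ceil(3·sigma_app)
  border. Singular aggregated 2×2 systems mark pixels invalid rather than
  propagating non-finite values.
- **Convergence guards.** If S < 10⁻¹² px² (identical images) the
  alignment declares convergence immediately; hitting `max_iter` warns
  and flags, never errors.
- **Ties.** The per-eye max-displacement slab breaks ties in the fixed
  order CC > DCP > SCP, with a flag.
- **Equalization is not idempotent at the default clip.** With
  `clip_limit = 0.01` each CLAHE pass is deliberately damped, so repeated
  application keeps stretching contrast; near-idempotence (a second pass
  changing the image much less than the first) holds from
  `clip_limit ≈ 0.05` upward. The pipeline applies it exactly once per
  image, so the default favors artifact suppression over idempotence.
- **Degenerate statistics.** Zero-variance paired differences are flagged
  (p = 1 only when the mean difference is also 0); a zero-residual cohort
  is fitted by OLS with variances pinned at 0 and `boundary = TRUE`.

## Mixed-model inference

The model is `displacement_um ~ slab + (1 | patient_id)` by REML (lme4),
CC as reference. On the balanced designs produced here the estimated
marginal mean of a slab equals that slab's raw mean — each is a mean of
`n` independent patient values with variance (σ²ᵤ + σ²ₑ)/n — so EMM CIs
use a t quantile with df = n_patients − 1, and slab contrasts (a
within-patient effect) use containment df = (n−1)(k−1). These df choices
were fixed a priori on design grounds; the coverage simulation in the
acceptance suite (200 replicates, true means 13/15/19 µm, patient SD 5,
residual SD 3, n = 18) checks that each true mean is covered by its 95%
CI at a 93–97% rate. The omnibus slab effect is reported as a
likelihood-ratio test of ML refits, alongside the per-contrast t tests,
because the source protocol does not say which it reported. No
multiplicity adjustment is applied (three slab-level tests), matching the
reporting convention; the association tests use Fisher's exact test and
the group comparison Welch's t — both artifact conventions, since the
source does not name its tests.

## Known limitations

- Gaussian aggregation (σ = 7 px) low-pass-filters the recovered field;
  for elastic fields with 15 px correlation length this attenuates the
  mean magnitude by ≈15%. The acceptance band (±20%) covers this known
  bias; callers comparing absolute magnitudes across parameter settings
  should keep `agg_sigma` fixed.
- A closed-form power calculation shows the paired-t Monte-Carlo example
  (n = 18, unit effect, α = 0.01) has power ≈0.89, so the test asserts
  the simulated rejection rate against that oracle value rather than an
  aspirational 95%.
- Rotation and elastic displacement are partially confounded at a single
  grid scale: a curl-bearing elastic field can donate a small rotation to
  the rigid fit (≲0.2° at 15 µm mean elastic). The residual grid is
  asserted to carry no remaining rigid component instead.
- The renderer writes NetPBM (PGM/PPM) rather than PNG/TIFF: the offline
  toolchain has no R bindings for those formats, and the byte-level
  determinism requirement is easier to guarantee in a header+raster
  format.
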