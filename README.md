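# coronaflow

Quantifying coronal (en-face, in-plane) displacement of the retinal
microvasculature between two OCTA acquisitions of the same eye.

## The problem

Optical coherence tomography angiography (OCTA) images blood flow in the
retinal microvascular layers — the superficial capillary plexus (SCP), the
deep capillary plexus (DCP) and the choriocapillaris (CC) — as 2D en-face
slabs of a fovea-centered 3 × 3 mm field. Between a baseline scan (T0) and
a follow-up scan (T6), the vascular network itself can shift tangentially
as the tissue remodels. That biological displacement is small (tens of
micrometers) and is confounded by a much larger rigid acquisition
misalignment (the eye and scanner never sit identically twice).
`coronaflow` separates the two and reports the biological part.

## The method

For each slab pair the pipeline runs:

1. **Preprocessing** — grayscale conversion and local (tiled,
   contrast-limited) histogram equalization of each image independently.
2. **Iterative rigid alignment** — dense optical flow is estimated between
   the pair, sampled on a regular 36 × 36 node grid, and the
   roto-translation (θ, tx, ty) minimizing
   Σᵢ ‖R pᵢ + t − (pᵢ + dᵢ)‖² over the grid vectors is solved in closed
   form (2D Procrustes, no scaling) and applied to the moving image. This
   repeats until the sum of squared grid displacements changes by less
   than 3% between iterations.
3. **Motion estimation** — the residual displacement field is computed by
   the Farnebäck two-frame algorithm: each local neighborhood is modeled
   as a quadratic polynomial expansion f(x) ≈ xᵀAx + bᵀx + c under a
   Gaussian applicability, and the per-pixel displacement solves the
   neighborhood-aggregated normal equations Ā d = Δb, iterated
   coarse-to-fine over an image pyramid. (The implementation is in this
   package; an independent scikit-image flow is used only as a test
   oracle.)
4. **Measurement** — per-vector magnitude D = √(Dx² + Dy²), converted to
   micrometers via the physical scale (1000 · scan_width_mm / width_px),
   averaged over the whole image and over circles of radius 0.5, 0.75 and
   1.5 mm centered on the fovea.
5. **Cohort statistics** — Shapiro–Wilk screening, paired t-tests with
   Cohen's d, a REML linear mixed model `displacement ~ slab +
   (1 | patient)` with CC as the reference category and estimated marginal
   means with 95% CI, per-eye classification by the slab of greatest
   displacement, and phenotype associations (RPD, dPED, drusen, iRORA).
6. **Rendering** — yellow displacement arrows over the slab and a
   color-coded deformation map on a fixed 0–90 µm blue→red scale.

Because clinical OCTA scans are not distributable, the package ships a
synthetic generator: slab-style vascular textures, known rigid + smooth
elastic ground-truth warps, and a cohort simulator matching the mixed
model's structure. Every stage is validated against that ground truth.

## Worked example

```r
library(coronaflow)

img <- generate_slab_image(slab_style("DCP"), size_px = 192, seed = 5)
w   <- ground_truth_warp(theta = 2, t = c(8, -5), mean_elastic_um = 15,
                         size_px = 192, seed = 31)
mov <- apply_warp(img, w, noise_sd = 0.02, seed = 9)

pp <- preprocess_pair(img, mov)
al <- align_iterative(pp$ref, pp$mov)
al$transform
#> <RigidTransform theta = 2.1136 deg, t = (8.009, -4.997) px>

summarize_displacement(al$residual_grid, img)
#>   slab   roi  mean_um    sd_um n_nodes timepair
#> 1  DCP whole 12.67793 6.883040    1156    T0-T6
#> 2  DCP  r0.5 14.21319 5.781430     112    T0-T6
#> 3  DCP r0.75 11.68371 5.051781     256    T0-T6
#> 4  DCP  r1.5 11.90413 6.434018     988    T0-T6
```

The recovered transform matches the injected misalignment (2°, 8, −5) —
the extra 0.11° of rotation is elastic curl absorbed into the rigid fit,
which is why rigid-only pairs recover θ to ≈0.01° while elastic-bearing
pairs sit within ≈0.2°; the whole-image residual mean (≈12.7 µm) estimates
the injected 15 µm biological displacement with the ≈15% attenuation that
Gaussian flow aggregation produces (see the methods vignette). A cohort
run:

```r
tb  <- run_pipeline("manifest.csv", pipeline_config(), out_dir = "out")
fit <- fit_lmm(simulate_cohort(cohort_spec(), seed = 1))
```

## Command line

```sh
Rscript inst/cli/coronaflow.R simulate --out-dir sim --n-eyes 3 --seed 1
Rscript inst/cli/coronaflow.R run-all --manifest sim/manifest.csv --out-dir out
Rscript inst/cli/coronaflow.R stats --cohort out/cohort.csv --out report.json
```

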